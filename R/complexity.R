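# Sequence-complexity metrics of modal reads: Shannon entropy over base
# fractions, mutual information over non-overlapping 2-mers, and the
# one-way ANOVA across cluster sizes.

#' Shannon entropy of a nucleotide string
#'
#' H = -sum over x in \{G,A,T,C\} of p(x) log2 p(x), where p(x) is the
#' fraction of the string consisting of base x and 0 log2 0 is taken as 0.
#' Homopolymers score 0, perfect dinucleotide repeats 1, uniform base
#' composition 2. N bases are excluded from the fractions.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Numeric vector of entropies in bits (\code{NA} for empty or
#'   all-N strings).
#' @export
shannon_entropy <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s)) return(NA_real_)
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    b <- b[b %in% c("A", "C", "G", "T")]
    if (!length(b)) return(NA_real_)
    p <- table(b) / length(b)
    -sum(p * log2(p)) + 0  # + 0 avoids IEEE negative zero for homopolymers
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mutual information between odd and even positions of a nucleotide string
#'
#' The string is made even by dropping its first character if needed, then
#' split into consecutive non-overlapping 2-mers (x, y). With p(x, y) the
#' fraction of 2-mers and the marginals p(x), p(y) the base fractions of the
#' whole evened string, I = sum p(x,y) log2( p(x,y) / (p(x) p(y)) ) over
#' observed pairs. High when a base strongly predicts its successor: perfect
#' dinucleotide repeats score 2 bits, homopolymers 0. 2-mers containing N
#' are dropped and the marginals taken from the remaining pairs.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Numeric vector of mutual information in bits (\code{NA} when
#'   fewer than one valid 2-mer remains).
#' @export
mutual_information <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s)) return(NA_real_)
    n <- nchar(s)
    if (n %% 2L == 1L) {
      s <- substr(s, 2L, n)
      n <- n - 1L
    }
    if (n < 2L) return(NA_real_)
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    x <- b[seq(1L, n, by = 2L)]
    y <- b[seq(2L, n, by = 2L)]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    x <- x[ok]
    y <- y[ok]
    pxy <- table(paste0(x, y)) / length(x)
    pb <- table(c(x, y)) / (2L * length(x))
    px <- pb[substr(names(pxy), 1L, 1L)]
    py <- pb[substr(names(pxy), 2L, 2L)]
    sum(pxy * log2(as.numeric(pxy) / (as.numeric(px) * as.numeric(py))))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Complexity of the modal read of each UMI-read cluster
#'
#' One record per cluster (not per read): Shannon entropy and mutual
#' information of the cluster's modal read sequence — the most frequent
#' sequence among reads at the modal coordinate — together with the cluster
#' size. Clusters without a stored sequence are skipped and tallied.
#'
#' @param clusters An [umi_clusters()] object whose alignments carried read
#'   sequences.
#' @return Data.frame with columns \code{cluster_size}, \code{sequence},
#'   \code{H_bits}, \code{I_bits}; attribute \code{n_skipped} counts
#'   clusters lacking a sequence.
#' @export
modal_read_complexity <- function(clusters) {
  has_seq <- !is.na(clusters$modal_sequence)
  cl <- clusters[has_seq, , drop = FALSE]
  out <- data.frame(cluster_size = cl$size,
                    sequence = cl$modal_sequence,
                    H_bits = shannon_entropy(cl$modal_sequence),
                    I_bits = mutual_information(cl$modal_sequence),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!has_seq)
  out
}

#' One-way ANOVA of a complexity metric across cluster sizes
#'
#' Classical fixed-effects one-way analysis of variance with cluster size as
#' the factor, fitted with [stats::aov()]. Size groups with fewer than
#' \code{min_group} records are dropped with a warning (their within-group
#' variance is undefined at 1). When the within-group mean square is zero
#' while group means differ, F is infinite and p is 0.
#'
#' @param records Data.frame from [modal_read_complexity()].
#' @param metric Column to analyse: \code{"H_bits"} or \code{"I_bits"}.
#' @param min_group Minimum records per size group (default 2).
#' @return List with \code{F}, \code{p}, \code{df} (numerator,
#'   denominator), \code{groups} (sizes retained) and the aov \code{table};
#'   \code{NULL} (with a message) when fewer than two eligible groups
#'   remain.
#' @export
anova_by_cluster_size <- function(records, metric = c("H_bits", "I_bits"),
                                  min_group = 2L) {
  metric <- match.arg(metric)
  y <- records[[metric]]
  ok <- !is.na(y)
  size <- records$cluster_size[ok]
  y <- y[ok]
  tab <- table(size)
  small <- names(tab)[tab < min_group]
  if (length(small)) {
    warning("dropping cluster-size group(s) with < ", min_group,
            " records: ", paste(small, collapse = ", "))
    keep <- !(as.character(size) %in% small)
    size <- size[keep]
    y <- y[keep]
  }
  if (length(unique(size)) < 2L) {
    message("fewer than 2 eligible cluster-size groups; ANOVA skipped")
    return(NULL)
  }
  fit <- stats::aov(y ~ factor(size))
  tab <- stats::anova(fit)
  ssb <- tab$`Sum Sq`[1L]
  ssw <- tab$`Sum Sq`[2L]
  df <- tab$Df
  msb <- ssb / df[1L]
  msw <- ssw / df[2L]
  if (msw <= 1e-12 * max(msb, 1) && msb > 0) {
    f <- Inf
    p <- 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, df[1L], df[2L], lower.tail = FALSE)
  }
  list(F = f, p = p, df = df, groups = sort(unique(size)), table = tab,
       metric = metric)
}
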