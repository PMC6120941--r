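# The core method: per-coordinate UMI merging at Levenshtein distance <= 1,
# chaining of coordinates sharing a UMI into UMI-read clusters under a gap
# threshold, cluster collapsing, and shift/cluster statistics.

#' Levenshtein edit distance
#'
#' Minimum number of single-character substitutions, insertions or deletions
#' converting \code{a} into \code{b}; elementwise over recycled vectors.
#'
#' @param a,b Character vectors.
#' @return Integer vector of edit distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1L, 1L])
  out
}

#' Merge the UMIs observed at one coordinate
#'
#' UMIs mapping to the same coordinate are considered the same molecule's tag
#' when their Levenshtein distance is at most 1 (PCR or sequencing error in
#' the UMI). Because "distance <= 1" is not transitive, assignment is greedy
#' and deterministic: UMIs are visited in descending read count (ties broken
#' lexicographically); each joins the earliest-founded representative within
#' distance 1, else founds a new group. This mirrors the abundance-first
#' logic of established UMI error correctors. An N inside a UMI matches only
#' another N.
#'
#' @param umi_counts Named numeric vector: read count per observed UMI.
#' @return A data.frame with one row per observed UMI: \code{umi},
#'   \code{count}, \code{representative} (the group it was merged into).
#' @export
merge_umis_at_position <- function(umi_counts) {
  if (!length(umi_counts))
    return(data.frame(umi = character(), count = numeric(),
                      representative = character(),
                      stringsAsFactors = FALSE))
  umis <- names(umi_counts)
  if (is.null(umis) || anyNA(umis))
    stop("umi_counts must be named by UMI", call. = FALSE)
  ord <- order(-umi_counts, umis)
  reps <- character(0)
  assigned <- character(length(umis))
  for (i in ord) {
    u <- umis[i]
    hit <- 0L
    if (length(reps)) {
      d <- utils::adist(u, reps)
      w <- which(d <= 1L)
      if (length(w)) hit <- w[1L]
    }
    if (hit) {
      assigned[i] <- reps[hit]
    } else {
      reps <- c(reps, u)
      assigned[i] <- u
    }
  }
  data.frame(umi = umis, count = as.numeric(umi_counts),
             representative = assigned, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Index merged UMI groups by (reference, strand, representative UMI)
#'
#' Cross-position identity uses exact equality of representatives: the
#' Levenshtein merge applies only among UMIs at the same coordinate.
#'
#' @param groups Data.frame with columns \code{reference}, \code{strand},
#'   \code{representative}, \code{coordinate}, \code{count} (one row per
#'   merged group per position).
#' @return The same rows sorted by reference, strand, representative and
#'   ascending coordinate, with a \code{key} column identifying each
#'   (reference, strand, representative) combination.
#' @export
build_position_index <- function(groups) {
  o <- order(groups$reference, groups$strand, groups$representative,
             groups$coordinate)
  out <- groups[o, , drop = FALSE]
  out$key <- paste(out$reference, out$strand, out$representative, sep = "\r")
  rownames(out) <- NULL
  out
}

#' Chain one UMI's mapping coordinates into UMI-read clusters
#'
#' Single-linkage chaining over the sorted coordinate list: a new cluster
#' starts whenever the gap to the previous coordinate exceeds
#' \code{max_gap}. A cluster may therefore span more than \code{max_gap} in
#' total. Every coordinate belongs to exactly one cluster.
#'
#' @param coordinates Strictly increasing integer vector of 1-based mapping
#'   positions for one (reference, strand, UMI) key.
#' @param counts Read count at each coordinate (same length).
#' @param max_gap Maximum spacing (bp) joining adjacent coordinates
#'   (default 3).
#' @return A list of clusters, each a list with \code{coordinates},
#'   \code{counts}, \code{size}, \code{total_reads}, \code{mode} (coordinate
#'   with the maximal count; ties take the leftmost).
#' @export
find_clusters <- function(coordinates, counts, max_gap = 3L) {
  stopifnot(length(coordinates) == length(counts), max_gap >= 0L)
  if (!length(coordinates)) return(list())
  if (is.unsorted(coordinates, strictly = TRUE))
    stop("coordinates must be strictly increasing", call. = FALSE)
  id <- cumsum(c(1L, as.integer(diff(coordinates) > max_gap)))
  lapply(unname(split(seq_along(coordinates), id)), function(i) {
    co <- coordinates[i]
    ct <- counts[i]
    list(coordinates = co, counts = ct, size = length(co),
         total_reads = sum(ct), mode = co[which.max(ct)])
  })
}

#' Classify a cluster's spacing as strictly-n
#'
#' A cluster has mapping shifts of strictly n when every spacing between
#' adjacent mapping coordinates equals n bp. Size-1 clusters have no shifts.
#'
#' @param coordinates Sorted coordinate vector of one cluster.
#' @return \code{"none"} for size-1 clusters, the spacing \code{n} as a
#'   character string when uniform, \code{"mixed"} otherwise.
#' @export
classify_strict_shift <- function(coordinates) {
  if (length(coordinates) < 2L) return("none")
  g <- unique(diff(coordinates))
  if (length(g) == 1L) as.character(g) else "mixed"
}

#' Detect UMI-read clusters in UMI-tagged alignments
#'
#' The central operation. At each (reference, strand, coordinate), observed
#' UMIs are merged at Levenshtein distance <= 1
#' ([merge_umis_at_position()]); each representative's coordinates are then
#' chained into clusters wherever adjacent positions lie within
#' \code{max_gap} bp ([find_clusters()]). Each cluster records its
#' per-coordinate read counts, modal coordinate, strictly-n spacing class and
#' the modal read sequence (most frequent sequence among the cluster's reads
#' at the modal coordinate, ties lexicographic).
#'
#' @param alignments UMI-alignment table from [umi_alignments()] (columns
#'   \code{umi}, \code{reference}, \code{strand}, \code{coordinate}, and
#'   optionally \code{sequence}).
#' @param max_gap Maximum spacing (bp) joining adjacent coordinates into one
#'   cluster (default 3; 0 degenerates to per-coordinate UMI counting).
#' @param ignore_strand Group sense and antisense reads at one coordinate
#'   together (default \code{FALSE}: they are distinct molecules).
#' @return An object of class \code{"umi_clusters"}: a data.frame with one
#'   row per cluster and columns \code{umi} (representative), \code{reference},
#'   \code{strand}, \code{coordinates} and \code{counts} (list columns),
#'   \code{size}, \code{total_reads}, \code{mode}, \code{strict_class},
#'   \code{modal_sequence}; attributes record \code{max_gap},
#'   \code{ignore_strand} and the number of input alignments.
#' @seealso [collapse_clusters()], [shift_distribution()],
#'   [summary.umi_clusters()]
#' @export
umi_clusters <- function(alignments, max_gap = 3L, ignore_strand = FALSE) {
  max_gap <- as.integer(max_gap)
  stopifnot(max_gap >= 0L)
  n_in <- nrow(alignments)
  if (is.null(alignments$umi) && !is.null(alignments$read_id))
    alignments$umi <- umi_from_id(alignments$read_id)
  if (anyNA(alignments$umi))
    stop("alignments without a UMI", call. = FALSE)
  if (is.null(alignments$sequence))
    alignments$sequence <- NA_character_
  if (ignore_strand) alignments$strand <- "+"

  empty <- data.frame(umi = character(), reference = character(),
                      strand = character(), size = integer(),
                      total_reads = numeric(), mode = integer(),
                      strict_class = character(),
                      modal_sequence = character(),
                      stringsAsFactors = FALSE)
  if (!n_in) {
    empty$coordinates <- list()
    empty$counts <- list()
    return(structure(empty, class = c("umi_clusters", "data.frame"),
                     max_gap = max_gap, ignore_strand = ignore_strand,
                     n_alignments = 0L))
  }

  pos_key <- paste(alignments$reference, alignments$strand,
                   alignments$coordinate, sep = "\r")
  pu_key <- paste(pos_key, alignments$umi, sep = "\r")
  pu <- factor(pu_key, levels = unique(pu_key))
  pu_count <- tabulate(pu)
  pu_first <- match(levels(pu), pu_key)

  # per-position greedy Levenshtein merge (fast path: one UMI at a position)
  pu_pos <- pos_key[pu_first]
  pu_umi <- alignments$umi[pu_first]
  rep_of_pu <- pu_umi
  multi <- split(seq_along(pu_umi), pu_pos)
  for (idx in multi) {
    if (length(idx) > 1L) {
      m <- merge_umis_at_position(stats::setNames(pu_count[idx], pu_umi[idx]))
      rep_of_pu[idx] <- m$representative[match(pu_umi[idx], m$umi)]
    }
  }

  # reassign reads to their representative and re-aggregate per position
  rep_of_read <- rep_of_pu[as.integer(pu)]
  grp_key <- paste(pos_key, rep_of_read, sep = "\r")
  grp <- factor(grp_key, levels = unique(grp_key))
  grp_count <- tabulate(grp)
  grp_first <- match(levels(grp), grp_key)
  grp_seq <- vapply(split(alignments$sequence, grp), modal_value,
                    character(1))

  groups <- data.frame(
    reference = alignments$reference[grp_first],
    strand = alignments$strand[grp_first],
    coordinate = alignments$coordinate[grp_first],
    representative = rep_of_read[grp_first],
    count = grp_count,
    modal_sequence = as.vector(grp_seq),
    stringsAsFactors = FALSE)
  groups <- build_position_index(groups)

  # chain coordinates per key into clusters
  keyf <- factor(groups$key, levels = unique(groups$key))
  new_key <- c(TRUE, keyf[-1L] != keyf[-length(keyf)])
  gap_break <- c(TRUE, diff(groups$coordinate) > max_gap)
  cl_id <- cumsum(new_key | gap_break)

  cl <- split(seq_len(nrow(groups)), cl_id)
  first <- vapply(cl, `[`, integer(1), 1L)
  coords <- lapply(cl, function(i) groups$coordinate[i])
  cnts <- lapply(cl, function(i) groups$count[i])
  mode_i <- vapply(cl, function(i) i[which.max(groups$count[i])], integer(1))
  out <- data.frame(
    umi = groups$representative[first],
    reference = groups$reference[first],
    strand = groups$strand[first],
    size = lengths(coords),
    total_reads = vapply(cnts, sum, numeric(1)),
    mode = groups$coordinate[mode_i],
    strict_class = vapply(coords, classify_strict_shift, character(1)),
    modal_sequence = groups$modal_sequence[mode_i],
    stringsAsFactors = FALSE)
  out$coordinates <- coords
  out$counts <- cnts
  rownames(out) <- NULL
  structure(out, class = c("umi_clusters", "data.frame"),
            max_gap = max_gap, ignore_strand = ignore_strand,
            n_alignments = n_in)
}

# most frequent value, ties broken by the smallest; NAs ignored
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  t <- table(x)
  names(t)[which.max(t)]  # table is sorted by name, which.max takes first
}

#' @export
print.umi_clusters <- function(x, ...) {
  cat("UMI-read clusters:", nrow(x), "clusters from",
      attr(x, "n_alignments"), "unique alignments",
      sprintf("(max_gap = %d bp%s)\n", attr(x, "max_gap"),
              if (isTRUE(attr(x, "ignore_strand"))) ", strand ignored" else ""))
  if (nrow(x)) {
    cat("  sizes: ", paste0(range(x$size), collapse = "-"),
        "; total reads: ", sum(x$total_reads), "\n", sep = "")
    utils::str(utils::head(as.data.frame(x)[c("umi", "reference", "strand",
                                              "size", "total_reads", "mode",
                                              "strict_class")], 5L))
  }
  invisible(x)
}

#' Collapse each UMI-read cluster into a single molecule observation
#'
#' Replaces every cluster by one observation of its UMI at the modal
#' coordinate (ties in per-coordinate counts take the leftmost coordinate),
#' carrying the cluster's total read count for reporting.
#'
#' @param clusters An [umi_clusters()] object.
#' @return Data.frame with columns \code{reference}, \code{strand},
#'   \code{coordinate} (the mode), \code{umi}, \code{total_reads} — one row
#'   per cluster.
#' @export
collapse_clusters <- function(clusters) {
  data.frame(reference = clusters$reference, strand = clusters$strand,
             coordinate = clusters$mode, umi = clusters$umi,
             total_reads = clusters$total_reads, stringsAsFactors = FALSE)
}

#' Uncollapsed molecule observations
#'
#' One observation per (UMI, coordinate) pair — the counting scheme that
#' treats every mapping position of a UMI as a distinct molecule.
#'
#' @param clusters An [umi_clusters()] object.
#' @return Data.frame with columns \code{reference}, \code{strand},
#'   \code{coordinate}, \code{umi}, \code{reads}.
#' @export
uncollapsed_observations <- function(clusters) {
  n <- clusters$size
  data.frame(reference = rep(clusters$reference, n),
             strand = rep(clusters$strand, n),
             coordinate = unlist(clusters$coordinates, use.names = FALSE),
             umi = rep(clusters$umi, n),
             reads = unlist(clusters$counts, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Pooled mapping-shift distribution
#'
#' Each cluster's modal coordinate is normalized to offset zero (upstream
#' positions negative, downstream positive) and read counts are summed
#' across clusters per offset; counts are converted to proportions summing
#' to 1. Optionally restricted to clusters whose spacings are strictly
#' \code{n} bp.
#'
#' @param clusters An [umi_clusters()] object.
#' @param strict_n Restrict to strictly-n clusters (integer), or \code{NULL}
#'   for all clusters including size 1.
#' @return An object of class \code{"shift_distribution"}: a data.frame with
#'   columns \code{offset}, \code{reads}, \code{density}, sorted by offset.
#'   Empty when no cluster qualifies (density then undefined).
#' @export
shift_distribution <- function(clusters, strict_n = NULL) {
  keep <- if (is.null(strict_n)) rep(TRUE, nrow(clusters))
  else clusters$strict_class == as.character(strict_n)
  cl <- clusters[keep, , drop = FALSE]
  if (!nrow(cl)) {
    out <- data.frame(offset = integer(), reads = numeric(),
                      density = numeric())
    return(structure(out, class = c("shift_distribution", "data.frame"),
                     strict_n = strict_n, n_clusters = 0L))
  }
  offs <- unlist(mapply(function(co, mo) co - mo, cl$coordinates, cl$mode,
                        SIMPLIFY = FALSE), use.names = FALSE)
  cts <- unlist(cl$counts, use.names = FALSE)
  pooled <- tapply(cts, offs, sum)
  out <- data.frame(offset = as.integer(names(pooled)),
                    reads = as.numeric(pooled))
  out <- out[order(out$offset), , drop = FALSE]
  out$density <- out$reads / sum(out$reads)
  rownames(out) <- NULL
  structure(out, class = c("shift_distribution", "data.frame"),
            strict_n = strict_n, n_clusters = nrow(cl))
}

#' @export
print.shift_distribution <- function(x, ...) {
  n <- attr(x, "strict_n")
  cat("Pooled mapping-shift distribution",
      if (!is.null(n)) sprintf("(strictly %s bp)", n) else "(all clusters)",
      "over", attr(x, "n_clusters"), "clusters\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Plot a pooled shift distribution
#'
#' Bars show the square root of the probability density to make the small
#' off-mode proportions visible; stored densities are untransformed.
#'
#' @param x A [shift_distribution()] object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.shift_distribution <- function(x, ...) {
  if (!nrow(x)) {
    warning("empty shift distribution; nothing to plot")
    return(invisible(x))
  }
  graphics::barplot(sqrt(x$density), names.arg = x$offset,
                    xlab = "offset from modal coordinate (bp)",
                    ylab = expression(sqrt(density)), ...)
  invisible(x)
}

#' @rdname shift_distribution
#' @param x An [umi_clusters()] object (method for [plot()]).
#' @param ... Passed on to [plot.shift_distribution()].
#' @export
plot.umi_clusters <- function(x, strict_n = NULL, ...) {
  plot(shift_distribution(x, strict_n = strict_n), ...)
}

#' Summarize UMI-read clusters by size and spacing class
#'
#' Proportions of clusters of each size and proportions of reads contained
#' in clusters of each size, the strictly-n shift tables for n = 1, 2, 3,
#' and the maximum observed cluster size.
#'
#' @param object An [umi_clusters()] object.
#' @param strict_n Spacing classes for which restricted shift tables are
#'   computed (default 1:3).
#' @param ... Ignored.
#' @return An object of class \code{"umi_clusters_summary"}: a list with
#'   \code{clusters_by_size} and \code{reads_by_size} data.frames (columns
#'   \code{size}, \code{n}/\code{reads}, \code{proportion}),
#'   \code{max_size}, \code{strict_tally} and \code{strict_shift_tables}.
#' @export
summary.umi_clusters <- function(object, strict_n = 1:3, ...) {
  if (!nrow(object)) {
    by_size <- data.frame(size = integer(), n = integer(),
                          proportion = numeric())
    reads_by_size <- data.frame(size = integer(), reads = numeric(),
                                proportion = numeric())
    res <- list(n_clusters = 0L, total_reads = 0,
                clusters_by_size = by_size, reads_by_size = reads_by_size,
                max_size = NA_integer_, strict_tally = table(character()),
                strict_shift_tables = list())
    return(structure(res, class = "umi_clusters_summary"))
  }
  tab <- table(object$size)
  by_size <- data.frame(size = as.integer(names(tab)),
                        n = as.integer(tab),
                        proportion = as.numeric(tab) / nrow(object))
  rtab <- tapply(object$total_reads, object$size, sum)
  reads_by_size <- data.frame(size = as.integer(names(rtab)),
                              reads = as.numeric(rtab),
                              proportion = as.numeric(rtab) /
                                sum(object$total_reads))
  rownames(by_size) <- rownames(reads_by_size) <- NULL
  sst <- lapply(strict_n, function(n) shift_distribution(object, n))
  names(sst) <- paste0("strictly_", strict_n)
  structure(list(n_clusters = nrow(object),
                 total_reads = sum(object$total_reads),
                 clusters_by_size = by_size,
                 reads_by_size = reads_by_size,
                 max_size = max(object$size),
                 strict_tally = table(object$strict_class),
                 strict_shift_tables = sst),
            class = "umi_clusters_summary")
}

#' @export
print.umi_clusters_summary <- function(x, ...) {
  cat("UMI-read cluster summary:", x$n_clusters, "clusters,",
      x$total_reads, "reads; max size", x$max_size, "\n")
  cat("\nClusters by size:\n")
  print(x$clusters_by_size, row.names = FALSE)
  cat("\nReads by size:\n")
  print(x$reads_by_size, row.names = FALSE)
  cat("\nSpacing classes:\n")
  print(x$strict_tally)
  invisible(x)
}

#' Write a cluster table as TSV
#'
#' Columns: umi, reference, strand, coordinates and counts (comma-joined),
#' size, total_reads, mode, strict_class.
#'
#' @param clusters An [umi_clusters()] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  flat <- data.frame(
    umi = clusters$umi, reference = clusters$reference,
    strand = clusters$strand,
    coordinates = vapply(clusters$coordinates, paste, character(1),
                         collapse = ","),
    counts = vapply(clusters$counts, paste, character(1), collapse = ","),
    size = clusters$size, total_reads = clusters$total_reads,
    mode = clusters$mode, strict_class = clusters$strict_class,
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
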