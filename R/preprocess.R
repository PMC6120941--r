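# FASTQ-level UMI handling: quality filtering on the UMI substring, UMI
# extraction into the read header, motif trimming, fixed-length trimming.

#' Describe where the UMI lives in a library layout
#'
#' A layout states how the unique molecular identifier (UMI) is carried by the
#' raw reads: inline at the 5' end of the biological read
#' (\code{"inline-5prime"}), on the mate read of a pair (\code{"mate-read"}),
#' or already placed in the read header upstream (\code{"header"}).
#'
#' @param mode One of \code{"inline-5prime"}, \code{"mate-read"},
#'   \code{"header"}.
#' @param umi_length UMI length in bp (e.g. 10 for tagmentation libraries,
#'   6 for CEL-Seq2-style, 16 for SCRB-style layouts).
#' @param post_umi_trim Number of bases removed after the UMI
#'   (the expected GGG(G) template-switch motif: 4 for tagmentation data,
#'   3 for CEL-Seq2-style data). A fixed count, not a motif match; how often
#'   the motif was actually present is reported separately.
#' @param fixed_read_trim Optional length to which the biological read is
#'   truncated after UMI handling (\code{NA} for none).
#' @return An object of class \code{"umi_layout"}.
#' @export
umi_layout <- function(mode = c("inline-5prime", "mate-read", "header"),
                       umi_length = 10L, post_umi_trim = 4L,
                       fixed_read_trim = NA_integer_) {
  mode <- match.arg(mode)
  umi_length <- as.integer(umi_length)
  post_umi_trim <- as.integer(post_umi_trim)
  if (is.na(umi_length) || umi_length < 1L)
    stop("umi_length must be >= 1", call. = FALSE)
  if (is.na(post_umi_trim) || post_umi_trim < 0L)
    stop("post_umi_trim must be >= 0", call. = FALSE)
  structure(list(mode = mode, umi_length = umi_length,
                 post_umi_trim = post_umi_trim,
                 fixed_read_trim = as.integer(fixed_read_trim)),
            class = "umi_layout")
}

#' @export
print.umi_layout <- function(x, ...) {
  cat("UMI layout:", x$mode, "| UMI", x$umi_length, "bp | post-UMI trim",
      x$post_umi_trim, "bp")
  if (!is.na(x$fixed_read_trim)) cat(" | read trim to", x$fixed_read_trim, "bp")
  cat("\n")
  invisible(x)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (gzip-transparent).
#' @return A data.frame with columns \code{read_id}, \code{sequence},
#'   \code{quality}, and \code{umi} (\code{NA} until extracted; populated when
#'   the header already carries a \code{UMI:<seq>} field).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(seqs)$qualities)
  ids <- sub("\\s.*$", "", names(seqs))
  reads <- data.frame(read_id = ids,
                      sequence = as.character(seqs),
                      quality = qual,
                      umi = umi_from_id(ids),
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  validate_reads(reads)
  reads
}

#' Write a read table back to FASTQ
#'
#' @param reads Read table as from [read_fastq()].
#' @param path Output path (\code{.gz} suffix compresses).
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

validate_reads <- function(reads) {
  bad <- which(nchar(reads$quality) != nchar(reads$sequence))
  if (length(bad))
    stop("quality/sequence length mismatch for read ",
         reads$read_id[bad[1L]], call. = FALSE)
  invisible(reads)
}

# Parse a UMI out of a read id carrying the "_UMI:<seq>" suffix convention.
umi_from_id <- function(read_id) {
  umi <- rep(NA_character_, length(read_id))
  hit <- grepl("_UMI:[ACGTN]+$", read_id)
  umi[hit] <- sub("^.*_UMI:", "", read_id[hit])
  umi
}

# Mean Phred score (offset 33) of the first umi_length characters of each
# quality string. Characters below '!' are a format error.
umi_mean_phred <- function(quality, umi_length) {
  sub <- substr(quality, 1L, umi_length)
  if (any(nchar(sub) < umi_length))
    stop("quality string shorter than the UMI length", call. = FALSE)
  vapply(sub, function(q) {
    ph <- utf8ToInt(q) - 33L
    if (any(ph < 0L))
      stop("quality character below Phred+33 offset; offset-64 input?",
           call. = FALSE)
    mean(ph)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter reads on the mean Phred quality of the UMI substring
#'
#' Reads whose UMI substring has an arithmetic mean Phred score (offset 33)
#' below \code{min_mean_phred} are discarded: the UMI is the part of the read
#' in which sequencing error must be avoided so that reads sharing a UMI and
#' mapping location are clonal in origin. For \code{"mate-read"} layouts pass
#' the mate carrying the UMI; for \code{"header"} layouts no quality is
#' available and all reads are kept.
#'
#' @param reads Read table.
#' @param layout An [umi_layout()].
#' @param min_mean_phred Threshold on the mean Phred score (default 30).
#' @return The kept rows, with attributes \code{n_kept} and \code{n_discarded}.
#' @export
filter_umi_quality <- function(reads, layout, min_mean_phred = 30) {
  stopifnot(inherits(layout, "umi_layout"))
  validate_reads(reads)
  if (layout$mode == "header") {
    keep <- rep(TRUE, nrow(reads))
  } else {
    keep <- umi_mean_phred(reads$quality, layout$umi_length) >= min_mean_phred
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Extract the inline 5' UMI into the read header
#'
#' Removes the first \code{umi_length} bases (the UMI) plus the following
#' \code{post_umi_trim} motif bases from sequence and quality, and appends the
#' UMI to the read id as a \code{_UMI:<seq>} suffix so that downstream SAM
#' QNAMEs retain it. Reads too short to contain UMI plus motif are dropped and
#' counted. The fraction of reads whose trimmed motif bases actually start
#' with GGG is reported in attribute \code{motif_ggg_fraction}.
#'
#' @param reads Read table.
#' @param layout An [umi_layout()] with \code{mode = "inline-5prime"}.
#' @return Read table with \code{umi} set and sequence/quality trimmed;
#'   attributes \code{n_dropped_short} and \code{motif_ggg_fraction}.
#' @export
extract_umi <- function(reads, layout) {
  stopifnot(inherits(layout, "umi_layout"))
  if (layout$mode != "inline-5prime")
    stop("extract_umi applies to the inline-5prime layout", call. = FALSE)
  validate_reads(reads)
  skip <- layout$umi_length + layout$post_umi_trim
  long_enough <- nchar(reads$sequence) > skip
  dropped <- sum(!long_enough)
  reads <- reads[long_enough, , drop = FALSE]
  umi <- substr(reads$sequence, 1L, layout$umi_length)
  motif <- if (layout$post_umi_trim >= 3L && nrow(reads))
    mean(substr(reads$sequence, layout$umi_length + 1L,
                layout$umi_length + 3L) == "GGG")
  else NA_real_
  out <- data.frame(
    read_id = paste0(reads$read_id, "_UMI:", umi),
    sequence = substr(reads$sequence, skip + 1L, nchar(reads$sequence)),
    quality = substr(reads$quality, skip + 1L, nchar(reads$quality)),
    umi = umi, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.na(layout$fixed_read_trim))
    out <- trim_to_length(out, layout$fixed_read_trim)
  attr(out, "n_dropped_short") <- dropped
  attr(out, "motif_ggg_fraction") <- motif
  out
}

#' Transfer the UMI from the mate read into the biological read's header
#'
#' For layouts in which one read of a pair carries the UMI and the other the
#' biological sequence, takes the first \code{umi_length} bases of each UMI
#' read and attaches them to the paired biological read's id. Pairing is by
#' read-id stem (any \code{/1}, \code{/2}, \code{.1}, \code{.2} suffix is
#' ignored); records must come in matching order.
#'
#' @param biological_reads,umi_reads Paired read tables in matching order.
#' @param layout An [umi_layout()] with \code{mode = "mate-read"}.
#' @return The biological reads with \code{umi} set and the id suffixed,
#'   optionally truncated to \code{fixed_read_trim}.
#' @export
transfer_umi_from_mate <- function(biological_reads, umi_reads, layout) {
  stopifnot(inherits(layout, "umi_layout"))
  if (layout$mode != "mate-read")
    stop("transfer_umi_from_mate applies to the mate-read layout",
         call. = FALSE)
  if (nrow(biological_reads) != nrow(umi_reads))
    stop("read tables differ in length: unpaired records", call. = FALSE)
  stem <- function(id) sub("[/.][12]$", "", id)
  s1 <- stem(biological_reads$read_id)
  s2 <- stem(umi_reads$read_id)
  bad <- which(s1 != s2)
  if (length(bad))
    stop("unpaired records: ", biological_reads$read_id[bad[1L]], " vs ",
         umi_reads$read_id[bad[1L]], call. = FALSE)
  umi <- substr(umi_reads$sequence, 1L, layout$umi_length)
  out <- biological_reads
  out$umi <- umi
  out$read_id <- paste0(out$read_id, "_UMI:", umi)
  if (!is.na(layout$fixed_read_trim))
    out <- trim_to_length(out, layout$fixed_read_trim)
  rownames(out) <- NULL
  out
}

#' Truncate reads to a fixed length
#'
#' @param reads Read table.
#' @param n Target length in bp (reads already shorter are unchanged).
#' @return The truncated read table.
#' @export
trim_to_length <- function(reads, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  reads$sequence <- substr(reads$sequence, 1L, n)
  reads$quality <- substr(reads$quality, 1L, n)
  reads
}

#' Preprocess a FASTQ library: filter on UMI quality, extract the UMI
#'
#' Convenience driver combining [filter_umi_quality()] with the layout's
#' extraction step, reporting per-stage record counts.
#'
#' @param reads Read table (for \code{"mate-read"} layouts, the biological
#'   reads; supply the mates via \code{umi_reads}).
#' @param layout An [umi_layout()].
#' @param min_mean_phred UMI quality threshold; \code{NA} disables the filter.
#' @param umi_reads Mate reads carrying the UMI (mate-read layouts only).
#' @return Processed read table with a \code{counts} attribute
#'   (\code{total}, \code{kept_quality}, \code{out}).
#' @export
preprocess_reads <- function(reads, layout, min_mean_phred = 30,
                             umi_reads = NULL) {
  stopifnot(inherits(layout, "umi_layout"))
  total <- nrow(reads)
  if (layout$mode == "mate-read") {
    if (is.null(umi_reads))
      stop("mate-read layout requires umi_reads", call. = FALSE)
    if (!is.na(min_mean_phred)) {
      keepq <- umi_mean_phred(umi_reads$quality, layout$umi_length) >=
        min_mean_phred
      reads <- reads[keepq, , drop = FALSE]
      umi_reads <- umi_reads[keepq, , drop = FALSE]
    }
    kept <- nrow(reads)
    out <- transfer_umi_from_mate(reads, umi_reads, layout)
  } else if (layout$mode == "inline-5prime") {
    if (!is.na(min_mean_phred))
      reads <- filter_umi_quality(reads, layout, min_mean_phred)
    kept <- nrow(reads)
    out <- extract_umi(reads, layout)
  } else { # header: UMI already present
    kept <- total
    out <- reads
    out$umi <- umi_from_id(out$read_id)
    if (anyNA(out$umi))
      stop("header layout but some read ids lack a UMI:<seq> field",
           call. = FALSE)
    if (!is.na(layout$fixed_read_trim))
      out <- trim_to_length(out, layout$fixed_read_trim)
  }
  attr(out, "counts") <- c(total = total, kept_quality = kept,
                           out = nrow(out))
  out
}
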