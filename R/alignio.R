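# SAM/BAM ingestion: keep uniquely aligning reads and turn them into
# UMI-alignment records keyed by (reference, strand, leftmost coordinate).

#' Read alignments from SAM or BAM
#'
#' Loads every record with its NH auxiliary tag (number of reported
#' alignments). SAM input is converted in a temporary directory via
#' [Rsamtools::asBam()]. Coordinates are 1-based leftmost mapping positions
#' (SAM POS); strand comes from the reverse-complement flag.
#'
#' @param path SAM (\code{.sam}) or BAM file.
#' @return A data.frame with columns \code{read_id}, \code{reference},
#'   \code{strand}, \code{coordinate}, \code{mapq}, \code{sequence},
#'   \code{nh} (\code{NA} when the tag is absent) and \code{mapped}.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "seq"),
    tag = "NH")
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(x$qname))
  out <- data.frame(
    read_id = x$qname,
    reference = as.character(x$rname),
    strand = as.character(x$strand),
    coordinate = x$pos,
    mapq = x$mapq,
    sequence = as.character(x$seq),
    nh = nh,
    mapped = !bitwAnd(x$flag, 4L),
    stringsAsFactors = FALSE)
  out$strand[!out$mapped] <- NA_character_
  out
}

#' Keep uniquely aligning reads
#'
#' Retains mapped records whose NH tag equals 1, mirroring selection of SAM
#' lines carrying \code{NH:i:1}. Unmapped records are dropped regardless of
#' NH. For aligners that omit NH, \code{assume_unique} treats mapped records
#' with MAPQ at or above \code{min_mapq} as unique.
#'
#' @param alignments Alignment table from [read_alignments()].
#' @param assume_unique Fall back to a MAPQ threshold when NH is absent.
#' @param min_mapq MAPQ threshold used by the fallback (default 20).
#' @return The unique records, with attribute \code{dropped}: a named count
#'   vector (\code{unmapped}, \code{non_unique}, \code{no_nh}).
#' @export
filter_unique <- function(alignments, assume_unique = FALSE, min_mapq = 20L) {
  mapped <- alignments$mapped
  no_nh <- is.na(alignments$nh)
  if (any(no_nh & mapped) && !assume_unique)
    stop("record without an NH tag: ",
         alignments$read_id[which(no_nh & mapped)[1L]],
         " (use assume_unique to fall back to MAPQ)", call. = FALSE)
  unique_nh <- !no_nh & alignments$nh == 1L
  if (assume_unique)
    unique_nh <- unique_nh | (no_nh & alignments$mapq >= min_mapq)
  keep <- mapped & unique_nh
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(
    unmapped = sum(!mapped),
    non_unique = sum(mapped & !no_nh & alignments$nh != 1L),
    no_nh = sum(mapped & no_nh & !(assume_unique & alignments$mapq >= min_mapq)))
  out
}

#' Recover UMIs from read names and emit UMI-alignment records
#'
#' Expects the preprocess convention of a \code{_UMI:<seq>} suffix on the
#' QNAME. Duplicate read ids (two unique records with one name) are kept with
#' a warning. The coordinate is the leftmost POS for both strands.
#'
#' @param alignments Unique alignment table from [filter_unique()].
#' @return A data.frame of one record per alignment: \code{read_id},
#'   \code{umi}, \code{reference}, \code{strand}, \code{coordinate},
#'   \code{sequence}.
#' @export
umi_alignments <- function(alignments) {
  umi <- umi_from_id(alignments$read_id)
  if (anyNA(umi) && nrow(alignments))
    stop("QNAME without a UMI field: ",
         alignments$read_id[which(is.na(umi))[1L]], call. = FALSE)
  if (anyDuplicated(alignments$read_id))
    warning("duplicate read ids in unique alignments; all records kept")
  out <- data.frame(read_id = alignments$read_id, umi = umi,
                    reference = alignments$reference,
                    strand = alignments$strand,
                    coordinate = alignments$coordinate,
                    sequence = alignments$sequence,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write alignment records as SAM
#'
#' Emits a minimal valid SAM file (one \code{<len>M} match per record,
#' \code{NH:i:1} on every line) from UMI-alignment records; used by the
#' simulator and for round-tripping retained alignments.
#'
#' @param alignments Data.frame with \code{read_id}, \code{reference},
#'   \code{strand}, \code{coordinate}, \code{sequence}.
#' @param ref_lengths Named integer vector of reference sequence lengths
#'   covering every reference used.
#' @param path Output SAM path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  refs <- unique(alignments$reference)
  missing <- setdiff(refs, names(ref_lengths))
  if (length(missing))
    stop("no length for reference ", missing[1L], call. = FALSE)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(ref_lengths),
                  "\tLN:", as.integer(ref_lengths)))
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  lines <- paste(alignments$read_id, flag, alignments$reference,
                 alignments$coordinate, 255L,
                 paste0(nchar(alignments$sequence), "M"),
                 "*", 0L, 0L, alignments$sequence, "*", "NH:i:1",
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
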