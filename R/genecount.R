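# Projection of molecule observations onto gene annotations: BED export,
# interval intersection, and the collapsed/uncollapsed gene count tables.

#' Write single-base observations as BED
#'
#' One line per occupied site in standard 0-based half-open single-base
#' intervals (a 1-based coordinate c becomes \code{c-1\tc}), with the number
#' of observations at the site in column 4, sorted by reference then start.
#' Observations at the same site are summed into one line.
#'
#' @param observations Data.frame with \code{reference}, \code{coordinate}
#'   (1-based) and optionally \code{count} (default 1 per row).
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(observations, path) {
  if (!nrow(observations)) {
    writeLines("# empty observation set", path)
    return(invisible(path))
  }
  count <- observations$count
  if (is.null(count)) count <- rep(1L, nrow(observations))
  key <- paste(observations$reference, observations$coordinate, sep = "\r")
  agg <- tapply(count, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  ref <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  o <- order(ref, pos)
  writeLines(paste(ref[o], pos[o] - 1L, pos[o], as.numeric(agg)[o],
                   sep = "\t"), path)
  invisible(path)
}

#' Load gene features from a GFF3 annotation
#'
#' @param path GFF3 file.
#' @return A [GenomicRanges::GRanges] of features with type \code{"gene"},
#'   with a \code{gene_id} metadata column (the ID attribute).
#' @export
read_gff_genes <- function(path) {
  gff <- rtracklayer::import(path)
  genes <- gff[!is.na(gff$type) & as.character(gff$type) == "gene"]
  if (!length(genes))
    stop("annotation contains no 'gene' features: ", path, call. = FALSE)
  id <- genes$ID
  if (is.null(id)) id <- genes$Name
  if (is.null(id)) id <- paste0("gene", seq_along(genes))
  genes$gene_id <- as.character(id)
  genes
}

#' Sum observation counts over overlapping gene features
#'
#' Each single-base observation contributes its count to every gene feature
#' overlapping it (strand is ignored, as in a plain interval intersection);
#' observations overlapping no gene accumulate in an \code{"unassigned"}
#' bucket. With \code{unique_only}, sites overlapping more than one gene are
#' dropped instead of double-counted.
#'
#' @param observations Data.frame with \code{reference}, \code{coordinate}
#'   (1-based) and optionally \code{count}.
#' @param genes Gene [GenomicRanges::GRanges] from [read_gff_genes()].
#' @param unique_only Drop observations overlapping multiple genes.
#' @return Named numeric vector of summed counts per \code{gene_id}, with
#'   attributes \code{unassigned} (count overlapping no gene) and
#'   \code{multi_gene} (count at sites overlapping more than one gene).
#' @export
intersect_genes <- function(observations, genes, unique_only = FALSE) {
  count <- observations$count
  if (is.null(count)) count <- rep(1L, nrow(observations))
  ids <- unique(genes$gene_id)
  tally <- stats::setNames(numeric(length(ids)), ids)
  if (!nrow(observations)) {
    attr(tally, "unassigned") <- 0
    attr(tally, "multi_gene") <- 0
    return(tally)
  }
  sites <- GenomicRanges::GRanges(
    observations$reference,
    IRanges::IRanges(observations$coordinate, width = 1L))
  ov <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
  hits_per_site <- tabulate(S4Vectors::queryHits(ov), nrow(observations))
  multi <- hits_per_site > 1L
  keep <- if (unique_only) hits_per_site == 1L else hits_per_site >= 1L
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  use <- keep[qh]
  if (any(use)) {
    s <- tapply(count[qh[use]], genes$gene_id[sh[use]], sum)
    tally[names(s)] <- tally[names(s)] + as.numeric(s)
  }
  attr(tally, "unassigned") <- sum(count[hits_per_site == 0L])
  attr(tally, "multi_gene") <- sum(count[multi])
  tally
}

#' Gene-level count table with and without cluster collapsing
#'
#' Builds, per gene: raw read counts (every unique alignment), collapsed UMI
#' counts (one observation per UMI-read cluster, placed at its modal
#' coordinate), uncollapsed UMI counts (one observation per (UMI,
#' coordinate) pair), and the uncollapsed/collapsed ratio — the factor by
#' which the mapping-shift artefact inflates the apparent expression of the
#' gene when clusters are not collapsed. A cluster spanning a gene boundary
#' is assigned by its modal coordinate in collapsed mode, while in
#' uncollapsed mode each coordinate is assigned independently.
#'
#' @param clusters An [umi_clusters()] object.
#' @param genes Gene [GenomicRanges::GRanges] from [read_gff_genes()].
#' @param unique_only Drop observations overlapping multiple genes.
#' @return An object of class \code{"gene_count_table"}: a data.frame with
#'   columns \code{gene_id}, \code{reads}, \code{umis_uncollapsed},
#'   \code{umis_collapsed}, \code{ratio} (\code{NA} where the collapsed
#'   count is zero), plus an \code{unassigned} attribute with the per-mode
#'   unassigned totals.
#' @export
gene_count_table <- function(clusters, genes, unique_only = FALSE) {
  coll <- collapse_clusters(clusters)
  coll$count <- 1L
  uncoll <- uncollapsed_observations(clusters)
  uncoll$count <- 1L
  readobs <- uncoll
  readobs$count <- readobs$reads
  c_coll <- intersect_genes(coll, genes, unique_only)
  c_unc <- intersect_genes(uncoll, genes, unique_only)
  c_reads <- intersect_genes(readobs, genes, unique_only)
  out <- data.frame(gene_id = names(c_coll),
                    reads = as.numeric(c_reads),
                    umis_uncollapsed = as.numeric(c_unc),
                    umis_collapsed = as.numeric(c_coll),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$umis_collapsed > 0,
                      out$umis_uncollapsed / out$umis_collapsed, NA_real_)
  rownames(out) <- NULL
  structure(out, class = c("gene_count_table", "data.frame"),
            unassigned = c(reads = attr(c_reads, "unassigned"),
                           umis_uncollapsed = attr(c_unc, "unassigned"),
                           umis_collapsed = attr(c_coll, "unassigned")),
            multi_gene = c(reads = attr(c_reads, "multi_gene"),
                           umis_uncollapsed = attr(c_unc, "multi_gene"),
                           umis_collapsed = attr(c_coll, "multi_gene")))
}

#' @export
print.gene_count_table <- function(x, ...) {
  cat("Gene count table:", nrow(x), "genes\n")
  r <- x$ratio[!is.na(x$ratio)]
  if (length(r))
    cat(sprintf("  uncollapsed/collapsed ratio: median %.3f, max %.3f; %d gene(s) > 1\n",
                stats::median(r), max(r), sum(r > 1)))
  ua <- attr(x, "unassigned")
  if (!is.null(ua))
    cat("  unassigned observations (collapsed mode):",
        ua[["umis_collapsed"]], "\n")
  print(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more genes\n")
  invisible(x)
}

#' Write a gene count table as TSV
#'
#' @param table A [gene_count_table()] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_counts <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
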