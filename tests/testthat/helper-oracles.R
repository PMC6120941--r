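# Independent oracles and fixture builders used across the suite.

# Levenshtein distance by the classic dynamic program; independent of
# utils::adist, which the implementation wraps.
lev_dp <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
  }
  d[n + 1L, m + 1L]
}

# connected components of the graph joining coordinates within max_gap,
# by brute-force transitive closure over the pairwise-within-gap relation
brute_components <- function(coords, max_gap) {
  n <- length(coords)
  adj <- abs(outer(coords, coords, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        lab <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(coords, comp))
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), character(1))
}

# the bell-shaped five-coordinate worked example: one UMI, counts
# 1/10/796/3/1 centred on Chr03:591516
fig1_alignments <- function(sequence = strrep("ACGT", 9)) {
  counts <- c(1L, 10L, 796L, 3L, 1L)
  coords <- 591514:591518
  data.frame(
    read_id = sprintf("r%04d_UMI:AAAGGAGTGG", seq_len(sum(counts))),
    reference = "Chr03", strand = "+",
    coordinate = rep(coords, counts),
    sequence = sequence, stringsAsFactors = FALSE)
}

fig1_sam <- function(path = tempfile(fileext = ".sam")) {
  write_sam(fig1_alignments(), c(Chr03 = 700000L), path)
  path
}

# minimal read table constructor
reads_df <- function(sequence, quality = strrep("I", nchar(sequence)),
                     id = sprintf("read%d", seq_along(sequence))) {
  data.frame(read_id = id, sequence = sequence, quality = quality,
             umi = NA_character_, stringsAsFactors = FALSE)
}

# hand-rolled SAM writer with full control over FLAG/NH for format tests
raw_sam <- function(lines, path = tempfile(fileext = ".sam"),
                    refs = c(chr1 = 10000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(refs), "\tLN:", refs))
  writeLines(c(hdr, lines), path)
  path
}

sam_line <- function(qname, flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 255L, seq = "ACGTACGTAC", nh = 1L) {
  tag <- if (is.na(nh)) character(0) else paste0("NH:i:", nh)
  paste(c(qname, flag, rname, pos, mapq, paste0(nchar(seq), "M"),
          "*", 0L, 0L, seq, "*", tag), collapse = "\t")
}

# plain GFF3 with gene features given as 1-based inclusive intervals
write_test_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$reference, genes$start, genes$end,
                       genes$gene_id)), path)
  path
}
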