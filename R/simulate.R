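# Synthetic UMI-tagged libraries with a parameterized PCR-stutter model.
# Emits reference FASTA, GFF3 gene annotation, SAM alignments (NH:i:1, UMI
# in QNAME), optional FASTQ, and ground-truth tables, so every pipeline
# stage is testable without external data.

#' Configuration for the PCR-stutter library simulator
#'
#' Defaults describe a desk-scale tagmentation-style library: 50 genes of
#' 500 bp on one chromosome, 20 molecules per gene tagged with 10 bp UMIs,
#' 36 bp reads, 10 PCR cycles. Half of the genes carry a tandem repeat
#' (unit 1-3 bp) in their 5' capture region; on those templates each PCR
#' cycle can shift a copy's effective start by one repeat unit with
#' probability \code{stutter_prob} (a lazy random walk whose net offset
#' produces the bell-shaped mapping-shift pattern). Sequencing substitution
#' errors are applied per base, including inside the UMI, so Levenshtein
#' merging is exercised downstream.
#'
#' @param seed Integer seed; identical seeds give identical libraries.
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp.
#' @param repeat_genes_fraction Fraction of genes whose capture region is a
#'   tandem repeat.
#' @param repeat_unit_sizes Repeat unit sizes sampled for repeat genes.
#' @param molecules_per_gene Tagged molecules per gene.
#' @param umi_length UMI length in bp.
#' @param pcr_cycles Number of PCR cycles.
#' @param stutter_prob Per-cycle probability that a copy of a repeat
#'   template gains or loses one repeat unit (0 for non-repeat templates).
#' @param per_base_error Sequencing substitution rate per base.
#' @param read_length Read length in bp.
#' @param mean_reads_per_molecule Mean sequenced reads per molecule
#'   (1 + Poisson).
#' @param capture_window Width (bp) of the window at the gene 5' end from
#'   which true molecule start coordinates are drawn.
#' @return A \code{"sim_config"} list.
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, gene_length = 500L,
                       repeat_genes_fraction = 0.5,
                       repeat_unit_sizes = 1:3,
                       molecules_per_gene = 20L, umi_length = 10L,
                       pcr_cycles = 10L, stutter_prob = 0.1,
                       per_base_error = 0.001, read_length = 36L,
                       mean_reads_per_molecule = 3,
                       capture_window = 10L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              repeat_genes_fraction = repeat_genes_fraction,
              repeat_unit_sizes = as.integer(repeat_unit_sizes),
              molecules_per_gene = as.integer(molecules_per_gene),
              umi_length = as.integer(umi_length),
              pcr_cycles = as.integer(pcr_cycles),
              stutter_prob = stutter_prob,
              per_base_error = per_base_error,
              read_length = as.integer(read_length),
              mean_reads_per_molecule = mean_reads_per_molecule,
              capture_window = as.integer(capture_window))
  probs <- c(cfg$repeat_genes_fraction, cfg$stutter_prob, cfg$per_base_error)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$pcr_cycles < 0L) stop("pcr_cycles must be >= 0", call. = FALSE)
  max_walk <- cfg$pcr_cycles * max(cfg$repeat_unit_sizes)
  if (cfg$read_length + cfg$capture_window + 2L * max_walk >= cfg$gene_length)
    stop("read_length + capture_window + maximal stutter walk must fit ",
         "inside gene_length", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a UMI-tagged library with PCR-stutter mapping shifts
#'
#' Builds a random reference chromosome with evenly spaced genes, tags
#' molecules with random UMIs, amplifies them through a per-cycle stutter
#' random walk on repeat templates, applies per-base sequencing error, and
#' emits perfectly mapped alignments (the pipeline consumes alignments;
#' stutter is modelled as offset bookkeeping at the mapped-start level).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created). Files written: \code{ref.fasta},
#'   \code{genes.gff3}, \code{reads.sam}, \code{truth_genes.tsv},
#'   \code{truth_reads.tsv}, \code{config.json}, and \code{reads.fastq}
#'   when \code{fastq = TRUE}.
#' @param fastq Also emit an inline-5prime FASTQ (UMI + GGGG motif +
#'   biological sequence, qualities uniform Q40) for end-to-end tests.
#' @return Invisibly, a list with \code{dir}, file paths, the per-gene
#'   truth (\code{gene_id}, \code{start}, \code{end}, \code{is_repeat},
#'   \code{repeat_unit}, \code{true_molecules}) and per-read provenance
#'   (\code{read_id}, \code{gene_id}, \code{molecule_id}, \code{true_umi},
#'   \code{observed_umi}, \code{true_start}, \code{stutter_offset}).
#' @export
simulate_library <- function(config = sim_config(), dir = tempfile("umisim"),
                             fastq = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  bases <- c("A", "C", "G", "T")
  spacer <- 100L
  gene_start <- spacer + (seq_len(config$n_genes) - 1L) *
    (config$gene_length + spacer) + 1L
  gene_end <- gene_start + config$gene_length - 1L
  chrom_len <- config$n_genes * (config$gene_length + spacer) + spacer
  ref <- sample(bases, chrom_len, replace = TRUE)

  n_rep <- round(config$n_genes * config$repeat_genes_fraction)
  is_repeat <- seq_len(config$n_genes) <= n_rep
  units <- config$repeat_unit_sizes
  repeat_unit <- ifelse(is_repeat,
                        units[sample.int(length(units), config$n_genes,
                                         replace = TRUE)], NA_integer_)
  # overwrite the capture region of repeat genes with a tandem repeat;
  # wide enough to cover every read a maximal stutter walk can produce
  max_walk <- config$pcr_cycles * max(config$repeat_unit_sizes)
  capture_len <- config$capture_window + config$read_length + 2L * max_walk
  for (g in which(is_repeat)) {
    unit <- sample(bases, repeat_unit[g], replace = TRUE)
    reg <- gene_start[g]:(gene_start[g] + capture_len - 1L)
    ref[reg] <- rep_len(unit, length(reg))
  }

  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
                      start = gene_start, end = gene_end,
                      is_repeat = is_repeat, repeat_unit = repeat_unit,
                      true_molecules = config$molecules_per_gene,
                      stringsAsFactors = FALSE)

  # molecules: UMI drawn uniformly, true start within the capture window
  n_mol <- config$n_genes * config$molecules_per_gene
  mol_gene <- rep(seq_len(config$n_genes), each = config$molecules_per_gene)
  mol_umi <- vapply(seq_len(n_mol), function(i)
    paste(sample(bases, config$umi_length, replace = TRUE), collapse = ""),
    character(1))
  # offset by the maximal walk so stuttered starts never leave the gene
  mol_start <- gene_start[mol_gene] + max_walk +
    sample.int(config$capture_window, n_mol, replace = TRUE) - 1L

  # reads per molecule, stutter random walk per read lineage
  n_reads_mol <- 1L + stats::rpois(n_mol, config$mean_reads_per_molecule - 1)
  read_mol <- rep(seq_len(n_mol), n_reads_mol)
  n_reads <- length(read_mol)
  unit_of_read <- repeat_unit[mol_gene[read_mol]]
  stutter_events <- stats::rbinom(n_reads, config$pcr_cycles,
                                  ifelse(is.na(unit_of_read), 0,
                                         config$stutter_prob))
  net_steps <- vapply(stutter_events, function(k)
    if (k == 0L) 0L else sum(sample(c(-1L, 1L), k, replace = TRUE)),
    integer(1))
  offset <- ifelse(is.na(unit_of_read), 0L, net_steps * unit_of_read)
  pos <- mol_start[read_mol] + offset

  # sequences from the reference, then per-base substitution error
  seqs <- vapply(pos, function(p)
    paste(ref[p:(p + config$read_length - 1L)], collapse = ""),
    character(1))
  seqs <- add_base_errors(seqs, config$per_base_error, bases)
  obs_umi <- add_base_errors(mol_umi[read_mol], config$per_base_error, bases)

  provenance <- data.frame(
    read_id = sprintf("read%06d_UMI:%s", seq_len(n_reads), obs_umi),
    gene_id = genes$gene_id[mol_gene[read_mol]],
    molecule_id = read_mol,
    true_umi = mol_umi[read_mol],
    observed_umi = obs_umi,
    true_start = mol_start[read_mol],
    stutter_offset = offset,
    stringsAsFactors = FALSE)

  paths <- list(
    ref = file.path(dir, "ref.fasta"),
    gff = file.path(dir, "genes.gff3"),
    sam = file.path(dir, "reads.sam"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_reads = file.path(dir, "truth_reads.tsv"),
    config = file.path(dir, "config.json"))

  refset <- Biostrings::DNAStringSet(paste(ref, collapse = ""))
  names(refset) <- "chr1"
  Biostrings::writeXStringSet(refset, paths$ref)
  writeLines(c("##gff-version 3",
               sprintf("chr1\tumishift\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$start, genes$end, genes$gene_id)), paths$gff)
  aln <- data.frame(read_id = provenance$read_id, reference = "chr1",
                    strand = "+", coordinate = pos, sequence = seqs,
                    stringsAsFactors = FALSE)
  write_sam(aln, c(chr1 = chrom_len), paths$sam)
  utils::write.table(genes, paths$truth_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(provenance, paths$truth_reads, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE)

  if (fastq) {
    paths$fastq <- file.path(dir, "reads.fastq")
    raw_id <- sub("_UMI:.*$", "", provenance$read_id)
    full <- paste0(obs_umi, "GGGG", seqs)
    writeLines(rbind(paste0("@", raw_id), full, "+",
                     strrep("I", nchar(full))), paths$fastq)
  }

  invisible(list(dir = dir, paths = paths, genes = genes,
                 provenance = provenance, config = config))
}

add_base_errors <- function(seqs, rate, bases) {
  if (rate <= 0) return(seqs)
  n <- nchar(seqs)
  hit <- which(stats::rbinom(length(seqs), n, rate) > 0L)
  for (i in hit) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    j <- which(stats::runif(length(b)) < rate)
    if (!length(j)) j <- sample.int(length(b), 1L)
    for (k in j) b[k] <- sample(setdiff(bases, b[k]), 1L)
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

#' Compare a pipeline gene table with simulation ground truth
#'
#' Reports the per-gene absolute error of collapsed UMI counts against the
#' number of simulated molecules, flagging genes where exact recovery is
#' not expected from the truth alone: UMI collisions (two molecules of a
#' gene drew true UMIs within Levenshtein distance 2 of each other, so
#' observed tags can merge or co-cluster) and risky UMI sequencing errors
#' (an observed UMI differing from its molecule's true UMI in a way the
#' per-coordinate Levenshtein merge cannot provably absorb: distance > 1
#' from the true UMI, or no same-molecule reads carrying the true UMI with
#' a strictly larger count at the same coordinate) and stutter escapes (a
#' molecule whose realized mapping coordinates contain an adjacent gap
#' larger than \code{max_gap}, so gap-limited chaining cannot reunite them
#' — under-collapse that is reported rather than hidden). Genes free of all
#' three are the "clean stratum", in which collapsed counts must equal
#' truth exactly.
#'
#' @param gene_table A [gene_count_table()] computed on the simulator's SAM
#'   and GFF3 output.
#' @param truth The list returned by [simulate_library()] (or its
#'   \code{genes}/\code{provenance} components re-read from disk).
#' @param max_gap The gap threshold the pipeline was run with (default 3).
#' @return List with \code{per_gene} (gene_id, true_molecules, collapsed,
#'   uncollapsed, abs_error, umi_collision, umi_error_risk,
#'   stutter_escape, clean), \code{exact_match_rate} overall,
#'   \code{clean_exact_match_rate} within the clean stratum, and
#'   \code{error_histogram}.
#' @export
truth_compare <- function(gene_table, truth, max_gap = 3L) {
  genes <- truth$genes
  prov <- truth$provenance
  m <- match(genes$gene_id, gene_table$gene_id)
  if (anyNA(m))
    stop("gene table is missing simulated gene(s): ",
         genes$gene_id[which(is.na(m))[1L]], call. = FALSE)
  collapsed <- gene_table$umis_collapsed[m]
  uncollapsed <- gene_table$umis_uncollapsed[m]

  collision <- vapply(split(prov, prov$gene_id), function(p) {
    u <- unique(p[!duplicated(p$molecule_id), c("molecule_id", "true_umi")])
    if (nrow(u) < 2L) return(FALSE)
    d <- utils::adist(u$true_umi)
    any(d[upper.tri(d)] <= 2L)
  }, logical(1))[genes$gene_id]

  err_risk <- vapply(split(prov, prov$gene_id), function(p) {
    bad <- p$observed_umi != p$true_umi
    if (!any(bad)) return(FALSE)
    for (i in which(bad)) {
      if (utils::adist(p$observed_umi[i], p$true_umi[i])[1L, 1L] > 1L)
        return(TRUE)
      same_site <- p$molecule_id == p$molecule_id[i] &
        (p$true_start + p$stutter_offset) ==
        (p$true_start[i] + p$stutter_offset[i]) &
        p$observed_umi == p$true_umi[i]
      n_err_here <- sum(p$molecule_id == p$molecule_id[i] &
                          (p$true_start + p$stutter_offset) ==
                          (p$true_start[i] + p$stutter_offset[i]) &
                          p$observed_umi == p$observed_umi[i])
      if (sum(same_site) <= n_err_here) return(TRUE)
    }
    FALSE
  }, logical(1))[genes$gene_id]

  escape <- vapply(split(prov, prov$gene_id), function(p) {
    any(vapply(split(p$true_start + p$stutter_offset, p$molecule_id),
               function(sites) {
                 s <- sort(unique(sites))
                 length(s) > 1L && any(diff(s) > max_gap)
               }, logical(1)))
  }, logical(1))[genes$gene_id]

  per_gene <- data.frame(gene_id = genes$gene_id,
                         true_molecules = genes$true_molecules,
                         collapsed = collapsed,
                         uncollapsed = uncollapsed,
                         abs_error = abs(collapsed - genes$true_molecules),
                         umi_collision = as.vector(collision),
                         umi_error_risk = as.vector(err_risk),
                         stutter_escape = as.vector(escape),
                         stringsAsFactors = FALSE)
  per_gene$clean <- !per_gene$umi_collision & !per_gene$umi_error_risk &
    !per_gene$stutter_escape
  list(per_gene = per_gene,
       exact_match_rate = mean(per_gene$abs_error == 0),
       clean_exact_match_rate =
         if (any(per_gene$clean)) mean(per_gene$abs_error[per_gene$clean] == 0)
         else NA_real_,
       error_histogram = table(per_gene$abs_error))
}
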