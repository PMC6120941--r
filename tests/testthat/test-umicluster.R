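# Per-coordinate Levenshtein merging, gap-limited coordinate chaining,
# collapsing, and shift/cluster statistics.

test_that("levenshtein agrees with an independent dynamic program", {
  expect_identical(levenshtein("AAAGGAGTGG", "AAAGGAGTGG"), 0L)
  expect_identical(levenshtein("AAAGGAGTGG", "AAAGGAGTGC"), 1L)
  expect_identical(levenshtein("AAA", "AGAA"), 1L)
  set.seed(101)
  a <- random_dna(60, 10)
  b <- c(random_dna(30, 10), random_dna(30, 8))
  got <- levenshtein(a, b)
  want <- mapply(lev_dp, a, b, USE.NAMES = FALSE)
  expect_identical(got, as.integer(want))
  expect_identical(levenshtein(b, a), got)  # symmetry
})

test_that("per-position UMI merging is greedy by abundance", {
  m <- merge_umis_at_position(c(AAAA = 10, AAAT = 2, CCCC = 5))
  grp <- tapply(m$count, m$representative, sum)
  expect_identical(sort(names(grp)), c("AAAA", "CCCC"))
  expect_equal(as.numeric(grp[c("AAAA", "CCCC")]), c(12, 5))
})

test_that("non-transitive distance-1 relation is resolved deterministically", {
  # AATT is distance 1 from AAAT but 2 from the representative AAAA,
  # so it must found its own group
  m <- merge_umis_at_position(c(AAAA = 5, AAAT = 5, AATT = 1))
  expect_identical(m$representative[m$umi == "AAAT"], "AAAA")
  expect_identical(m$representative[m$umi == "AATT"], "AATT")
  # the stated visit order makes the result independent of input order
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(3, 1, 2))
  base <- c(AAAA = 5, AAAT = 5, AATT = 1)
  for (p in perms) {
    m2 <- merge_umis_at_position(base[p])
    m2 <- m2[order(m2$umi), ]
    expect_identical(m2$representative, c("AAAA", "AAAA", "AATT"))
  }
})

test_that("merging handles singletons, empties, and N as a literal character", {
  one <- merge_umis_at_position(c(ACGT = 3))
  expect_identical(one$representative, "ACGT")
  expect_equal(nrow(merge_umis_at_position(numeric(0))), 0L)
  # N differs from every base, so ACGN is within 1 of ACGT
  m <- merge_umis_at_position(c(ACGT = 5, ACGN = 1))
  expect_identical(unique(m$representative), "ACGT")
})

test_that("gap chaining reproduces the worked five-coordinate cluster", {
  cl <- find_clusters(591514:591518, c(1, 10, 796, 3, 1), max_gap = 3)
  expect_length(cl, 1L)
  expect_identical(cl[[1L]]$size, 5L)
  expect_equal(cl[[1L]]$total_reads, 811)
  expect_identical(cl[[1L]]$mode, 591516L)
})

test_that("gaps beyond the threshold split clusters; chaining is single-linkage", {
  two <- find_clusters(c(100L, 110L), c(1, 1), max_gap = 3)
  expect_length(two, 2L)
  expect_identical(vapply(two, `[[`, integer(1), "size"), c(1L, 1L))
  # chain spans 6 bp in total although each gap is 3
  one <- find_clusters(c(100L, 103L, 106L), c(1, 1, 1), max_gap = 3)
  expect_length(one, 1L)
  expect_identical(one[[1L]]$size, 3L)
  expect_error(find_clusters(c(5L, 3L), c(1, 1)), "increasing")
})

test_that("chaining matches brute-force connected components on random instances", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(1:40, 1)
    coords <- sort(sample(1:200, n))
    counts <- sample(1:50, n, replace = TRUE)
    gap <- sample(0:5, 1)
    got <- find_clusters(coords, counts, max_gap = gap)
    want <- brute_components(coords, gap)
    expect_identical(lapply(got, `[[`, "coordinates"), unname(want))
  }
})

test_that("raising max_gap never increases the cluster count", {
  set.seed(303)
  for (i in 1:20) {
    coords <- sort(sample(1:300, sample(5:60, 1)))
    counts <- rep(1, length(coords))
    sizes <- vapply(0:6, function(g)
      length(find_clusters(coords, counts, max_gap = g)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("strict-shift classification follows adjacent spacings", {
  expect_identical(classify_strict_shift(591514:591518), "1")
  expect_identical(classify_strict_shift(c(100L, 102L, 104L)), "2")
  expect_identical(classify_strict_shift(c(100L, 101L, 103L)), "mixed")
  expect_identical(classify_strict_shift(100L), "none")
})

test_that("collapsing places one observation at the mode, leftmost on ties", {
  cl <- umi_clusters(fig1_alignments(), max_gap = 3)
  obs <- collapse_clusters(cl)
  expect_equal(nrow(obs), 1L)
  expect_identical(obs$coordinate, 591516L)
  expect_equal(obs$total_reads, 811)
  # symmetric counts: the tie at 200/203 resolves to the leftmost
  tie <- data.frame(read_id = sprintf("t%d_UMI:AAAAAAAAAA", 1:4),
                    reference = "chr1", strand = "+",
                    coordinate = c(200L, 200L, 203L, 203L),
                    sequence = "ACGT", stringsAsFactors = FALSE)
  tc <- umi_clusters(tie, max_gap = 3)
  expect_identical(collapse_clusters(tc)$coordinate, 200L)
})

test_that("pooled shift distribution centres the mode and normalizes to 1", {
  cl <- umi_clusters(fig1_alignments(), max_gap = 3)
  d <- shift_distribution(cl)
  expect_equal(d$density[d$offset == 0], 796 / 811)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)
  expect_identical(d$offset[which.max(d$reads)], 0L)
  # hand-pooled: clusters {0:+5} and {0:+5, +1:+5}
  two <- data.frame(
    read_id = sprintf("p%02d_UMI:%s", 1:15,
                      rep(c("AAAAAAAAAA", "CCCCCCCCCC"), c(5, 10))),
    reference = "chr1", strand = "+",
    coordinate = c(rep(300L, 5), rep(400L, 5), rep(401L, 5)),
    sequence = "ACGT", stringsAsFactors = FALSE)
  d2 <- shift_distribution(umi_clusters(two, max_gap = 3))
  expect_equal(d2$reads, c(10, 5))
  expect_equal(d2$density, c(2 / 3, 1 / 3))
  # all clusters of size 1
  solo <- two[c(1, 6), ]
  d1 <- shift_distribution(umi_clusters(solo, max_gap = 3))
  expect_identical(d1$offset, 0L)
  expect_equal(d1$density, 1)
  # empty restriction is reported as empty, density undefined
  empty <- shift_distribution(umi_clusters(solo, max_gap = 3), strict_n = 2)
  expect_equal(nrow(empty), 0L)
})

test_that("size summaries report proportions of clusters and of reads", {
  # 3 clusters of sizes {1,1,2} holding {4,4,12} reads
  aln <- data.frame(
    read_id = sprintf("s%02d_UMI:%s", 1:20,
                      rep(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
                          c(4, 4, 12))),
    reference = "chr1", strand = "+",
    coordinate = c(rep(100L, 4), rep(500L, 4), rep(900L, 8), rep(901L, 4)),
    sequence = "ACGT", stringsAsFactors = FALSE)
  s <- summary(umi_clusters(aln, max_gap = 3))
  expect_equal(s$clusters_by_size$proportion, c(2 / 3, 1 / 3))
  expect_equal(s$reads_by_size$proportion, c(8 / 20, 12 / 20))
  expect_equal(sum(s$reads_by_size$reads), 20)
  expect_identical(s$max_size, 2L)
})

test_that("strand separation and the strand-blind mode behave as keyed", {
  # same UMI string on + and -: distinct molecules by default
  aln <- data.frame(read_id = sprintf("x%d_UMI:ACGTACGTAC", 1:2),
                    reference = "chr1", strand = c("+", "-"),
                    coordinate = c(100L, 101L),
                    sequence = "ACGT", stringsAsFactors = FALSE)
  expect_equal(nrow(umi_clusters(aln, max_gap = 3)), 2L)
  expect_equal(nrow(umi_clusters(aln, max_gap = 3, ignore_strand = TRUE)),
               1L)
})

test_that("cluster totals conserve the input alignments", {
  set.seed(404)
  sim <- simulate_library(sim_config(seed = 17, stutter_prob = 0.2))
  ua <- umi_alignments(filter_unique(read_alignments(sim$paths$sam)))
  cl <- umi_clusters(ua, max_gap = 3)
  expect_equal(sum(cl$total_reads), nrow(ua))
  expect_equal(nrow(collapse_clusters(cl)), nrow(cl))
  # collapsed count per key never exceeds the uncollapsed count
  expect_true(nrow(collapse_clusters(cl)) <=
                nrow(uncollapsed_observations(cl)))
})

test_that("max_gap 0 degenerates to per-coordinate UMI counting", {
  set.seed(505)
  sim <- simulate_library(sim_config(seed = 23, stutter_prob = 0.2))
  ua <- umi_alignments(filter_unique(read_alignments(sim$paths$sam)))
  cl0 <- umi_clusters(ua, max_gap = 0)
  expect_true(all(cl0$size == 1L))
  # collapsing changes nothing: one observation per (UMI, coordinate)
  expect_identical(nrow(collapse_clusters(cl0)),
                   nrow(uncollapsed_observations(cl0)))
  per_coord <- unique(paste(ua$reference, ua$strand, ua$coordinate))
  expect_true(nrow(cl0) >= length(per_coord))
})

test_that("erroneous UMIs at a coordinate are absorbed into the abundant tag", {
  aln <- data.frame(
    read_id = c(sprintf("m%d_UMI:AAAGGAGTGG", 1:5), "e1_UMI:AAAGGAGTGC"),
    reference = "chr1", strand = "+",
    coordinate = c(rep(100L, 5), 100L),
    sequence = "ACGT", stringsAsFactors = FALSE)
  cl <- umi_clusters(aln, max_gap = 3)
  expect_equal(nrow(cl), 1L)
  expect_identical(cl$umi, "AAAGGAGTGG")
  expect_equal(cl$total_reads, 6)
})
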