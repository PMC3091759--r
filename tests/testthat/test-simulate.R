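test_that("genome simulation is deterministic and ledger-complete", {
  f <- feature_request(n_ssrs = 10, n_repeats = 5, n_genes = 3)
  g1 <- simulate_genome(2, 20000, f, seed = 101)
  g2 <- simulate_genome(2, 20000, f, seed = 101)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$ledger$ssrs, g2$ledger$ssrs)
  g3 <- simulate_genome(2, 20000, f, seed = 102)
  expect_false(identical(g1$sequences, g3$sequences))

  expect_equal(nrow(g1$ledger$ssrs), 10L)
  expect_equal(nrow(g1$ledger$repeats), 5L)
  expect_equal(nrow(g1$ledger$genes), 3L)
  # every ledger span lies inside its pseudomolecule
  for (tab in list(g1$ledger$ssrs, g1$ledger$repeats, g1$ledger$genes)) {
    len <- setNames(nchar(g1$sequences$sequence), g1$sequences$id)
    expect_true(all(tab$start >= 0 & tab$end <= len[tab$seq_id]))
  }

  empty <- simulate_genome(1, 5000, feature_request(), seed = 103)
  expect_equal(nrow(empty$ledger$ssrs), 0L)
  expect_equal(nrow(scan_ssrs(empty$sequences)), 0L)
})

test_that("scanning a noise-free genome recovers exactly the planted SSRs", {
  for (seed in 104:106) {
    g <- simulate_genome(1, 30000, feature_request(n_ssrs = 20), seed = seed)
    found <- scan_ssrs(g$sequences)
    expect_identical(ssr_key(found), ssr_key(g$ledger$ssrs))
    expect_identical(found$canonical_motif, g$ledger$ssrs$canonical_motif)
  }
})

test_that("background GC tracks the requested content", {
  g <- simulate_genome(1, 200000, feature_request(), seed = 107)
  expect_equal(gc_content(g$sequences, digits = Inf), 35.2, tolerance = 0.02)
})

test_that("library simulation honours clone counts and read geometry", {
  g <- simulate_genome(1, 80000, feature_request(), seed = 108)
  lib <- simulate_library(
    g, library_spec(n_clones = 40, mean_insert = 10000, insert_sd = 800,
                    empty_fraction = 0.2, seed = 109), "SYN")
  expect_equal(nrow(lib), round(40 * 0.8))
  reads <- library_reads(lib)
  expect_equal(nrow(reads), 2L * nrow(lib))
  expect_true(all(nchar(reads$sequence) >= 50 & nchar(reads$sequence) <= 879))
  # reads are substrings of the genome, reverse reads as reverse complement
  for (i in seq_len(nrow(reads))) {
    chrom <- g$sequences$sequence[g$sequences$id == reads$src_chrom[i]]
    sub <- substr(chrom, reads$src_start[i] + 1, reads$src_end[i])
    if (reads$src_strand[i] == "-") sub <- revcomp(sub)
    expect_identical(sub, reads$sequence[i])
  }
  # pairing the flattened reads by id recovers the clones
  paired <- pair_bes(reads)
  expect_equal(nrow(paired$pairs), nrow(lib))
  expect_equal(nrow(paired$unpaired), 0L)
})

test_that("mean read length approaches the survey mean at scale", {
  g <- simulate_genome(1, 100000, feature_request(), seed = 110)
  lib <- simulate_library(
    g, library_spec(n_clones = 5000, mean_insert = 5000, insert_sd = 300,
                    seed = 111))
  reads <- library_reads(lib)
  expect_equal(mean(nchar(reads$sequence)), 543, tolerance = 0.02)
})

test_that("restriction libraries only cut at ledger sites", {
  set.seed(112)
  # a genome whose BamHI sites all sit in the left half
  raw <- gsub("GGATCC", "GGATCA", rand_dna(60000))
  ch <- strsplit(raw, "")[[1]]
  site_pos <- seq(1000, 28000, by = 1500)
  for (p in site_pos) ch[p:(p + 5)] <- c("G", "G", "A", "T", "C", "C")
  g <- structure(list(
    sequences = data.frame(id = "chr1", sequence = paste(ch, collapse = ""),
                           stringsAsFactors = FALSE),
    ledger = list(ssrs = NULL, repeats = NULL, genes = NULL,
                  restriction_sites = list(chr1 = site_pos - 1L)),
    params = list(gc = 0.35)), class = "genome_model")
  lib <- simulate_library(
    g, library_spec(n_clones = 30, mean_insert = 6000, insert_sd = 500,
                    method = "restriction", seed = 113))
  expect_true(all(lib$insert_start %in% (site_pos - 1L)))
  expect_true(all(lib$insert_end %in% (site_pos - 1L)))
  expect_true(all(lib$insert_end < 30000))       # coverage bias: left half only

  no_sites <- g
  no_sites$ledger$restriction_sites <- list(chr1 = integer(0))
  expect_error(simulate_library(no_sites, library_spec(
    n_clones = 5, mean_insert = 6000, method = "restriction", seed = 1)),
    "restriction")
})

test_that("related genomes copy blocks with the requested geometry", {
  g <- simulate_genome(1, 400000, feature_request(), seed = 114)
  spec <- synteny_spec(n_blocks = 2, block_len = c(50000, 60000),
                      multiplicity = 1, inversion_prob = 0, divergence = 0,
                      src_gap = 80000, seed = 115)
  rel <- simulate_related_genome(g, spec)
  expect_equal(nrow(rel$blocks), 2L)
  for (i in seq_len(nrow(rel$blocks))) {
    b <- rel$blocks[i, ]
    src <- substr(g$sequences$sequence, b$src_start + 1, b$src_end)
    tgt <- substr(rel$genome$sequences$sequence[
      rel$genome$sequences$id == b$tgt_chrom], b$tgt_start + 1, b$tgt_end)
    expect_identical(tgt, src)                   # no inversion, no divergence
  }

  dup <- simulate_related_genome(
    g, synteny_spec(n_blocks = 2, block_len = c(50000, 60000),
                    multiplicity = 2, src_gap = 80000, seed = 116))
  expect_equal(nrow(dup$genome$sequences), 2L)
  expect_equal(mean(table(dup$blocks$block_id)), 2.0)

  inv <- simulate_related_genome(
    g, synteny_spec(n_blocks = 2, block_len = c(50000, 60000),
                    inversion_prob = 1, src_gap = 80000, seed = 117))
  expect_true(all(inv$blocks$orientation == "inverted"))
  b <- inv$blocks[1, ]
  src <- substr(g$sequences$sequence, b$src_start + 1, b$src_end)
  tgt <- substr(inv$genome$sequences$sequence[
    inv$genome$sequences$id == b$tgt_chrom], b$tgt_start + 1, b$tgt_end)
  expect_identical(tgt, revcomp(src))
})

test_that("projected hits land reads exactly on their block copies", {
  g <- simulate_genome(1, 400000, feature_request(), seed = 118)
  rel <- simulate_related_genome(
    g, synteny_spec(n_blocks = 2, block_len = c(80000, 100000),
                    multiplicity = 1, inversion_prob = 0.5, divergence = 0,
                    src_gap = 80000, seed = 119))
  lib <- simulate_library(g, library_spec(n_clones = 40, mean_insert = 20000,
                                          insert_sd = 1000, seed = 120))
  reads <- library_reads(lib)
  hits <- project_read_hits(reads, rel$blocks)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    r <- reads[reads$id == h$query_id, ]
    tgt <- substr(rel$genome$sequences$sequence[
      rel$genome$sequences$id == h$subject_id], h$s_start + 1, h$s_end)
    # a plus-strand hit means the read matches the span as-is, a minus-strand
    # hit means it matches the reverse complement of the span
    want <- if (h$strand == "+") r$sequence else revcomp(r$sequence)
    expect_identical(tgt, want)
  }
})
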