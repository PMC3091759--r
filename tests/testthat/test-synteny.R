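syn_hit <- function(q, s, start, strand, e = 1e-40) {
  data.frame(query_id = q, subject_id = s, pident = 98, aln_len = 500L,
             mismatches = 0L, gap_opens = 0L, q_start = 0L, q_end = 500L,
             s_start = as.integer(start), s_end = as.integer(start + 500),
             strand = strand, evalue = e, bitscore = 900,
             stringsAsFactors = FALSE)
}

test_that("loci are the same-subject Cartesian product of merged anchors", {
  one <- loci_for_pair(syn_hit("f", "chrA", 1e5, "+"),
                       syn_hit("r", "chrA", 3e5, "-"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$separation, 2e5)
  expect_true(one$orientation_ok)

  two <- loci_for_pair(rbind(syn_hit("f", "chrA", 1e5, "+"),
                             syn_hit("f", "chrA", 8e5, "+")),
                       syn_hit("r", "chrA", 3e5, "-"))
  expect_equal(nrow(two), 2L)

  none <- loci_for_pair(syn_hit("f", "chrA", 1e5, "+"),
                        syn_hit("r", "chrB", 3e5, "-"))
  expect_equal(nrow(none), 0L)
})

test_that("anchor merging collapses nearby same-strand hits only", {
  near <- rbind(syn_hit("f", "chrA", 1e5, "+", e = 1e-60),
                syn_hit("f", "chrA", 1e5 + 5000, "+", e = 1e-30))
  l <- loci_for_pair(near, syn_hit("r", "chrA", 3e5, "-"))
  expect_equal(nrow(l), 1L)                       # merged into one anchor
  expect_equal(l$mid1, 1e5 + 250)                 # best-E representative

  opp <- rbind(syn_hit("f", "chrA", 1e5, "+"),
               syn_hit("f", "chrA", 1e5 + 5000, "-"))
  l2 <- loci_for_pair(opp, syn_hit("r", "chrA", 3e5, "-"))
  expect_equal(nrow(l2), 2L)                      # strands never merge
})

test_that("collinearity verdicts respect the inclusive window and orientation", {
  mk_locus <- function(sep, s1 = "+", s2 = "-") {
    loci_for_pair(syn_hit("f", "chrA", 1e5, s1),
                  syn_hit("r", "chrA", 1e5 + sep, s2))
  }
  expect_equal(classify_collinear(mk_locus(2e5)), "COLLINEAR")
  expect_equal(classify_collinear(mk_locus(6e5)), "FAIL_WINDOW")
  expect_equal(classify_collinear(mk_locus(49999)), "FAIL_WINDOW")
  expect_equal(classify_collinear(mk_locus(50000)), "COLLINEAR")
  expect_equal(classify_collinear(mk_locus(500000)), "COLLINEAR")

  same_strand <- mk_locus(2e5, "+", "+")
  expect_equal(classify_collinear(same_strand), "FAIL_ORIENTATION")
  expect_equal(classify_collinear(same_strand, require_orientation = FALSE),
               "COLLINEAR")

  # divergent (facing outward) placements fail even on opposite strands
  divergent <- loci_for_pair(syn_hit("f", "chrA", 1e5, "-"),
                             syn_hit("r", "chrA", 3e5, "+"))
  expect_false(divergent$orientation_ok)
  expect_equal(classify_collinear(divergent), "FAIL_ORIENTATION")
})

test_that("funnel counts are monotone and relaxation only adds pairs", {
  set.seed(701)
  for (i in 1:12) {
    inp <- random_synteny_input(30)
    s <- synteny_summary(inp$pairs, inp$hits)
    expect_gte(s$n_pairs_both_ends_hit, s$n_pairs_same_subject)
    expect_gte(s$n_pairs_same_subject, s$n_pairs_in_window)
    expect_gte(s$n_pairs_in_window, s$n_pairs_collinear)
    relaxed <- synteny_summary(inp$pairs, inp$hits,
                               synteny_params(require_orientation = FALSE))
    expect_gte(relaxed$n_pairs_collinear, s$n_pairs_collinear)
    expect_equal(relaxed$n_pairs_in_window, s$n_pairs_in_window)
  }
})

test_that("relaxed minus strict collinearity estimates the disruption rate", {
  set.seed(702)
  n <- 600
  p <- 0.3
  flipped <- runif(n) < p
  rows <- lapply(seq_len(n), function(i) {
    sep <- runif(1, 6e4, 4e5)
    s2 <- if (flipped[i]) "+" else "-"
    loci_for_pair(syn_hit(sprintf("f%d", i), "chrA", 1e5, "+"),
                  syn_hit(sprintf("r%d", i), "chrA", 1e5 + sep, s2),
                  pair_id = sprintf("c%d", i))
  })
  loci <- do.call(rbind, rows)
  strict <- sum(classify_collinear(loci) == "COLLINEAR")
  relaxed <- sum(classify_collinear(loci, require_orientation = FALSE) ==
                 "COLLINEAR")
  est <- (relaxed - strict) / relaxed
  expect_equal(est, p, tolerance = 0.2)          # binomial error at n = 600
})

test_that("an all-zero summary comes back for hitless input", {
  pairs <- data.frame(clone_id = "c1", forward_id = "c1.f",
                      reverse_id = "c1.r", stringsAsFactors = FALSE)
  s <- synteny_summary(pairs, syn_hit("other", "chrA", 1, "+")[0, ])
  expect_equal(s$n_bes_with_hits, 0L)
  expect_equal(s$n_loci, 0L)
  expect_equal(s$n_pairs_collinear, 0L)
  expect_true(is.na(s$mean_loci_per_pair))
})

test_that("planted collinear blocks are recovered perfectly without noise", {
  g <- simulate_genome(2, 450000, feature_request(), seed = 31)
  rel <- simulate_related_genome(
    g, synteny_spec(n_blocks = 2, block_len = c(90000, 110000),
                    multiplicity = 1, inversion_prob = 0, divergence = 0,
                    seed = 32))
  lib <- simulate_library(
    g, library_spec(n_clones = 50, mean_insert = 60000, insert_sd = 2000,
                    seed = 33))
  reads <- library_reads(lib)
  hits <- project_read_hits(reads, rel$blocks)
  s <- synteny_summary(lib[, c("clone_id", "forward_id", "reverse_id")], hits)

  in_block <- vapply(seq_len(nrow(lib)), function(i) {
    any(rel$blocks$src_chrom == lib$chrom[i] &
        rel$blocks$src_start <= lib$insert_start[i] &
        rel$blocks$src_end >= lib$insert_end[i])
  }, logical(1))
  truth <- lib$clone_id[in_block]
  called <- unique(s$loci$pair_id[s$loci$verdict == "COLLINEAR"])
  # precision = recall = 1 against the planted blocks
  expect_setequal(called, truth)
  expect_gt(length(truth), 0)
})
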