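test_that("overlap acceptance sits exactly on the survey thresholds", {
  set.seed(501)
  tpl <- rand_dna(1000)
  a <- substr(tpl, 1, 500)

  same <- overlap_align(a, a)
  expect_true(same$accepted)
  expect_equal(same$overlap_length, 500L)
  expect_equal(same$identity, 100)

  b80 <- substr(tpl, 421, 900)
  r80 <- overlap_align(a, b80)
  expect_true(r80$accepted)
  expect_equal(r80$overlap_length, 80L)

  b79 <- substr(tpl, 422, 900)
  expect_false(overlap_align(a, b79)$accepted)

  # 100-bp overlap with 6 mismatches is 94% identity: rejected; 5 passes
  mm <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- seq(5, by = 15, length.out = k)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  ov <- substr(tpl, 401, 500)
  tail6 <- paste0(mm(ov, 6), rand_dna(200))
  expect_false(overlap_align(a, tail6)$accepted)
  tail5 <- paste0(mm(ov, 5), rand_dna(200))
  r5 <- overlap_align(a, tail5)
  expect_true(r5$accepted)
  expect_true(r5$identity >= 95)

  # reverse-complement orientation is detected
  rc <- overlap_align(a, revcomp(substr(tpl, 401, 800)))
  expect_true(rc$accepted)
  expect_equal(rc$relative_orientation, "revcomp")
})

test_that("the compiled aligner scores agree with reference overlap alignment", {
  set.seed(510)
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  for (i in 1:25) {
    x <- rand_dna(sample(60:250, 1))
    y <- rand_dna(sample(60:250, 1))
    if (runif(1) < 0.6) {
      o <- sample(20:60, 1)
      y <- paste0(substr(x, nchar(x) - o + 1, nchar(x)), y)
    }
    ours <- beskit:::.ov_aln(x, y)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(x), Biostrings::DNAString(y), type = "overlap",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
    expect_equal(ours$score, BiocGenerics::score(ref))
  }
})

test_that("greedy assembly separates non-overlapping reads and merges tiles", {
  set.seed(502)
  lone <- setNames(replicate(3, rand_dna(300)), c("x", "y", "z"))
  asm <- greedy_assemble(lone)
  expect_equal(nrow(asm$contigs), 0L)
  expect_equal(nrow(asm$singletons), 3L)
  expect_setequal(asm$membership$id, c("x", "y", "z"))

  tpl <- rand_dna(900)
  two <- c(r1 = substr(tpl, 1, 500), r2 = substr(tpl, 401, 900))
  asm2 <- greedy_assemble(two)
  expect_equal(nrow(asm2$contigs), 1L)
  expect_equal(nchar(asm2$contigs$consensus), 900L)
  expect_equal(asm2$contigs$consensus, tpl)
  expect_equal(nrow(asm2$singletons), 0L)

  # conservation: every read appears exactly once
  expect_equal(sum(asm2$contigs$n_members) + nrow(asm2$singletons), 2L)
  expect_error(greedy_assemble(c(a = "ACGT", a = "ACGT")), "duplicate")
})

test_that("membership equals the overlap-graph components on fragment tilings", {
  set.seed(503)
  for (i in 1:8) {
    case <- fragment_case(n_templates = sample(1:3, 1))
    asm <- greedy_assemble(case$seqs)
    expect_equal(sum(asm$contigs$n_members) + nrow(asm$singletons),
                 length(case$seqs))
    oracle <- oracle_components(case$seqs)
    expect_true(same_partition(assembly_partition(asm), oracle))
    # and the components are exactly the templates
    expect_true(same_partition(oracle, split(names(case$truth), case$truth)))
  }
})

test_that("re-assembling an assembly's output makes no new merges", {
  set.seed(504)
  case <- fragment_case(n_templates = 2)
  asm <- greedy_assemble(case$seqs)
  again <- greedy_assemble(assembly_sequences(asm))
  expect_equal(nrow(again$contigs), 0L)
  expect_equal(nrow(again$singletons),
               nrow(asm$contigs) + nrow(asm$singletons))
})

test_that("cross-assembly accounts for joint redundancy", {
  set.seed(505)
  # disjoint: no cross overlaps, nothing removed
  a1 <- greedy_assemble(setNames(replicate(3, rand_dna(300)), c("a1", "a2", "a3")))
  a2 <- greedy_assemble(setNames(replicate(2, rand_dna(300)), c("b1", "b2")))
  res <- cross_assemble(a1, a2)
  expect_equal(res$redundancy$n_out, 5L)
  expect_equal(res$redundancy$n_removed, 0L)
  expect_equal(res$redundancy$bp_removed, 0L)

  # self-cross under fresh ids: every sequence merges with its copy
  seqs <- setNames(replicate(4, rand_dna(400)), sprintf("s%d", 1:4))
  asm <- greedy_assemble(seqs)
  copy <- asm
  copy$singletons$id <- paste0("dup_", copy$singletons$id)
  self <- cross_assemble(asm, copy)
  expect_equal(self$redundancy$n_in, 8L)
  expect_equal(self$redundancy$n_out, 4L)
  expect_equal(self$redundancy$n_removed, 4L)

  # id collision is refused
  expect_error(cross_assemble(asm, asm), "collision")
})
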