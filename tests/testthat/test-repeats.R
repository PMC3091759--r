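test_that("family labels map onto the taxonomy, with unclassified fallbacks", {
  expect_equal(unname(classify_repeat("Copia-12_Mel", "LTR/Copia")),
               c("Retroelements", "LTR", "Ty1/Copia"))
  expect_equal(unname(classify_repeat("EnSpm-3", "DNA/En-Spm")["element"]),
               "En-Spm")
  expect_equal(unname(classify_repeat("FooBar", "LTR")),
               c("Retroelements", "LTR", "Unclassified"))
  expect_equal(unname(classify_repeat("FooBar", "DNA")["class"]),
               "DNA_transposons")
  expect_equal(unname(classify_repeat("FooBar", "")["class"]),
               "Unclassified")
  expect_equal(unname(classify_repeat("Helitron-1", "RC/Helitron")["class"]),
               "Rolling_circles")
  expect_equal(unname(classify_repeat("18S_rRNA", "rRNA")["element"]),
               "Small_subunit")
})

test_that("repeat summary ratios follow the TE conventions", {
  mk <- function(element, class_label, n) {
    data.frame(seq_id = "s", start = 0L, end = 100L, strand = "+",
               family_label = element, class_label = class_label,
               stringsAsFactors = FALSE)[rep(1, n), ]
  }
  hits <- rbind(mk("Copia-1", "LTR/Copia", 5), mk("Gypsy-1", "LTR/Gypsy", 3),
                mk("MuDR-1", "DNA/MuDR", 2), mk("18S_rRNA", "rRNA", 2))
  cls <- classify_repeats(hits)
  s <- summarize_repeats(cls, total_bp = 1e5)
  expect_equal(s$n_total, 12L)
  expect_equal(s$te_count, 10L)
  expect_equal(s$retro_fraction, 80.0)           # 8 of 10 TEs
  expect_equal(s$copia_pct_of_retro, 62.5)
  expect_equal(s$ty1_ty3_ratio, round(5 / 3, 1))
  expect_equal(sum(s$class_counts), s$n_total)
  expect_error(summarize_repeats(cls, 0), "positive")

  none <- summarize_repeats(classify_repeats(hits[0, ]), 100)
  expect_equal(none$n_total, 0L)
  expect_true(is.na(none$retro_fraction))
})

test_that("masking unions spans and is idempotent", {
  seqs <- c(s1 = strrep("A", 100))
  one <- data.frame(seq_id = "s1", start = 10L, end = 20L)
  m <- mask_sequences(seqs, one, "hard")
  expect_equal(m$masked_bp, 10L)
  expect_equal(substr(m$seqs$sequence, 11, 20), strrep("N", 10))
  expect_equal(substr(m$seqs$sequence, 1, 10), strrep("A", 10))

  two <- data.frame(seq_id = "s1", start = c(0L, 5L), end = c(10L, 15L))
  expect_equal(mask_sequences(seqs, two)$masked_bp, 15L)

  soft <- mask_sequences(seqs, one, "soft")
  expect_equal(substr(soft$seqs$sequence, 11, 20), strrep("a", 10))

  again <- mask_sequences(m$seqs, one, "hard")
  expect_equal(again$seqs$sequence, m$seqs$sequence)

  expect_equal(mask_sequences(seqs, one[0, ])$masked_bp, 0L)
  bad <- data.frame(seq_id = "s1", start = 95L, end = 120L)
  expect_error(mask_sequences(seqs, bad), "beyond")
})

test_that("planted repeat classes are recovered from their labels", {
  g <- simulate_genome(1, 40000,
                       feature_request(n_repeats = 40), seed = 11)
  led <- g$ledger$repeats
  cls <- classify_repeats(led[, c("seq_id", "start", "end", "strand",
                                  "family_label", "class_label")])
  expect_equal(cls$class, led$class)
  expect_equal(cls$element, led$element)
  s <- summarize_repeats(cls, sum(nchar(g$sequences$sequence)))
  expect_equal(s$n_total, 40L)
  planted <- table(led$class)
  expect_equal(as.integer(planted[names(s$class_counts)]),
               unname(s$class_counts))
})
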