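mk_hit <- function(q, s, e, bit = 100) {
  data.frame(query_id = q, subject_id = s, pident = 95, aln_len = 100L,
             mismatches = 0L, gap_opens = 0L, q_start = 0L, q_end = 100L,
             s_start = 0L, s_end = 100L, strand = "+", evalue = e,
             bitscore = bit, stringsAsFactors = FALSE)
}

test_that("tier precedence and the double cutoff behave as specified", {
  hits <- list(
    melon = rbind(mk_hit("q1", "m1", 1e-30), mk_hit("q4", "m2", 1e-10)),
    cucumber = rbind(mk_hit("q1", "c1", 1e-60), mk_hit("q2", "c2", 1e-55)),
    plants = mk_hit("q3", "p1", 1e-21))
  res <- tiered_hits(hits, precedence = c("melon", "cucumber", "plants"),
                     queries = sprintf("q%d", 1:5))
  r <- function(q) res[res$query_id == q, ]
  # melon hit takes precedence even though cucumber is stronger
  expect_equal(r("q1")$tier, "melon")
  expect_false(r("q1")$high)                     # 1e-30 > 1e-50
  expect_equal(r("q2")$tier, "cucumber")
  expect_true(r("q2")$high)
  expect_equal(r("q3")$tier, "plants")
  expect_equal(r("q4")$tier, "none")             # 1e-10 fails the low cutoff
  expect_equal(r("q5")$tier, "none")
  expect_error(tiered_hits(hits, precedence = "melon"), "precedence")
})

test_that("best hit ties break by E-value then bit score", {
  hits <- list(db = rbind(mk_hit("q", "s1", 1e-30, bit = 90),
                          mk_hit("q", "s2", 1e-40, bit = 80),
                          mk_hit("q", "s3", 1e-40, bit = 120)))
  res <- tiered_hits(hits)
  expect_equal(res$subject_id, "s3")
  expect_equal(res$evalue, 1e-40)
})

test_that("stringency is monotone and tiers are exclusive", {
  set.seed(601)
  for (i in 1:10) {
    qs <- sprintf("q%d", 1:30)
    rnd_hits <- function() {
      n <- sample(10:40, 1)
      do.call(rbind, lapply(seq_len(n), function(.) {
        mk_hit(sample(qs, 1), "s", 10^-runif(1, 5, 70))
      }))
    }
    hits <- list(a = rnd_hits(), b = rnd_hits(), c = rnd_hits())
    loose <- tiered_hits(hits, e_low = 1e-10, e_high = 1e-50, queries = qs)
    strict <- tiered_hits(hits, e_low = 1e-20, e_high = 1e-50, queries = qs)
    for (db in c("a", "b", "c")) {
      # relaxing the low cutoff never loses a tier's queries to "none"
      expect_gte(sum(loose$tier != "none"), sum(strict$tier != "none"))
      expect_lte(sum(strict$tier == db & strict$high),
                 sum(strict$tier == db))
    }
    # precedence exclusivity: assigned tiers partition queries with a
    # qualifying hit
    qualifying <- unique(unlist(lapply(hits, function(h) {
      h$query_id[h$evalue <= 1e-20]
    })))
    expect_equal(sum(strict$tier != "none"), length(qualifying))
  }
})

test_that("coding fraction and transcriptome size arithmetic", {
  assignments <- data.frame(
    query_id = sprintf("q%d", 1:4),
    tier = c("melon", "melon", "cucurbit", "none"),
    high = c(TRUE, FALSE, FALSE, FALSE), stringsAsFactors = FALSE)
  ce <- coding_fraction(assignments, n_total = 10)
  expect_equal(ce$low_total, 3L)
  expect_equal(ce$low_total_pct, 30.0)
  expect_equal(ce$high_total_pct, 10.0)
  expect_equal(ce$coding_range_pct, c(10.0, 30.0))
  expect_error(coding_fraction(assignments, 0), "positive")
  expect_error(coding_fraction(assignments, 2), "smaller")

  none <- coding_fraction(assignments[assignments$tier == "none", ], 10)
  expect_equal(none$low_total_pct, 0)

  expect_equal(transcriptome_size(7929, 11372, 23762), 34000)
  expect_equal(transcriptome_size(5072, 6630, 23762), 31000)
  expect_equal(transcriptome_size(10, 10, 23762), 24000)  # complete-db limit
  expect_error(transcriptome_size(1, 0, 10), "positive")
})

test_that("planted gene content is recovered through the naive search", {
  g <- simulate_genome(1, 30000, feature_request(n_genes = 12), seed = 21)
  genes <- g$ledger$genes
  gene_db <- data.frame(
    id = genes$gene_id,
    sequence = substring(g$sequences$sequence[1], genes$start + 1, genes$end))
  set.seed(22)
  n_q <- 60
  from_gene <- runif(n_q) < 0.5
  qseq <- character(n_q)
  for (i in seq_len(n_q)) {
    if (from_gene[i]) {
      gi <- sample(nrow(genes), 1)
      glen <- genes$end[gi] - genes$start[gi]
      L <- min(200, glen)
      off <- sample(glen - L + 1, 1) - 1
      qseq[i] <- substr(gene_db$sequence[gi], off + 1, off + L)
      if (runif(1) < 0.5) qseq[i] <- revcomp(qseq[i])
    } else {
      qseq[i] <- rand_dna(200)
    }
  }
  queries <- data.frame(id = sprintf("q%d", 1:n_q), sequence = qseq)
  hits <- naive_homology_search(queries, gene_db)
  res <- tiered_hits(list(genes = hits), queries = queries$id)
  ce <- coding_fraction(res, n_q)
  expect_equal(ce$low_total, sum(from_gene))
  expect_equal(sort(res$query_id[res$tier == "genes"]),
               sort(queries$id[from_gene]))
})
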