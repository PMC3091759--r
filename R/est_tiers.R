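# Tiered EST-homology classification of coding content. Query sequences are
# searched against unigene/EST databases in precedence order (own species
# first, then related species, then everything else); a query consults the
# next database only if no hit at the low-stringency cutoff was found
# earlier. A double E-value cutoff (low 1e-20, high 1e-50) brackets the
# coding fraction between a permissive and a conservative estimate.

#' Assign queries to homology tiers
#'
#' @param hits_by_db named list of hit data.frames (see
#'   [read_hits_tabular()]), one per database.
#' @param precedence database names in search order; must cover every name in
#'   `hits_by_db`.
#' @param e_low low-stringency E-value cutoff (tier assignment).
#' @param e_high high-stringency cutoff (`e_high <= e_low`); the high flag is
#'   evaluated on the assigned tier's best hit only.
#' @param queries optional character vector of all query ids (queries without
#'   hits get tier `"none"`).
#' @return data.frame with one row per query: `query_id`, `tier` (a database
#'   name or `"none"`), `high` (best hit also passes `e_high`), `evalue`,
#'   `bitscore`, `subject_id` of the best hit (NA for `"none"`). The best hit
#'   per database is the lowest E-value, ties broken by highest bit score,
#'   then input order.
#' @export
tiered_hits <- function(hits_by_db, precedence = names(hits_by_db),
                        e_low = 1e-20, e_high = 1e-50, queries = NULL) {
  stopifnot(e_high <= e_low)
  unknown <- setdiff(names(hits_by_db), precedence)
  if (length(unknown)) .stopf("database '%s' not in precedence order",
                              unknown[1])
  all_q <- unique(c(queries %||% character(0),
                    unlist(lapply(hits_by_db, `[[`, "query_id"),
                           use.names = FALSE)))
  out <- data.frame(query_id = all_q, tier = "none", high = FALSE,
                    evalue = NA_real_, bitscore = NA_real_,
                    subject_id = NA_character_, stringsAsFactors = FALSE)
  unassigned <- rep(TRUE, length(all_q))
  names(unassigned) <- all_q
  for (db in precedence) {
    h <- hits_by_db[[db]]
    if (is.null(h) || nrow(h) == 0) next
    h <- h[h$evalue <= e_low & unassigned[h$query_id], , drop = FALSE]
    if (nrow(h) == 0) next
    h <- h[order(match(h$query_id, all_q), h$evalue, -h$bitscore), ,
           drop = FALSE]
    best <- h[!duplicated(h$query_id), , drop = FALSE]
    i <- match(best$query_id, out$query_id)
    out$tier[i] <- db
    out$high[i] <- best$evalue <= e_high
    out$evalue[i] <- best$evalue
    out$bitscore[i] <- best$bitscore
    out$subject_id[i] <- best$subject_id
    unassigned[best$query_id] <- FALSE
  }
  out
}

#' Coding-fraction estimate from tier assignments
#'
#' @param assignments output of [tiered_hits()].
#' @param n_total total number of analyzed sequences (>= number with a tier).
#' @param precedence tier order for the table rows; defaults to the tiers
#'   present.
#' @return object of class `coding_estimate`: per-tier hit counts and
#'   percentages (rounded half-up to 1 decimal over `n_total`) at the low
#'   and high stringency, totals, and the coding-fraction range
#'   `[high total %, low total %]`.
#' @export
coding_fraction <- function(assignments, n_total, precedence = NULL) {
  if (n_total <= 0) .stopf("n_total must be positive")
  hit <- assignments[assignments$tier != "none", , drop = FALSE]
  if (nrow(hit) > n_total) {
    .stopf("n_total (%d) smaller than number of assigned queries (%d)",
           n_total, nrow(hit))
  }
  tiers <- precedence %||% unique(hit$tier)
  tab <- data.frame(
    tier = tiers,
    low_hits = vapply(tiers, function(t) sum(hit$tier == t), integer(1)),
    high_hits = vapply(tiers, function(t) sum(hit$tier == t & hit$high),
                       integer(1)),
    stringsAsFactors = FALSE)
  tab$low_pct <- round_half_up(100 * tab$low_hits / n_total, 1)
  tab$high_pct <- round_half_up(100 * tab$high_hits / n_total, 1)
  low_total <- sum(tab$low_hits)
  high_total <- sum(tab$high_hits)
  structure(list(
    table = tab,
    n_total = n_total,
    low_total = low_total,
    high_total = high_total,
    low_total_pct = round_half_up(100 * low_total / n_total, 1),
    high_total_pct = round_half_up(100 * high_total / n_total, 1),
    coding_range_pct = c(round_half_up(100 * high_total / n_total, 1),
                         round_half_up(100 * low_total / n_total, 1))
  ), class = "coding_estimate")
}

#' @export
print.coding_estimate <- function(x, ...) {
  cat(sprintf("coding estimate over %d sequences: %d hits (%.1f%%) low, %d (%.1f%%) high\n",
              x$n_total, x$low_total, x$low_total_pct,
              x$high_total, x$high_total_pct))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Transcriptome-size estimate from tier shares
#'
#' If the own-species unigene database were complete, every coding query
#' would hit it; the share of coding queries that only hit other databases
#' measures the missing fraction, so the transcriptome size is estimated as
#' `unigene_count / (melon_hits / all_hits)`, rounded to the nearest 1,000.
#'
#' @param melon_hits coding queries hitting the own-species database.
#' @param all_hits all coding queries (>= `melon_hits`, > 0).
#' @param unigene_count size of the own-species unigene database.
#' @return estimated transcriptome size (sequences).
#' @export
transcriptome_size <- function(melon_hits, all_hits, unigene_count) {
  if (all_hits <= 0) .stopf("all_hits must be positive")
  stopifnot(melon_hits > 0, melon_hits <= all_hits, unigene_count > 0)
  round_half_up(unigene_count / (melon_hits / all_hits) / 1000, 0) * 1000
}

#' Naive exact-substring homology search
#'
#' A deliberately simple search used only for end-to-end tests on synthetic
#' data with zero divergence: each query is matched exactly (both strands)
#' against each subject with [Biostrings::matchPattern()]. Hits get perfect
#' identity and a nominal E-value of `m * n * 2^(-2L)` for a match of length
#' `L` in a search space of `m * n` bp, floored at `1e-300`.
#'
#' @param queries,subjects sequence data.frames or named character vectors.
#' @param min_len minimum query length searched.
#' @return hit data.frame in the internal convention (see
#'   [read_hits_tabular()]).
#' @export
naive_homology_search <- function(queries, subjects, min_len = 20L) {
  queries <- as_seq_df(queries)
  subjects <- as_seq_df(subjects)
  m <- sum(nchar(queries$sequence))
  n <- sum(nchar(subjects$sequence))
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    q <- queries$sequence[i]
    L <- nchar(q)
    if (L < min_len) next
    ev <- max(m * n * 2^(-2 * L), 1e-300)
    for (j in seq_len(nrow(subjects))) {
      subj <- Biostrings::DNAString(subjects$sequence[j])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") q else revcomp(q)
        mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
        if (length(mt) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queries$id[i], subject_id = subjects$id[j],
          pident = 100, aln_len = L,
          mismatches = 0L, gap_opens = 0L,
          q_start = 0L, q_end = L,
          s_start = BiocGenerics::start(mt) - 1L,
          s_end = BiocGenerics::end(mt),
          strand = strand, evalue = ev, bitscore = 2 * L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(hits_df())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
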