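# Perfect microsatellite (SSR) detection. A locus is a maximal perfect
# tandem run of a primitive 1-6 nt unit; partial final units are allowed, so
# copy number is real-valued. Motifs are canonicalized over rotation and
# reverse complement, collapsing e.g. TTC, CTT and GAA into the AAG class.

#' Default SSR thresholds
#'
#' Units of 1-3 nt must reach 12 nt of total length; units of 4-6 nt must
#' reach four unit repetitions.
#'
#' @param min_len_1_3 minimum total length (nt) for 1-3 nt units.
#' @param min_units_4_6 minimum number of unit repetitions for 4-6 nt units.
#' @return named list of thresholds.
#' @export
ssr_thresholds <- function(min_len_1_3 = 12L, min_units_4_6 = 4L) {
  list(min_len_1_3 = as.integer(min_len_1_3),
       min_units_4_6 = as.integer(min_units_4_6))
}

# is the motif primitive (not a repetition of a shorter unit)?
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k / d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

.rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L))
  }, character(1))
}

#' Canonical SSR motif class
#'
#' The canonical representative of a primitive 1-6 nt motif is the
#' lexicographic minimum over all rotations of the motif and all rotations of
#' its reverse complement, so that a class such as AAG covers AAG, AGA, GAA,
#' CTT, TTC and TCT. Non-primitive motifs (e.g. "ATAT") are rejected: the
#' caller must reduce to the primitive unit first.
#'
#' @param motif motif string over A/C/G/T, length 1-6.
#' @return the canonical motif, with attributes `strand` (`"+"` if a rotation
#'   of the input wins, `"-"` if a rotation of its reverse complement) and
#'   `class` (the conventional two-sided label, e.g. `"AAG/CTT"`).
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  k <- nchar(motif)
  if (k < 1L || k > 6L || grepl("[^ACGT]", motif)) {
    .stopf("motif must be a 1-6 nt string over ACGT, got '%s'", motif)
  }
  if (!is_primitive_motif(motif)) {
    .stopf("motif '%s' is not primitive; reduce to its shortest unit first",
           motif)
  }
  fwd <- .rotations(motif)
  rc <- .rotations(revcomp(motif))
  canon <- min(c(fwd, rc))
  canon_rc <- min(.rotations(revcomp(canon)))
  structure(canon,
            strand = if (canon %in% fwd) "+" else "-",
            class = if (canon == canon_rc) canon
                    else paste(canon, canon_rc, sep = "/"))
}

# threshold in total nt for unit length k
.ssr_min_len <- function(k, thresholds) {
  if (k <= 3L) thresholds$min_len_1_3 else thresholds$min_units_4_6 * k
}

# maximal perfect runs of period k in a character vector of bases; returns
# matrix cols (start, total_len) in 1-based coordinates
.period_runs <- function(bases, k) {
  n <- length(bases)
  if (n < k + 1L) return(NULL)
  a <- bases[seq_len(n - k)]
  b <- bases[seq.int(k + 1L, n)]
  eq <- a == b & a != "N" & b != "N"
  r <- rle(eq)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  cbind(start = starts[i], total = r$lengths[i] + k)
}

#' Find perfect microsatellites in one sequence
#'
#' Scans for maximal perfect tandem repeats of primitive 1-6 nt units. `N`
#' bases terminate runs. Nested loci are suppressed: a locus contained in
#' another candidate is dropped, with priority given to the longest total
#' span, then the smallest unit, then the leftmost start. Output is sorted by
#' `(start, unit_length)`.
#'
#' @param seq a single sequence string, or a one-row sequence data.frame.
#' @param seq_id id recorded in the output (taken from the data.frame when
#'   one is supplied).
#' @param thresholds thresholds from [ssr_thresholds()].
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `unit_length`, `motif` (as read), `canonical_motif`,
#'   `copy_number`, `total_length`.
#' @export
find_ssrs <- function(seq, seq_id = "seq", thresholds = ssr_thresholds()) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    seq_id <- seq$id
    seq <- seq$sequence
  }
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  cand <- list()
  for (k in 1:6) {
    runs <- .period_runs(bases, k)
    if (is.null(runs)) next
    min_len <- .ssr_min_len(k, thresholds)
    runs <- runs[runs[, "total"] >= min_len, , drop = FALSE]
    for (j in seq_len(nrow(runs))) {
      total <- runs[j, "total"]
      s <- runs[j, "start"]
      motif <- paste(bases[s:(s + k - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = s, total = total, unit = k, motif = motif,
                   stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                    unit_length = integer(), motif = character(),
                    canonical_motif = character(), copy_number = numeric(),
                    total_length = integer(), stringsAsFactors = FALSE)
  if (length(cand) == 0) return(out)
  cand <- do.call(rbind, cand)
  # suppression: longest span first, then smallest unit, then leftmost
  ord <- order(-cand$total, cand$unit, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(nrow(cand))) {
    s <- cand$start[j]; e <- s + cand$total[j] - 1L
    contained <- FALSE
    for (i in kept) {
      if (s >= cand$start[i] && e <= cand$start[i] + cand$total[i] - 1L) {
        contained <- TRUE
        break
      }
    }
    if (!contained) kept <- c(kept, j)
  }
  cand <- cand[kept, , drop = FALSE]
  canon <- vapply(cand$motif, function(m) as.character(canonical_motif(m)),
                  character(1))
  out <- data.frame(
    seq_id = seq_id,
    start = cand$start - 1L,
    end = cand$start - 1L + cand$total,
    unit_length = cand$unit,
    motif = cand$motif,
    canonical_motif = unname(canon),
    copy_number = cand$total / cand$unit,
    total_length = cand$total,
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of sequences for microsatellites
#'
#' @param seqs sequence data.frame or named character vector.
#' @param thresholds thresholds from [ssr_thresholds()].
#' @return row-bound [find_ssrs()] output over all sequences.
#' @export
scan_ssrs <- function(seqs, thresholds = ssr_thresholds()) {
  seqs <- as_seq_df(seqs)
  res <- lapply(seq_len(nrow(seqs)), function(i) {
    find_ssrs(seqs$sequence[i], seqs$id[i], thresholds)
  })
  out <- do.call(rbind, c(res, list(find_ssrs("", "drop")[0, ])))
  rownames(out) <- NULL
  out
}

#' SSR length-bin edges
#'
#' Bins are inclusive of their lower bound: 12-20, 21-50, 51-100, >100 nt.
#' Class I microsatellites are those longer than 20 nt.
#' @keywords internal
.ssr_bins <- data.frame(lo = c(12L, 21L, 51L, 101L),
                        hi = c(20L, 50L, 100L, .Machine$integer.max),
                        label = c("12-20", "21-50", "51-100", ">100"),
                        stringsAsFactors = FALSE)

#' Summarize a microsatellite scan
#'
#' @param loci SSR locus table from [scan_ssrs()].
#' @param total_sequence_bp total bp of the scanned sequence set.
#' @return object of class `ssr_summary`: counts per canonical motif and unit
#'   length, length-bin counts (12-20 / 21-50 / 51-100 / >100 nt), class I
#'   count (total length > 20 nt), total SSR bp, SSR percent of sequence, and
#'   density as kb per SSR (1 decimal; `NA` when there are no loci).
#' @export
summarize_ssrs <- function(loci, total_sequence_bp) {
  stopifnot(total_sequence_bp > 0)
  n <- nrow(loci)
  bin_counts <- setNames(integer(nrow(.ssr_bins)), .ssr_bins$label)
  for (i in seq_len(nrow(.ssr_bins))) {
    bin_counts[i] <- sum(loci$total_length >= .ssr_bins$lo[i] &
                         loci$total_length <= .ssr_bins$hi[i])
  }
  motif_counts <- if (n) table(loci$canonical_motif) else table(character(0))
  unit_counts <- setNames(integer(6), 1:6)
  if (n) {
    tu <- table(loci$unit_length)
    unit_counts[names(tu)] <- as.integer(tu)
  }
  total_bp <- sum(loci$total_length)
  structure(list(
    n = n,
    motif_counts = as.data.frame(motif_counts, stringsAsFactors = FALSE,
                                 responseName = "count"),
    unit_counts = unit_counts,
    bin_counts = bin_counts,
    class1 = sum(loci$total_length > 20L),
    total_bp = total_bp,
    pct_of_sequence = round_half_up(100 * total_bp / total_sequence_bp, 1),
    density_kb = if (n) ssr_density_kb(n, total_sequence_bp) else NA_real_,
    total_sequence_bp = total_sequence_bp
  ), class = "ssr_summary")
}

#' SSR density in kb of sequence per microsatellite
#'
#' @param n_ssrs number of microsatellites.
#' @param total_sequence_bp scanned sequence length in bp.
#' @return kb per SSR, rounded half-up to 1 decimal.
#' @export
ssr_density_kb <- function(n_ssrs, total_sequence_bp) {
  stopifnot(n_ssrs > 0, total_sequence_bp > 0)
  round_half_up(total_sequence_bp / n_ssrs / 1000, 1)
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("SSR summary: %d loci, %d bp (%.1f%% of %.1f kb), one per %.1f kb\n",
              x$n, x$total_bp, x$pct_of_sequence,
              x$total_sequence_bp / 1000, x$density_kb))
  cat(sprintf("  class I (>20 nt): %d; bins: %s\n", x$class1,
              paste(sprintf("%s:%d", names(x$bin_counts), x$bin_counts),
                    collapse = " ")))
  invisible(x)
}
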