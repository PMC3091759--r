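# Paired-BES microsynteny against a subject genome. A clone's two end reads
# are linked by its insert, so their co-placement on one subject sequence at
# an insert-like separation, facing each other, is evidence of conserved
# local order (microsynteny). The three collinearity criteria: (1) same
# subject sequence, (2) separation within a window (50-500 kb by default,
# bounds inclusive), (3) correct relative orientation, i.e. opposite strands
# with each read's 3' end pointing at the other (convergent).

#' Default synteny parameters
#'
#' @param min_sep,max_sep separation window in bp (inclusive bounds).
#' @param merge_window hits of one end on the same subject and strand within
#'   this distance collapse into a single anchor.
#' @param require_orientation apply the orientation criterion.
#' @return named list of parameters.
#' @export
synteny_params <- function(min_sep = 50000, max_sep = 500000,
                           merge_window = 10000, require_orientation = TRUE) {
  list(min_sep = min_sep, max_sep = max_sep, merge_window = merge_window,
       require_orientation = require_orientation)
}

# Collapse one end's hits into anchors: same subject + strand within
# merge_window merge; representative = best E-value (tie: bitscore, order).
merge_anchors <- function(hits, merge_window = 10000) {
  if (nrow(hits) == 0) {
    return(data.frame(subject_id = character(), strand = character(),
                      mid = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits$mid <- (hits$s_start + hits$s_end) / 2
  hits$.ord <- seq_len(nrow(hits))
  grp <- split(hits, paste(hits$subject_id, hits$strand, sep = "\r"))
  anchors <- lapply(grp, function(g) {
    g <- g[order(g$mid), , drop = FALSE]
    cluster <- cumsum(c(1, diff(g$mid) > merge_window))
    reps <- lapply(split(g, cluster), function(cl) {
      cl <- cl[order(cl$evalue, -cl$bitscore, cl$.ord), , drop = FALSE]
      data.frame(subject_id = cl$subject_id[1], strand = cl$strand[1],
                 mid = cl$mid[1], evalue = cl$evalue[1],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, reps)
  })
  out <- do.call(rbind, anchors)
  rownames(out) <- NULL
  out
}

#' Enumerate mapping loci for one BES pair
#'
#' Each end's hits are merged into anchors; every (anchor1, anchor2)
#' combination sharing a subject sequence is one mapping locus. Separation is
#' the distance between anchor midpoints; orientation is correct when the
#' strands are opposite and the plus-strand anchor lies left of the
#' minus-strand anchor (convergent reads).
#'
#' @param hits_end1,hits_end2 hit data.frames for the two ends.
#' @param merge_window anchor merge distance in bp.
#' @param pair_id id recorded in the output.
#' @return data.frame with one row per locus: `pair_id`, `subject_id`,
#'   `mid1`, `mid2`, `strand1`, `strand2`, `separation`, `orientation_ok`.
#' @export
loci_for_pair <- function(hits_end1, hits_end2, merge_window = 10000,
                          pair_id = "pair") {
  a1 <- merge_anchors(hits_end1, merge_window)
  a2 <- merge_anchors(hits_end2, merge_window)
  empty <- data.frame(pair_id = character(), subject_id = character(),
                      mid1 = numeric(), mid2 = numeric(),
                      strand1 = character(), strand2 = character(),
                      separation = numeric(), orientation_ok = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(a1) == 0 || nrow(a2) == 0) return(empty)
  shared <- intersect(a1$subject_id, a2$subject_id)
  if (length(shared) == 0) return(empty)
  rows <- list()
  for (sid in shared) {
    u <- a1[a1$subject_id == sid, , drop = FALSE]
    v <- a2[a2$subject_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(u))) for (j in seq_len(nrow(v))) {
      opp <- u$strand[i] != v$strand[j]
      conv <- FALSE
      if (opp) {
        plus_mid <- if (u$strand[i] == "+") u$mid[i] else v$mid[j]
        minus_mid <- if (u$strand[i] == "-") u$mid[i] else v$mid[j]
        conv <- plus_mid <= minus_mid
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pair_id, subject_id = sid,
        mid1 = u$mid[i], mid2 = v$mid[j],
        strand1 = u$strand[i], strand2 = v$strand[j],
        separation = abs(u$mid[i] - v$mid[j]),
        orientation_ok = opp && conv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a mapping locus against the collinearity criteria
#'
#' @param loci locus data.frame from [loci_for_pair()].
#' @param min_sep,max_sep separation window (bp, inclusive).
#' @param require_orientation apply the orientation criterion; when `FALSE`
#'   a locus in the window is collinear regardless of orientation (the
#'   relaxed analysis tolerating localized inversions).
#' @return character vector of verdicts: `"COLLINEAR"`, `"FAIL_WINDOW"` or
#'   `"FAIL_ORIENTATION"`.
#' @export
classify_collinear <- function(loci, min_sep = 50000, max_sep = 500000,
                               require_orientation = TRUE) {
  in_window <- loci$separation >= min_sep & loci$separation <= max_sep
  ifelse(!in_window, "FAIL_WINDOW",
         ifelse(require_orientation & !loci$orientation_ok,
                "FAIL_ORIENTATION", "COLLINEAR"))
}

#' Paired-BES synteny funnel summary
#'
#' Applies the three collinearity criteria pair by pair and reports the
#' funnel: ends with hits, pairs with both ends hit, pairs with at least one
#' same-subject locus, total loci and mean loci per same-subject pair, pairs
#' with a locus in the separation window, and pairs with a fully collinear
#' locus. The funnel is monotone by construction. Dispersal: among pairs
#' with more than one locus, the fraction whose loci sit on two or more
#' different subjects.
#'
#' @param pairs pair table from [pair_bes()] or [simulate_library()]
#'   (columns `clone_id`, `forward_id`, `reverse_id`).
#' @param hits hit data.frame covering both ends, keyed by read id.
#' @param params parameters from [synteny_params()].
#' @return object of class `synteny_summary`; its `loci` element holds the
#'   per-locus table with verdicts.
#' @export
synteny_summary <- function(pairs, hits, params = synteny_params()) {
  by_query <- if (nrow(hits)) split(hits, hits$query_id) else list()
  empty_h <- hits[0, , drop = FALSE]
  loci <- list()
  n_both <- 0L
  for (i in seq_len(nrow(pairs))) {
    h1 <- by_query[[pairs$forward_id[i]]] %||% empty_h
    h2 <- by_query[[pairs$reverse_id[i]]] %||% empty_h
    if (nrow(h1) && nrow(h2)) n_both <- n_both + 1L
    l <- loci_for_pair(h1, h2, params$merge_window, pairs$clone_id[i])
    if (nrow(l)) loci[[length(loci) + 1L]] <- l
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    loci_for_pair(hits_df(), hits_df())
  if (nrow(loci)) {
    loci$verdict <- classify_collinear(loci, params$min_sep, params$max_sep,
                                       params$require_orientation)
    loci$in_window <- loci$separation >= params$min_sep &
      loci$separation <= params$max_sep
  } else {
    loci$verdict <- character(0)
    loci$in_window <- logical(0)
  }
  per_pair <- split(loci, loci$pair_id)
  n_same <- length(per_pair)
  n_window <- sum(vapply(per_pair, function(l) any(l$in_window), logical(1)))
  n_coll <- sum(vapply(per_pair, function(l) any(l$verdict == "COLLINEAR"),
                       logical(1)))
  multi <- per_pair[vapply(per_pair, nrow, integer(1)) > 1L]
  dispersal <- if (length(multi)) {
    mean(vapply(multi, function(l) length(unique(l$subject_id)) >= 2L,
                logical(1)))
  } else NA_real_
  reads <- unique(c(pairs$forward_id, pairs$reverse_id))
  structure(list(
    n_pairs = nrow(pairs),
    n_bes_with_hits = sum(reads %in% hits$query_id),
    n_pairs_both_ends_hit = n_both,
    n_pairs_same_subject = n_same,
    n_loci = nrow(loci),
    mean_loci_per_pair = if (n_same > 0)
      round_half_up(nrow(loci) / n_same, 1) else NA_real_,
    n_pairs_in_window = n_window,
    n_pairs_collinear = n_coll,
    pct_of_pairs = if (nrow(pairs) > 0)
      round_half_up(100 * n_coll / nrow(pairs), 2) else NA_real_,
    multi_locus_dispersal = dispersal,
    params = params,
    loci = loci
  ), class = "synteny_summary")
}

#' @export
print.synteny_summary <- function(x, ...) {
  cat(sprintf(
    "synteny funnel over %d pairs: both-ends-hit %d >= same-subject %d >= in-window %d >= collinear %d (%.2f%% of pairs)\n",
    x$n_pairs, x$n_pairs_both_ends_hit, x$n_pairs_same_subject,
    x$n_pairs_in_window, x$n_pairs_collinear, x$pct_of_pairs))
  cat(sprintf("  %d loci, %.1f per same-subject pair\n",
              x$n_loci, x$mean_loci_per_pair))
  invisible(x)
}

#' Mean mapping loci per same-subject pair
#'
#' @param n_loci total mapping loci.
#' @param n_pairs_same_subject pairs with at least one same-subject locus.
#' @return loci per pair, rounded half-up to 1 decimal.
#' @export
mean_loci_per_pair <- function(n_loci, n_pairs_same_subject) {
  stopifnot(n_pairs_same_subject > 0)
  round_half_up(n_loci / n_pairs_same_subject, 1)
}
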