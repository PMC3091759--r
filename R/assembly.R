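# Greedy overlap clustering of BES into contigs and singletons. The survey's
# redundancy reduction used stringent thresholds (minimum overlap 80 columns,
# minimum identity 95%); identity is computed over aligned overlap columns
# with gaps counted as mismatches, and both orientations of the incoming read
# are considered because BES strands are arbitrary.

.ov_aln <- function(a, b) {
  res <- .ov_align_cpp(a, b)
  res$identity <- if (res$columns > 0) 100 * res$matches / res$columns else 0
  res
}

#' Overlap-align two sequences
#'
#' Best ends-free (dovetail or containment) alignment of `b` against `a`,
#' considering both orientations of `b`, with unit gap cost. The overlap is
#' accepted iff it spans at least `min_overlap` aligned columns at
#' `min_identity` percent identity or better (gaps count as mismatches).
#'
#' @param a,b sequence strings.
#' @param min_overlap minimum aligned columns (bp) to accept.
#' @param min_identity minimum percent identity over the aligned columns.
#' @return list with `accepted`, `overlap_length`, `identity`,
#'   `relative_orientation` (`"same"` or `"revcomp"`), `offset` (start of the
#'   aligned region in `a` minus start in `b`, in original coordinates) and
#'   the alignment details used by the merger.
#' @export
overlap_align <- function(a, b, min_overlap = 80L, min_identity = 95) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  fwd <- .ov_aln(a, b)
  brc <- revcomp(b)
  rev <- .ov_aln(a, brc)
  use_rev <- rev$score > fwd$score
  best <- if (use_rev) rev else fwd
  list(accepted = best$columns >= min_overlap && best$identity >= min_identity,
       overlap_length = best$columns,
       identity = best$identity,
       relative_orientation = if (use_rev) "revcomp" else "same",
       offset = best$p_start - best$s_start,
       b_oriented = if (use_rev) brc else b,
       detail = best)
}

# Merge sequence b (already oriented) into a given an accepted overlap.
# Mismatching columns take the base of the longer sequence (tie: a).
merge_overlap <- function(a, b, detail) {
  ap <- strsplit(detail$ap, "", fixed = TRUE)[[1]]
  as_ <- strsplit(detail$as, "", fixed = TRUE)[[1]]
  prefer_a <- nchar(a) >= nchar(b)
  core <- ifelse(ap == "-", as_,
          ifelse(as_ == "-", ap,
          ifelse(ap == as_, ap, if (prefer_a) ap else as_)))
  left <- if (detail$p_start > 1) {
    substr(a, 1, detail$p_start - 1)
  } else if (detail$s_start > 1) {
    substr(b, 1, detail$s_start - 1)
  } else ""
  right <- if (detail$p_end < nchar(a)) {
    substr(a, detail$p_end + 1, nchar(a))
  } else if (detail$s_end < nchar(b)) {
    substr(b, detail$s_end + 1, nchar(b))
  } else ""
  paste0(left, paste(core, collapse = ""), right)
}

# all k-mers of a sequence (and its reverse complement when both = TRUE)
.kmers <- function(s, k = 12L, both = FALSE) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1L), k:n)
  if (both) km <- c(km, substring(revcomp(s), 1:(n - k + 1L), k:n))
  unique(km)
}

# Lossless seed prefilter: any >=80-column overlap at >=95% identity contains
# an exact 12-mer (<= cols/20 mismatches+gaps cut it into runs, the longest
# >= 0.95*cols/(cols/20 + 1) >= 15 for cols >= 80).
.share_seed <- function(kmers_a, kmers_b12) {
  any(kmers_b12 %in% kmers_a)
}

#' Greedy overlap assembly
#'
#' Reads are processed by descending length (ties by id); each read joins the
#' first existing cluster whose current consensus yields an accepted overlap,
#' updating the consensus, otherwise it founds a new cluster. After every
#' join, clusters whose consensi now overlap are merged to a fixpoint, so
#' membership equals the connected components of the overlap graph on clean
#' instances. Clusters with one member are singletons.
#'
#' @param seqs sequence data.frame or named character vector (unique ids).
#' @param min_overlap,min_identity acceptance thresholds (see
#'   [overlap_align()]).
#' @return object of class `assembly`: `contigs` (data.frame `contig_id`,
#'   `consensus`, `n_members`), `singletons` (data.frame `id`, `sequence`),
#'   `membership` (data.frame `id`, `contig_id`, `"SINGLETON"` for unplaced
#'   reads), and the thresholds used.
#' @export
greedy_assemble <- function(seqs, min_overlap = 80L, min_identity = 95) {
  seqs <- as_seq_df(seqs)
  if (anyDuplicated(seqs$id)) .stopf("duplicate sequence id: %s",
                                     seqs$id[duplicated(seqs$id)][1])
  ord <- order(-nchar(seqs$sequence), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  clusters <- list()  # each: list(consensus, members, kmers)
  for (i in seq_len(nrow(seqs))) {
    rid <- seqs$id[i]
    rseq <- seqs$sequence[i]
    rkm <- .kmers(rseq, both = TRUE)
    joined <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (!.share_seed(cl$kmers, rkm)) next
      res <- overlap_align(cl$consensus, rseq, min_overlap, min_identity)
      if (!res$accepted) next
      cl$consensus <- merge_overlap(cl$consensus, res$b_oriented, res$detail)
      cl$members <- c(cl$members, rid)
      cl$kmers <- .kmers(cl$consensus)
      clusters[[ci]] <- cl
      clusters <- .merge_clusters(clusters, ci, min_overlap, min_identity)
      joined <- TRUE
      break
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <-
        list(consensus = rseq, members = rid, kmers = .kmers(rseq))
    }
  }
  .as_assembly(clusters, min_overlap, min_identity)
}

# after cluster `ci` changed, merge any cluster overlapping it, repeatedly
.merge_clusters <- function(clusters, ci, min_overlap, min_identity) {
  repeat {
    merged <- FALSE
    cl <- clusters[[ci]]
    j <- 1L
    while (j <= length(clusters)) {
      if (j != ci) {
        other <- clusters[[j]]
        okm <- .kmers(other$consensus, both = TRUE)
        if (.share_seed(cl$kmers, okm)) {
          res <- overlap_align(cl$consensus, other$consensus,
                               min_overlap, min_identity)
          if (res$accepted) {
            cl$consensus <- merge_overlap(cl$consensus, res$b_oriented,
                                          res$detail)
            cl$members <- c(cl$members, other$members)
            cl$kmers <- .kmers(cl$consensus)
            clusters[[ci]] <- cl
            clusters[[j]] <- NULL
            if (j < ci) ci <- ci - 1L
            merged <- TRUE
            next
          }
        }
      }
      j <- j + 1L
    }
    if (!merged) break
  }
  clusters
}

.as_assembly <- function(clusters, min_overlap, min_identity) {
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  ctg <- clusters[sizes >= 2L]
  sng <- clusters[sizes == 1L]
  contigs <- data.frame(
    contig_id = if (length(ctg)) sprintf("ctg%d", seq_along(ctg)) else character(0),
    consensus = vapply(ctg, `[[`, character(1), "consensus"),
    n_members = vapply(ctg, function(cl) length(cl$members), integer(1)),
    stringsAsFactors = FALSE)
  singletons <- data.frame(
    id = vapply(sng, function(cl) cl$members, character(1)),
    sequence = vapply(sng, `[[`, character(1), "consensus"),
    stringsAsFactors = FALSE)
  membership <- rbind(
    if (length(ctg)) do.call(rbind, lapply(seq_along(ctg), function(i) {
      data.frame(id = ctg[[i]]$members, contig_id = sprintf("ctg%d", i),
                 stringsAsFactors = FALSE)
    })),
    if (nrow(singletons)) data.frame(id = singletons$id,
                                     contig_id = "SINGLETON",
                                     stringsAsFactors = FALSE))
  if (is.null(membership)) {
    membership <- data.frame(id = character(), contig_id = character(),
                             stringsAsFactors = FALSE)
  }
  structure(list(contigs = contigs, singletons = singletons,
                 membership = membership,
                 min_overlap = min_overlap, min_identity = min_identity),
            class = "assembly")
}

#' Non-redundant sequences of an assembly
#'
#' Contig consensi plus singleton reads, the "non-redundant sequence set" the
#' survey's downstream analyses run on.
#'
#' @param asm an `assembly` object.
#' @return sequence data.frame (`id`, `sequence`).
#' @export
assembly_sequences <- function(asm) {
  rbind(data.frame(id = asm$contigs$contig_id,
                   sequence = asm$contigs$consensus,
                   stringsAsFactors = FALSE),
        asm$singletons)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: %d contigs (%d reads), %d singletons [overlap >= %d, identity >= %g%%]\n",
              nrow(x$contigs), sum(x$contigs$n_members),
              nrow(x$singletons), x$min_overlap, x$min_identity))
  invisible(x)
}

#' Cross-assemble two assemblies
#'
#' The contig consensi and singletons of both assemblies are pooled as plain
#' sequences (their id spaces must be disjoint) and re-clustered with the
#' same algorithm; the redundancy report counts how many sequences and bp the
#' joint clustering removed.
#'
#' @param asm1,asm2 `assembly` objects with disjoint sequence ids.
#' @param min_overlap,min_identity acceptance thresholds.
#' @param prefix1,prefix2 prefixes applied to contig ids of each input so the
#'   pooled ids stay unique.
#' @return list with `assembly` (the joint `assembly` object) and
#'   `redundancy`: `n_in`, `n_out`, `n_removed`, `bp_in`, `bp_out`,
#'   `bp_removed`.
#' @export
cross_assemble <- function(asm1, asm2, min_overlap = 80L, min_identity = 95,
                           prefix1 = "a1.", prefix2 = "a2.") {
  s1 <- assembly_sequences(asm1)
  s1$id[grepl("^ctg", s1$id)] <- paste0(prefix1, s1$id[grepl("^ctg", s1$id)])
  s2 <- assembly_sequences(asm2)
  s2$id[grepl("^ctg", s2$id)] <- paste0(prefix2, s2$id[grepl("^ctg", s2$id)])
  if (length(intersect(s1$id, s2$id))) {
    .stopf("id collision between assemblies: %s",
           intersect(s1$id, s2$id)[1])
  }
  pooled <- rbind(s1, s2)
  joint <- greedy_assemble(pooled, min_overlap, min_identity)
  out <- assembly_sequences(joint)
  list(assembly = joint,
       redundancy = list(
         n_in = nrow(pooled), n_out = nrow(out),
         n_removed = nrow(pooled) - nrow(out),
         bp_in = sum(nchar(pooled$sequence)),
         bp_out = sum(nchar(out$sequence)),
         bp_removed = sum(nchar(pooled$sequence)) - sum(nchar(out$sequence))))
}
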