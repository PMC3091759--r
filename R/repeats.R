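# Repeat-annotation classification into a transposable-element taxonomy,
# summary ratios, and masking of repeat spans ahead of homology searches.
# The counting unit is the annotation row (a homology match), not a
# reconstructed element; fragmented elements are not defragmented.

#' Load a repeat taxonomy
#'
#' The taxonomy is a flat table of leaves: `class` (Retroelements,
#' DNA_transposons, Rolling_circles, Telomere, rRNA), `subclass` (e.g. LTR,
#' LINES; `"."` when unused), `element` (leaf label) and `pattern`, a
#' case-insensitive regex matched against the annotation's family and class
#' labels, in row order (first match wins). The default shipped table covers
#' the conventional plant TE families (Ty1/Copia, Ty3/Gypsy, L1,
#' hobo-Activator, En-Spm, MuDR, Harbinger, Helitron) plus rRNA and
#' telomere-related sequences; it is editable config because label
#' conventions are screening-tool dependent.
#'
#' @param path taxonomy TSV; default is the table shipped with the package.
#' @return data.frame of class `repeat_taxonomy`.
#' @export
repeat_taxonomy <- function(path = system.file("extdata", "repeat_taxonomy.tsv",
                                               package = "beskit")) {
  tx <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("class", "subclass", "element", "pattern") %in% names(tx)))
  class(tx) <- c("repeat_taxonomy", "data.frame")
  tx
}

# classes counted as transposable elements
.te_classes <- c("Retroelements", "DNA_transposons", "Rolling_circles")

#' Classify one repeat annotation
#'
#' The family label (and, as fallback, the class label) is matched against
#' the taxonomy patterns in row order. Labels matching nothing fall back on
#' the declared class: an unknown LTR element maps to
#' Retroelements/LTR/Unclassified, an unknown DNA transposon to
#' DNA_transposons/Unclassified, anything else to the global Unclassified
#' bucket.
#'
#' @param family_label annotation family string.
#' @param class_label annotation class string (e.g. `"LTR/Copia"`).
#' @param taxonomy a [repeat_taxonomy()].
#' @return character vector `(class, subclass, element)`; subclass is `"."`
#'   when unused.
#' @export
classify_repeat <- function(family_label, class_label = "",
                            taxonomy = repeat_taxonomy()) {
  probe <- paste(family_label, class_label)
  for (i in seq_len(nrow(taxonomy))) {
    if (grepl(taxonomy$pattern[i], probe, ignore.case = TRUE, perl = TRUE)) {
      return(c(class = taxonomy$class[i], subclass = taxonomy$subclass[i],
               element = taxonomy$element[i]))
    }
  }
  if (grepl("LTR", probe, ignore.case = TRUE)) {
    return(c(class = "Retroelements", subclass = "LTR",
             element = "Unclassified"))
  }
  if (grepl("LINE", probe, ignore.case = TRUE)) {
    return(c(class = "Retroelements", subclass = "LINES",
             element = "Unclassified"))
  }
  if (grepl("DNA", probe, ignore.case = TRUE)) {
    return(c(class = "DNA_transposons", subclass = ".",
             element = "Unclassified"))
  }
  c(class = "Unclassified", subclass = ".", element = "Unclassified")
}

#' Classify a table of repeat annotations
#'
#' @param hits annotation data.frame from [read_repeat_annotations()].
#' @param taxonomy a [repeat_taxonomy()].
#' @return `hits` with `class`, `subclass`, `element` columns appended.
#' @export
classify_repeats <- function(hits, taxonomy = repeat_taxonomy()) {
  if (nrow(hits) == 0) {
    hits$class <- character(0)
    hits$subclass <- character(0)
    hits$element <- character(0)
    return(hits)
  }
  cls <- t(vapply(seq_len(nrow(hits)), function(i) {
    classify_repeat(hits$family_label[i],
                    if (is.null(hits$class_label)) "" else hits$class_label[i],
                    taxonomy)
  }, character(3)))
  hits$class <- cls[, 1]
  hits$subclass <- cls[, 2]
  hits$element <- cls[, 3]
  hits
}

#' Summarize classified repeat annotations
#'
#' Transposable elements (TEs) are Retroelements + DNA transposons + rolling
#' circles. Ratios follow the survey conventions: retroelement fraction of
#' TEs, Ty1/Copia and Ty3/Gypsy shares of retroelements, En-Spm share of DNA
#' transposons, the class I/class II ratio, and the Copia/Gypsy ratio.
#' Percentages are rounded half-up to 1 decimal.
#'
#' @param hits classified annotation table from [classify_repeats()].
#' @param total_bp total bp of the annotated sequence set (> 0).
#' @param masked_bp optional masked bp (e.g. from [mask_sequences()]).
#' @return object of class `repeat_summary`.
#' @export
summarize_repeats <- function(hits, total_bp, masked_bp = NA_integer_) {
  if (total_bp <= 0) .stopf("total_bp must be positive")
  counts <- if (nrow(hits)) {
    aggregate(list(count = seq_len(nrow(hits))),
              by = list(class = hits$class, subclass = hits$subclass,
                        element = hits$element),
              FUN = length)
  } else {
    data.frame(class = character(), subclass = character(),
               element = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  class_counts <- setNames(
    vapply(unique(counts$class),
           function(cl) sum(counts$count[counts$class == cl]), integer(1)),
    unique(counts$class))
  n_retro <- sum(class_counts[names(class_counts) == "Retroelements"])
  n_dna <- sum(class_counts[names(class_counts) == "DNA_transposons"])
  n_rc <- sum(class_counts[names(class_counts) == "Rolling_circles"])
  te <- n_retro + n_dna + n_rc
  leaf <- function(el) sum(counts$count[counts$element == el])
  n_copia <- leaf("Ty1/Copia")
  n_gypsy <- leaf("Ty3/Gypsy")
  pct <- function(a, b) if (b > 0) round_half_up(100 * a / b, 1) else NA_real_
  structure(list(
    counts = counts[order(counts$class, counts$subclass, counts$element), ],
    class_counts = class_counts,
    n_total = sum(counts$count),
    te_count = te,
    te_pct_of_repeats = pct(te, sum(counts$count)),
    retro_fraction = pct(n_retro, te),
    copia_pct_of_retro = pct(n_copia, n_retro),
    gypsy_pct_of_retro = pct(n_gypsy, n_retro),
    enspm_pct_of_dna = pct(leaf("En-Spm"), n_dna),
    ty1_ty3_ratio = if (n_gypsy > 0) round_half_up(n_copia / n_gypsy, 1)
                    else NA_real_,
    class_ratio = if (n_dna > 0) round_half_up(n_retro / n_dna, 1)
                  else NA_real_,
    masked_bp = masked_bp,
    masked_pct = if (!is.na(masked_bp)) pct(masked_bp, total_bp) else NA_real_,
    total_bp = total_bp
  ), class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("repeat summary: %d annotations, %d TEs (retro %.1f%% of TEs)\n",
              x$n_total, x$te_count, x$retro_fraction))
  cat(sprintf("  Ty1/Copia %.1f%%, Ty3/Gypsy %.1f%% of retroelements; En-Spm %.1f%% of DNA TEs\n",
              x$copia_pct_of_retro, x$gypsy_pct_of_retro, x$enspm_pct_of_dna))
  invisible(x)
}

#' Mask repeat spans in sequences
#'
#' `"hard"` masking replaces each annotated span with `N`; `"soft"` masking
#' lower-cases it. `masked_bp` is the length of the union of spans per
#' sequence (overlaps counted once).
#'
#' @param seqs sequence data.frame or named character vector.
#' @param hits annotation table with `seq_id`, `start`, `end` (0-based
#'   half-open) within the sequences.
#' @param mode `"hard"` or `"soft"`.
#' @return list with `seqs` (masked sequence data.frame) and `masked_bp`.
#' @export
mask_sequences <- function(seqs, hits, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  seqs <- as_seq_df(seqs)
  masked_bp <- 0L
  out <- seqs$sequence
  for (i in seq_len(nrow(seqs))) {
    h <- hits[hits$seq_id == seqs$id[i], , drop = FALSE]
    if (nrow(h) == 0) next
    if (any(h$end > nchar(out[i]) | h$start < 0)) {
      .stopf("repeat span beyond end of sequence '%s'", seqs$id[i])
    }
    spans <- IRanges::reduce(IRanges::IRanges(h$start + 1L, h$end))
    masked_bp <- masked_bp + sum(IRanges::width(spans))
    s <- out[i]
    for (j in seq_along(spans)) {
      a <- BiocGenerics::start(spans)[j]
      b <- BiocGenerics::end(spans)[j]
      piece <- if (mode == "hard") strrep("N", b - a + 1L)
               else tolower(substr(s, a, b))
      substr(s, a, b) <- piece
    }
    out[i] <- s
  }
  seqs$sequence <- out
  list(seqs = seqs, masked_bp = masked_bp)
}
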