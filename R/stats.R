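# Survey arithmetic: genome coverage in clone equivalents, GC content,
# read-set length statistics, and the structured survey report. Percentages
# and coverage are rounded half-up to 1 decimal; integer counts are never
# rounded.

#' Genomic coverage of a BAC library
#'
#' Coverage in genome equivalents: true clones (clones times the true-clone
#' fraction, rounded) times the mean insert size, divided by the haploid
#' genome size. Note that libraries whose published coverage was derived
#' with other constants can differ from this arithmetic in the last decimal;
#' the value returned is always the recomputation.
#'
#' @param n_clones number of clones in the library.
#' @param true_fraction fraction of clones carrying genuine nuclear inserts.
#' @param mean_insert_kb mean insert size in kb.
#' @param genome_mb haploid genome size in Mb.
#' @return coverage in genome equivalents, rounded half-up to 1 decimal.
#' @export
genomic_coverage <- function(n_clones, true_fraction, mean_insert_kb,
                             genome_mb) {
  if (n_clones <= 0 || true_fraction <= 0 || mean_insert_kb <= 0 ||
      genome_mb <= 0) {
    .stopf("all coverage inputs must be positive")
  }
  true_clones <- round(n_clones * true_fraction)
  round_half_up(true_clones * mean_insert_kb / (genome_mb * 1000), 1)
}

#' GC content of a sequence set
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` and other ambiguity codes are
#' excluded from the denominator.
#'
#' @param seqs sequence data.frame or named character vector.
#' @param digits decimals (half-up); `Inf` for the unrounded value.
#' @return GC percent.
#' @export
gc_content <- function(seqs, digits = 1) {
  seqs <- as_seq_df(seqs)
  af <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(toupper(seqs$sequence)))
  af <- colSums(af)
  gc <- af[["G"]] + af[["C"]]
  at <- af[["A"]] + af[["T"]]
  if (gc + at == 0) .stopf("no unambiguous bases in input")
  pct <- 100 * gc / (gc + at)
  if (is.finite(digits)) round_half_up(pct, digits) else pct
}

#' Length statistics of a read set
#'
#' @param lengths integer vector of read lengths in bp (or a data.frame with
#'   a `sequence` column).
#' @param genome_mb optional genome size for the sequenced-fraction percent.
#' @return list: `count`, `min`, `max`, `mean` (bp), `total_mb` (1 decimal),
#'   `genome_fraction_pct` (1 decimal, 0 when empty), `total_bp`.
#' @export
total_length_stats <- function(lengths, genome_mb = NA_real_) {
  if (is.data.frame(lengths)) lengths <- nchar(lengths$sequence)
  n <- length(lengths)
  total <- sum(lengths)
  list(count = n,
       min = if (n) min(lengths) else 0L,
       max = if (n) max(lengths) else 0L,
       mean = if (n) mean(lengths) else 0,
       total_bp = total,
       total_mb = round_half_up(total / 1e6, 1),
       genome_fraction_pct = if (!is.na(genome_mb) && n > 0)
         round_half_up(100 * total / (genome_mb * 1e6), 1) else 0)
}

#' Assemble a structured survey report
#'
#' Collects the section outputs of the other modules into one deterministic,
#' serializable report. Mandatory sections must be present; a section can be
#' deliberately omitted by passing `list(absent = TRUE)`, which is recorded
#' as absent rather than zero.
#'
#' @param sequence_stats,ssr,repeats,coding,synteny section objects (the
#'   outputs of [total_length_stats()], [summarize_ssrs()],
#'   [summarize_repeats()], [coding_fraction()], [synteny_summary()]), or
#'   `list(absent = TRUE)`.
#' @param config named list of run parameters and seeds embedded verbatim.
#' @return object of class `survey_report`.
#' @export
build_report <- function(sequence_stats, ssr, repeats, coding, synteny,
                         config = list()) {
  sections <- list(sequence_stats = sequence_stats, ssr = ssr,
                   repeats = repeats, coding = coding, synteny = synteny)
  missing <- names(sections)[vapply(sections, is.null, logical(1))]
  if (length(missing)) {
    .stopf("missing mandatory report section: %s", missing[1])
  }
  structure(list(sections = sections, config = config,
                 package_version = as.character(utils::packageVersion("beskit"))),
            class = "survey_report")
}

#' Serialize a survey report to JSON
#'
#' Identical inputs produce byte-identical output (no timestamps).
#'
#' @param report a `survey_report`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "synteny_summary")) x$loci <- NULL
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
    }
    x
  }
  json <- jsonlite::toJSON(strip(unclass(report)), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null",
                           dataframe = "columns", force = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.survey_report <- function(x, ...) {
  cat("survey report (beskit", x$package_version, ")\n")
  for (nm in names(x$sections)) {
    s <- x$sections[[nm]]
    status <- if (is.list(s) && isTRUE(s$absent)) "absent" else "present"
    cat(sprintf("  %-15s %s\n", nm, status))
  }
  invisible(x)
}
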