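# Published reference counts from a melon BAC-end-sequencing survey, shipped
# as plain-text tables, and the recomputation of every derived statistic the
# survey printed from those counts. The recomputations run through the same
# summary operations the pipeline applies to fresh data, so they double as a
# check of the report arithmetic.

#' Load a reference survey count table
#'
#' @param name one of `"library"`, `"bes"`, `"assembly"`, `"ssr"`,
#'   `"ssr_bins"`, `"ssr_totals"`, `"repeat"`, `"est"`, `"synteny"`,
#'   `"constants"`.
#' @return data.frame of the shipped counts.
#' @export
survey_counts <- function(name = c("library", "bes", "assembly", "ssr",
                                   "ssr_bins", "ssr_totals", "repeat",
                                   "est", "synteny", "constants")) {
  name <- match.arg(name)
  file <- c(library = "library_counts.tsv", bes = "bes_counts.tsv",
            assembly = "assembly_counts.tsv", ssr = "ssr_counts.tsv",
            ssr_bins = "ssr_length_bins.tsv", ssr_totals = "ssr_totals.tsv",
            "repeat" = "repeat_counts.tsv", est = "est_counts.tsv",
            synteny = "synteny_counts.tsv", constants = "constants.tsv")[name]
  path <- system.file("extdata", "survey", file, package = "beskit")
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

.survey_constant <- function(key) {
  k <- survey_counts("constants")
  as.numeric(k$value[k$key == key])
}

#' Recompute the survey's derived statistics from its reference counts
#'
#' Every ratio, density, coverage and estimate the survey derived from its
#' summary tables is recomputed here from the shipped counts, flowing
#' through the package's own summary operations (tier expansion through
#' [coding_fraction()], repeat rows through [classify_repeats()] and
#' [summarize_repeats()], coverage through [genomic_coverage()], and so on).
#' Values are on the scale the survey printed (percentages as percentages).
#'
#' @return named list of recomputed statistics.
#' @export
recompute_survey_stats <- function() {
  out <- list()
  cons <- survey_counts("constants")

  # --- libraries: coverage in genome equivalents -------------------------
  lib <- survey_counts("library")
  for (i in seq_len(nrow(lib))) {
    out[[paste0(tolower(lib$library[i]), "_genomic_coverage")]] <-
      genomic_coverage(lib$n_clones[i], lib$true_fraction[i],
                       lib$insert_kb[i], lib$genome_mb[i])
  }

  # --- BES read sets ------------------------------------------------------
  bes <- survey_counts("bes")
  all <- bes[bes$set == "ALL", ]
  out$paired_bes_pct <- round_half_up(100 * all$n_paired / all$n_bes, 1)
  out$total_bes_mb <- round_half_up(all$n_bes * all$len_mean / 1e6, 1)
  out$genome_pct_sequenced <- round_half_up(
    100 * all$n_bes * all$len_mean / (.survey_constant("genome_mb") * 1e6), 1)

  # --- assembly / cross-assembly accounting ------------------------------
  asm <- survey_counts("assembly")
  per_lib <- asm[asm$set != "MERGED", ]
  merged <- asm[asm$set == "MERGED", ]
  out$nonredundant_total <- merged$n_contigs + merged$n_singletons
  out$cross_assembly_redundancy <- sum(per_lib$n_seq) - merged$n_seq

  # --- microsatellites ----------------------------------------------------
  tot <- survey_counts("ssr_totals")
  mtot <- tot[tot$set == "MERGED", ]
  out$ssr_density_kb <- ssr_density_kb(mtot$n_ssrs, mtot$total_sequence_bp)
  out$ssr_pct_of_sequence <- round_half_up(
    100 * mtot$total_ssr_bp / mtot$total_sequence_bp, 1)
  bins <- survey_counts("ssr_bins")
  out$ssr_class1_count <- sum(bins$merged[bins$bin_lo > 20])
  ssr <- survey_counts("ssr")
  unit_n <- vapply(1:6, function(u) sum(ssr$merged[ssr$unit == u]),
                   numeric(1))
  out$ssr_mono_pct <- round_half_up(100 * unit_n[1] / mtot$n_ssrs, 1)
  out$ssr_di_pct <- round_half_up(100 * unit_n[2] / mtot$n_ssrs, 1)
  out$ssr_tri_pct <- round_half_up(100 * unit_n[3] / mtot$n_ssrs, 1)
  out$ssr_polyA_pct_of_mono <- round_half_up(
    100 * ssr$merged[ssr$motif_class == "A"] / unit_n[1], 1)

  # --- repeats: expand counts to rows, classify, summarize ---------------
  rep_counts <- survey_counts("repeat")
  fam_label <- c("Ty1/Copia" = "Copia-SYN", "Ty3/Gypsy" = "Gypsy-SYN",
                 "L1" = "L1-SYN", "hobo-Activator" = "hAT-SYN",
                 "En-Spm" = "EnSpm-SYN", "MuDR" = "MuDR-SYN",
                 "Harbinger" = "Harbinger-SYN", "Helitron" = "Helitron-SYN",
                 "Telomere-related" = "telomeric-SYN",
                 "Small_subunit" = "18S_rRNA", "Large_subunit" = "25S_rRNA",
                 "45S_ITS" = "45S_ITS_rRNA", "Unclassified" = "unknown")
  cls_label <- c(Retroelements = "LTR", DNA_transposons = "DNA",
                 Rolling_circles = "RC", Telomere = "Satellite",
                 rRNA = "rRNA")
  idx <- rep(seq_len(nrow(rep_counts)), rep_counts$count)
  rows <- data.frame(
    seq_id = "ref", start = 0L, end = 1L, strand = "+",
    family_label = unname(fam_label[rep_counts$element[idx]]),
    class_label = unname(cls_label[rep_counts$class[idx]]),
    stringsAsFactors = FALSE)
  sub <- rep_counts$subclass[idx]
  lines <- rep_counts$element[idx] == "Unclassified" & sub == "LINES"
  rows$class_label[lines] <- "LINE"
  rsum <- summarize_repeats(classify_repeats(rows), total_bp = 1e6)
  out$retro_pct_of_te <- rsum$retro_fraction
  out$copia_pct_of_retro <- rsum$copia_pct_of_retro
  out$gypsy_pct_of_retro <- rsum$gypsy_pct_of_retro
  out$enspm_pct_of_dna <- rsum$enspm_pct_of_dna

  # --- coding tiers: expand counts to assignments ------------------------
  est <- survey_counts("est")
  n_total <- .survey_constant("n_nonredundant")
  tier <- rep(est$tier, est$low_hits)
  high <- unlist(lapply(seq_len(nrow(est)), function(i) {
    c(rep(TRUE, est$high_hits[i]), rep(FALSE, est$low_hits[i] - est$high_hits[i]))
  }))
  assignments <- data.frame(
    query_id = sprintf("q%d", seq_along(tier)), tier = tier, high = high,
    stringsAsFactors = FALSE)
  ce <- coding_fraction(assignments, n_total, precedence = est$tier)
  out$coding_pct_low <- ce$low_total_pct
  out$coding_pct_high <- ce$high_total_pct
  melon_low <- est$low_hits[est$tier == "melon"]
  melon_high <- est$high_hits[est$tier == "melon"]
  out$melon_share_of_hits_low_pct <-
    round_half_up(100 * melon_low / ce$low_total, 1)
  out$melon_share_of_hits_high_pct <-
    round_half_up(100 * melon_high / ce$high_total, 1)
  n_uni <- .survey_constant("n_unigenes")
  out$transcriptome_size_low <- transcriptome_size(melon_low, ce$low_total,
                                                   n_uni)
  out$transcriptome_size_high <- transcriptome_size(melon_high, ce$high_total,
                                                    n_uni)

  # --- paired-BES synteny funnel -----------------------------------------
  syn <- survey_counts("synteny")
  g <- function(genome) syn[syn$genome == genome, ]
  out$cucumber_mean_loci_per_pair <-
    mean_loci_per_pair(g("cucumber")$n_loci, g("cucumber")$pairs_same_subject)
  out$arabidopsis_mean_loci_per_pair <-
    mean_loci_per_pair(g("arabidopsis")$n_loci,
                       g("arabidopsis")$pairs_same_subject)
  out$cucumber_window_pct <- round_half_up(
    100 * g("cucumber")$pairs_in_window / g("cucumber")$pairs_same_subject, 0)
  out$poplar_orientation_pct <- round_half_up(
    100 * g("poplar")$pairs_collinear / g("poplar")$pairs_in_window, 0)
  out$cucumber_orientation_pct <- round_half_up(
    100 * g("cucumber")$pairs_collinear / g("cucumber")$pairs_in_window, 0)
  out$cucumber_collinear_pct_of_pairs <- round_half_up(
    100 * g("cucumber")$pairs_collinear / g("cucumber")$n_pairs_total, 0)
  out$poplar_collinear_pct_of_pairs <- round_half_up(
    100 * g("poplar")$pairs_collinear / g("poplar")$n_pairs_total, 2)
  out$arabidopsis_collinear_pct_of_pairs <- round_half_up(
    100 * g("arabidopsis")$pairs_collinear / g("arabidopsis")$n_pairs_total, 2)

  out
}
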