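# Synthetic genomes, BAC libraries and related target genomes, with a ledger
# of every planted feature. The generator's defaults emulate the surveyed
# genome: 35.2% GC background, microsatellite motif proportions and repeat
# taxonomy proportions taken from the reference count tables, reads of
# 50-879 bp around a 543 bp mean, and insert sizes around 120-139 kb.
# Everything is a pure function of (inputs, seed).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# i.i.d. background bases at a given GC content
random_dna <- function(n, gc = 0.352) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Feature request for a synthetic genome
#'
#' Defaults reproduce the surveyed genome's feature mix: microsatellite
#' motif-class proportions and repeat-element proportions from the shipped
#' reference counts, 35.2% GC background.
#'
#' @param n_ssrs,n_repeats,n_genes number of features to plant.
#' @param ssr_max_len maximum total SSR length (nt); minimum is the
#'   detection threshold for the drawn unit.
#' @param repeat_len,gene_len length ranges (bp).
#' @param gc background GC fraction.
#' @param ssr_weights optional data.frame (`motif_class`, `weight`); default
#'   from the reference counts (named classes only).
#' @param repeat_weights optional data.frame (`class`, `subclass`,
#'   `element`, `weight`); default from the reference counts.
#' @return list of class `feature_request`.
#' @export
feature_request <- function(n_ssrs = 0L, n_repeats = 0L, n_genes = 0L,
                            ssr_max_len = 40L, repeat_len = c(100L, 400L),
                            gene_len = c(300L, 1200L), gc = 0.352,
                            ssr_weights = NULL, repeat_weights = NULL) {
  if (is.null(ssr_weights)) {
    ssr <- survey_counts("ssr")
    ssr <- ssr[ssr$motif_class != "other", ]
    ssr_weights <- data.frame(motif_class = ssr$motif_class,
                              weight = ssr$merged, stringsAsFactors = FALSE)
  }
  if (is.null(repeat_weights)) {
    rc <- survey_counts("repeat")
    repeat_weights <- data.frame(class = rc$class, subclass = rc$subclass,
                                 element = rc$element, weight = rc$count,
                                 stringsAsFactors = FALSE)
  }
  structure(list(n_ssrs = n_ssrs, n_repeats = n_repeats, n_genes = n_genes,
                 ssr_max_len = ssr_max_len, repeat_len = repeat_len,
                 gene_len = gene_len, gc = gc, ssr_weights = ssr_weights,
                 repeat_weights = repeat_weights),
            class = "feature_request")
}

# synthetic family label and screening-style class label for a taxonomy leaf
.syn_family <- function(class, subclass, element, i) {
  base <- c("Ty1/Copia" = "Copia", "Ty3/Gypsy" = "Gypsy", "L1" = "L1",
            "hobo-Activator" = "hAT", "En-Spm" = "EnSpm", "MuDR" = "MuDR",
            "Harbinger" = "Harbinger", "Helitron" = "Helitron",
            "Telomere-related" = "Telomeric", "Small_subunit" = "18S_rRNA",
            "Large_subunit" = "25S_rRNA", "45S_ITS" = "45S_ITS_rRNA")
  cls <- c(Retroelements = "LTR", DNA_transposons = "DNA",
           Rolling_circles = "RC", Telomere = "Satellite", rRNA = "rRNA")
  b <- base[element]
  if (is.na(b)) b <- "Unknown"
  cl <- cls[class]
  if (!is.na(cl) && class == "Retroelements" && subclass == "LINES") cl <- "LINE"
  c(family = sprintf("%s-%d_SYN", b, i),
    class = if (is.na(cl)) "Unknown" else unname(cl))
}

# choose a non-overlapping placement (1-based start) for a feature of length
# flen on chromosome of length n, >= gap bp away from occupied spans and >= 2
# bp from either sequence end; errors when packing fails
.place <- function(occ, n, flen, gap = 30L, tries = 200L) {
  lo <- 2L
  hi <- n - flen - 1L
  if (hi < lo) .stopf("infeasible packing: feature of %d bp in %d bp", flen, n)
  for (t in seq_len(tries)) {
    s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    e <- s + flen - 1L
    if (nrow(occ) == 0 ||
        all(s > occ$end + gap | e < occ$start - gap)) {
      return(c(start = s, end = e))
    }
  }
  # dense packing: enumerate the free intervals and draw a start uniformly
  # from the positions that actually fit
  bounds <- occ[order(occ$start), , drop = FALSE]
  free_lo <- c(lo, bounds$end + gap + 1L)
  free_hi <- c(bounds$start - gap - 1L - flen + 1L, hi)
  ok <- free_hi >= free_lo
  if (!any(ok)) {
    .stopf("infeasible packing: no room for a feature of %d bp", flen)
  }
  free_lo <- free_lo[ok]
  free_hi <- free_hi[ok]
  w <- free_hi - free_lo + 1L
  iv <- sample.int(length(w), 1L, prob = w)
  s <- free_lo[iv] + sample.int(w[iv], 1L) - 1L
  c(start = s, end = s + flen - 1L)
}

# pick a replacement base not in `forbidden`, deterministically
.fresh_base <- function(forbidden) {
  setdiff(c("A", "C", "G", "T"), forbidden)[1]
}

#' Simulate a genome with planted features
#'
#' Background bases are i.i.d. at the requested GC. Planted microsatellites
#' get flank bases chosen to break the repeat period, so each is a maximal
#' run exactly as recorded; chance microsatellites arising in the background
#' (or inside planted repeat/gene fragments) are then disrupted by point
#' changes until a scan finds exactly the ledger, giving noise-free ground
#' truth. Restriction sites (BamHI, GGATCC) are located after generation and
#' recorded per pseudomolecule.
#'
#' @param n_chrom number of pseudomolecules.
#' @param chrom_len length of each pseudomolecule (bp).
#' @param features a [feature_request()].
#' @param seed integer seed; the output is a pure function of the arguments.
#' @param thresholds SSR thresholds used for the background clean-up.
#' @return object of class `genome_model`: `sequences` (data.frame `id`,
#'   `sequence`) and `ledger` with `ssrs`, `repeats`, `genes`,
#'   `restriction_sites` (0-based positions per pseudomolecule).
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_len = 1e5,
                            features = feature_request(), seed = 1L,
                            thresholds = ssr_thresholds()) {
  .with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    seqs <- lapply(chroms, function(.) random_dna(chrom_len, features$gc))
    names(seqs) <- chroms
    occ <- lapply(chroms, function(.) {
      data.frame(start = integer(), end = integer())
    })
    names(occ) <- chroms
    ssr_rows <- list(); rep_rows <- list(); gene_rows <- list()

    pick_chrom <- function() sample(chroms, 1L,
                                    prob = vapply(seqs, length, numeric(1)))

    # --- microsatellites --------------------------------------------------
    if (features$n_ssrs > 0) {
      w <- features$ssr_weights
      classes <- sample(w$motif_class, features$n_ssrs, replace = TRUE,
                        prob = w$weight)
      for (i in seq_len(features$n_ssrs)) {
        motif <- classes[i]
        k <- nchar(motif)
        min_len <- .ssr_min_len(k, thresholds)
        total <- sample(seq.int(min_len, max(min_len, features$ssr_max_len)), 1L)
        cname <- pick_chrom()
        pos <- .place(occ[[cname]], length(seqs[[cname]]), total)
        unit <- strsplit(motif, "", fixed = TRUE)[[1]]
        run <- rep_len(unit, total)
        s <- pos["start"]; e <- pos["end"]
        seqs[[cname]][s:e] <- run
        # break the period at both flanks so the run is maximal as planted
        seqs[[cname]][s - 1L] <- .fresh_base(seqs[[cname]][s - 1L + k])
        seqs[[cname]][e + 1L] <- .fresh_base(seqs[[cname]][e + 1L - k])
        occ[[cname]] <- rbind(occ[[cname]],
                              data.frame(start = s - 1L, end = e + 1L))
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          seq_id = cname, start = s - 1L, end = as.integer(e),
          unit_length = k, motif = motif, canonical_motif = motif,
          copy_number = total / k, total_length = total,
          stringsAsFactors = FALSE)
      }
    }

    # --- repeat fragments -------------------------------------------------
    if (features$n_repeats > 0) {
      w <- features$repeat_weights
      leaf <- sample(seq_len(nrow(w)), features$n_repeats, replace = TRUE,
                     prob = w$weight)
      for (i in seq_len(features$n_repeats)) {
        flen <- sample(seq.int(features$repeat_len[1], features$repeat_len[2]), 1L)
        cname <- pick_chrom()
        pos <- .place(occ[[cname]], length(seqs[[cname]]), flen)
        frag <- random_dna(flen, 0.40)  # TEs run GC-richer than background
        seqs[[cname]][pos["start"]:pos["end"]] <- frag
        occ[[cname]] <- rbind(occ[[cname]],
                              data.frame(start = pos["start"], end = pos["end"]))
        lab <- .syn_family(w$class[leaf[i]], w$subclass[leaf[i]],
                           w$element[leaf[i]], i)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          seq_id = cname, start = pos["start"] - 1L,
          end = as.integer(pos["end"]), strand = "+",
          family_label = unname(lab["family"]),
          class_label = unname(lab["class"]),
          class = w$class[leaf[i]], subclass = w$subclass[leaf[i]],
          element = w$element[leaf[i]], stringsAsFactors = FALSE)
      }
    }

    # --- gene spans ---------------------------------------------------------
    if (features$n_genes > 0) {
      for (i in seq_len(features$n_genes)) {
        glen <- sample(seq.int(features$gene_len[1], features$gene_len[2]), 1L)
        cname <- pick_chrom()
        pos <- .place(occ[[cname]], length(seqs[[cname]]), glen)
        occ[[cname]] <- rbind(occ[[cname]],
                              data.frame(start = pos["start"], end = pos["end"]))
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = sprintf("gene%d", i), seq_id = cname,
          start = pos["start"] - 1L, end = as.integer(pos["end"]),
          stringsAsFactors = FALSE)
      }
    }

    ssrs <- if (length(ssr_rows)) do.call(rbind, ssr_rows) else
      find_ssrs("")[0, ]
    repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), family_label = character(),
                 class_label = character(), class = character(),
                 subclass = character(), element = character(),
                 stringsAsFactors = FALSE)
    genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(gene_id = character(), seq_id = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)

    # --- disrupt chance microsatellites so the scan matches the ledger ----
    seqs <- .neutralize_chance_ssrs(seqs, ssrs, thresholds)

    # ledger tables in scan order: pseudomolecule, then start
    sort_led <- function(d) {
      d <- d[order(match(d$seq_id, chroms), d$start), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    ssrs <- sort_led(ssrs)
    repeats <- sort_led(repeats)
    genes <- sort_led(genes)

    sequences <- data.frame(
      id = chroms,
      sequence = vapply(seqs, paste, character(1), collapse = ""),
      stringsAsFactors = FALSE)
    sites <- lapply(sequences$sequence, function(s) {
      as.integer(gregexpr("GGATCC", s, fixed = TRUE)[[1]]) - 1L
    })
    sites <- lapply(sites, function(x) x[x >= 0])
    names(sites) <- chroms
    structure(list(sequences = sequences,
                   ledger = list(ssrs = ssrs, repeats = repeats,
                                 genes = genes, restriction_sites = sites),
                   params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                                 gc = features$gc, seed = seed)),
              class = "genome_model")
  })
}

# point-mutate any scanned locus absent from the ledger until the scan finds
# exactly the planted set; mutations stay outside planted SSR spans and
# respect their flank-break bases
.neutralize_chance_ssrs <- function(seqs, ssrs, thresholds) {
  for (iter in 1:25) {
    dirty <- FALSE
    for (cname in names(seqs)) {
      found <- find_ssrs(paste(seqs[[cname]], collapse = ""), cname,
                         thresholds)
      planted <- ssrs[ssrs$seq_id == cname, , drop = FALSE]
      key <- function(d) paste(d$start, d$end, d$unit_length)
      extra <- found[!(key(found) %in% key(planted)), , drop = FALSE]
      if (nrow(extra) == 0) next
      dirty <- TRUE
      for (j in seq_len(nrow(extra))) {
        # candidate positions (1-based), centre first, outside planted spans
        cand <- (extra$start[j] + 1L):extra$end[j]
        cand <- cand[order(abs(cand - (extra$start[j] + extra$end[j]) / 2))]
        in_planted <- rep(FALSE, length(cand))
        for (p in seq_len(nrow(planted))) {
          in_planted <- in_planted |
            (cand > planted$start[p] & cand <= planted$end[p])
        }
        pos <- cand[!in_planted][1]
        if (is.na(pos)) next
        forbidden <- seqs[[cname]][pos]
        for (p in seq_len(nrow(planted))) {
          k <- planted$unit_length[p]
          if (pos == planted$start[p]) {         # left flank-break base
            forbidden <- c(forbidden, seqs[[cname]][pos + k])
          }
          if (pos == planted$end[p] + 1L) {      # right flank-break base
            forbidden <- c(forbidden, seqs[[cname]][pos - k])
          }
        }
        seqs[[cname]][pos] <- .fresh_base(forbidden)
      }
    }
    if (!dirty) break
  }
  seqs
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("synthetic genome: %d pseudomolecule(s), %s bp total; ledger: %d SSRs, %d repeats, %d genes\n",
              nrow(x$sequences),
              format(sum(nchar(x$sequences$sequence)), big.mark = ","),
              nrow(x$ledger$ssrs), nrow(x$ledger$repeats),
              nrow(x$ledger$genes)))
  invisible(x)
}

#' BAC library specification
#'
#' Defaults follow the surveyed libraries: reads of 50-879 bp with mean
#' 543 bp (truncated normal, sd chosen so ~99% of the mass is inside the
#' range), insert sizes normal truncated at +/- 3 sd.
#'
#' @param n_clones number of clones attempted.
#' @param mean_insert,insert_sd insert size distribution (bp).
#' @param method `"random_shear"` (uniform insert starts) or `"restriction"`
#'   (insert boundaries only at ledger restriction sites).
#' @param empty_fraction fraction of clones without a genuine insert; the
#'   number of sequenced clones is `round(n_clones * (1 - empty_fraction))`.
#' @param read_len_min,read_len_max,read_len_mean read length distribution.
#' @param seed integer seed.
#' @return list of class `library_spec`.
#' @export
library_spec <- function(n_clones = 100L, mean_insert = 130000,
                         insert_sd = mean_insert * 0.1,
                         method = c("random_shear", "restriction"),
                         empty_fraction = 0,
                         read_len_min = 50L, read_len_max = 879L,
                         read_len_mean = 543L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(read_len_min >= 1, read_len_min <= read_len_mean,
            read_len_mean <= read_len_max,
            empty_fraction >= 0, empty_fraction < 1)
  structure(list(n_clones = n_clones, mean_insert = mean_insert,
                 insert_sd = insert_sd, method = method,
                 empty_fraction = empty_fraction,
                 read_len_min = read_len_min, read_len_max = read_len_max,
                 read_len_mean = read_len_mean, seed = seed),
            class = "library_spec")
}

.trunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

#' Simulate paired BAC-end reads from a genome
#'
#' The forward read is the first bases of the insert; the reverse read is
#' the reverse complement of its last bases (the two reads of a clone face
#' inward). Random-shear inserts start uniformly; restriction inserts run
#' between two ledger restriction sites whose distance is within 3 sd of the
#' insert-size draw.
#'
#' @param genome a `genome_model`.
#' @param spec a [library_spec()].
#' @param library library label for read ids.
#' @return data.frame of class `bes_pairs`: one row per sequenced clone with
#'   clone/insert coordinates and both reads.
#' @export
simulate_library <- function(genome, spec = library_spec(),
                             library = "SYN") {
  chrom_len <- nchar(genome$sequences$sequence)
  if (spec$mean_insert >= max(chrom_len)) {
    .stopf("mean insert (%d) must be below the pseudomolecule length (%d)",
           spec$mean_insert, max(chrom_len))
  }
  read_sd <- (spec$read_len_max - spec$read_len_min) / 5.16
  .with_seed(spec$seed, {
    n_out <- round(spec$n_clones * (1 - spec$empty_fraction))
    rows <- vector("list", n_out)
    if (spec$method == "restriction") {
      sites <- genome$ledger$restriction_sites
      if (sum(lengths(sites)) == 0) {
        .stopf("restriction library requested but the genome has no restriction sites")
      }
    }
    for (i in seq_len(n_out)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 1000L) {
          .stopf("could not draw a valid insert after 1000 tries (method %s)",
                 spec$method)
        }
        ci <- sample.int(nrow(genome$sequences), 1L, prob = chrom_len)
        len <- chrom_len[ci]
        ins <- .trunc_norm(1L, spec$mean_insert, spec$insert_sd,
                           max(1, spec$mean_insert - 3 * spec$insert_sd),
                           spec$mean_insert + 3 * spec$insert_sd)
        if (spec$method == "random_shear") {
          if (ins >= len) next
          s0 <- sample.int(len - ins, 1L) - 1L   # 0-based insert start
          e0 <- s0 + ins
          break
        } else {
          ss <- genome$ledger$restriction_sites[[ci]]
          if (length(ss) < 2) next
          a <- ss[sample.int(length(ss), 1L)]
          partner <- ss[which.min(abs(ss - (a + ins)))]
          if (partner <= a) next
          if (abs((partner - a) - ins) > 3 * spec$insert_sd) next
          s0 <- a; e0 <- partner
          break
        }
      }
      l1 <- .trunc_norm(1L, spec$read_len_mean, read_sd,
                        spec$read_len_min, spec$read_len_max)
      l2 <- .trunc_norm(1L, spec$read_len_mean, read_sd,
                        spec$read_len_min, spec$read_len_max)
      l1 <- min(l1, e0 - s0); l2 <- min(l2, e0 - s0)
      chrom_seq <- genome$sequences$sequence[ci]
      fwd <- substr(chrom_seq, s0 + 1L, s0 + l1)
      rev <- revcomp(substr(chrom_seq, e0 - l2 + 1L, e0))
      rows[[i]] <- data.frame(
        clone_id = sprintf("%s_c%05d", library, i), library = library,
        chrom = genome$sequences$id[ci],
        insert_start = s0, insert_end = e0,
        forward_id = sprintf("%s_c%05d.f", library, i),
        reverse_id = sprintf("%s_c%05d.r", library, i),
        forward_seq = fwd, reverse_seq = rev,
        forward_len = l1, reverse_len = l2,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("bes_pairs", "data.frame")
    out
  })
}

#' Flatten simulated pairs into a BES read table
#'
#' @param pairs output of [simulate_library()].
#' @return read data.frame (`id`, `sequence`, `library`, `clone_id`, `end`)
#'   with the true source span of each read (`src_chrom`, `src_start`,
#'   `src_end`, 0-based half-open, `src_strand`).
#' @export
library_reads <- function(pairs) {
  fwd <- data.frame(
    id = pairs$forward_id, sequence = pairs$forward_seq,
    library = pairs$library, clone_id = pairs$clone_id, end = "forward",
    src_chrom = pairs$chrom, src_start = pairs$insert_start,
    src_end = pairs$insert_start + pairs$forward_len, src_strand = "+",
    stringsAsFactors = FALSE)
  rev <- data.frame(
    id = pairs$reverse_id, sequence = pairs$reverse_seq,
    library = pairs$library, clone_id = pairs$clone_id, end = "reverse",
    src_chrom = pairs$chrom, src_start = pairs$insert_end - pairs$reverse_len,
    src_end = pairs$insert_end, src_strand = "-",
    stringsAsFactors = FALSE)
  out <- rbind(fwd, rev)
  out[order(out$clone_id, out$end), , drop = FALSE]
}

#' Synteny block specification for a related genome
#'
#' @param n_blocks number of collinear blocks copied from the source genome.
#' @param block_len block length range (bp).
#' @param multiplicity copies per block: a single integer or a vector to
#'   sample from. Copy `j` of every block is placed on target pseudomolecule
#'   `j`, emulating whole-genome duplication (multi-locus pairs then map to
#'   different chromosomes).
#' @param inversion_prob probability that a copy is inserted reverse
#'   complemented (recorded in the block ledger).
#' @param divergence per-base substitution rate applied to each copy
#'   (substitutions only; no indels).
#' @param spacer_len range of random spacer lengths between blocks (bp).
#' @param src_gap minimum gap between sampled source blocks (bp); the
#'   default keeps typical BAC inserts from spanning two sampled blocks.
#' @param seed integer seed.
#' @return list of class `synteny_spec`.
#' @export
synteny_spec <- function(n_blocks = 4L, block_len = c(250000, 350000),
                         multiplicity = 1L, inversion_prob = 0,
                         divergence = 0, spacer_len = c(20000, 60000),
                         src_gap = 100000L, seed = 1L) {
  stopifnot(inversion_prob >= 0, inversion_prob <= 1,
            divergence >= 0, divergence < 1, all(multiplicity >= 1))
  structure(list(n_blocks = n_blocks, block_len = block_len,
                 multiplicity = as.integer(multiplicity),
                 inversion_prob = inversion_prob, divergence = divergence,
                 spacer_len = spacer_len, src_gap = as.integer(src_gap),
                 seed = seed),
            class = "synteny_spec")
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) bases[i] <- .fresh_base(bases[i])
  paste(bases, collapse = "")
}

#' Simulate a related genome sharing collinear blocks
#'
#' Non-overlapping source blocks are copied into a target genome; copy `j`
#' of every block lands on target pseudomolecule `j` (in shuffled order,
#' separated by random spacers), optionally reverse complemented and with
#' per-base substitutions. The block ledger records every placement.
#'
#' @param genome source `genome_model`.
#' @param spec a [synteny_spec()].
#' @return list: `genome` (the target as a `genome_model` without feature
#'   ledger) and `blocks`, a data.frame with one row per placed copy
#'   (`block_id`, source span, target span, `orientation` = `"same"` /
#'   `"inverted"`, `copy_index`).
#' @export
simulate_related_genome <- function(genome, spec = synteny_spec()) {
  .with_seed(spec$seed, {
    src_len <- nchar(genome$sequences$sequence)
    occ <- lapply(seq_len(nrow(genome$sequences)), function(.) {
      data.frame(start = integer(), end = integer())
    })
    blocks <- vector("list", spec$n_blocks)
    for (b in seq_len(spec$n_blocks)) {
      blen <- sample(seq.int(spec$block_len[1], spec$block_len[2]), 1L)
      # try pseudomolecules in size-weighted random order until one fits
      order_ci <- sample.int(nrow(genome$sequences), prob = src_len)
      pos <- NULL
      for (ci in order_ci) {
        pos <- tryCatch(.place(occ[[ci]], src_len[ci], blen,
                               gap = spec$src_gap),
                        error = function(e) NULL)
        if (!is.null(pos)) break
      }
      if (is.null(pos)) {
        .stopf("infeasible packing: no pseudomolecule has room for a %d bp block",
               blen)
      }
      occ[[ci]] <- rbind(occ[[ci]],
                         data.frame(start = pos["start"], end = pos["end"]))
      m <- if (length(spec$multiplicity) == 1L) spec$multiplicity
           else sample(spec$multiplicity, 1L)
      blocks[[b]] <- data.frame(
        block_id = sprintf("block%d", b),
        src_chrom = genome$sequences$id[ci],
        src_start = pos["start"] - 1L, src_end = as.integer(pos["end"]),
        multiplicity = m, stringsAsFactors = FALSE)
    }
    blocks <- do.call(rbind, blocks)
    n_tgt <- max(blocks$multiplicity)
    tgt_rows <- list()
    ledger <- list()
    for (j in seq_len(n_tgt)) {
      present <- blocks[blocks$multiplicity >= j, , drop = FALSE]
      present <- present[sample.int(nrow(present)), , drop = FALSE]
      pieces <- character(0)
      cursor <- 0L
      tgt_id <- sprintf("tchr%d", j)
      for (b in seq_len(nrow(present))) {
        spacer <- paste(random_dna(
          sample(seq.int(spec$spacer_len[1], spec$spacer_len[2]), 1L),
          genome$params$gc %||% 0.352), collapse = "")
        pieces <- c(pieces, spacer)
        cursor <- cursor + nchar(spacer)
        src <- substr(genome$sequences$sequence[
          genome$sequences$id == present$src_chrom[b]],
          present$src_start[b] + 1L, present$src_end[b])
        inverted <- runif(1) < spec$inversion_prob
        if (inverted) src <- revcomp(src)
        src <- .mutate_seq(src, spec$divergence)
        pieces <- c(pieces, src)
        ledger[[length(ledger) + 1L]] <- data.frame(
          block_id = present$block_id[b],
          src_chrom = present$src_chrom[b],
          src_start = present$src_start[b], src_end = present$src_end[b],
          tgt_chrom = tgt_id, tgt_start = cursor,
          tgt_end = cursor + nchar(src),
          orientation = if (inverted) "inverted" else "same",
          copy_index = j, stringsAsFactors = FALSE)
        cursor <- cursor + nchar(src)
      }
      tail_spacer <- paste(random_dna(
        sample(seq.int(spec$spacer_len[1], spec$spacer_len[2]), 1L),
        genome$params$gc %||% 0.352), collapse = "")
      tgt_rows[[j]] <- data.frame(id = tgt_id,
                                  sequence = paste0(paste(pieces, collapse = ""),
                                                    tail_spacer),
                                  stringsAsFactors = FALSE)
    }
    target <- structure(list(
      sequences = do.call(rbind, tgt_rows),
      ledger = list(ssrs = NULL, repeats = NULL, genes = NULL,
                    restriction_sites = NULL),
      params = list(seed = spec$seed)), class = "genome_model")
    list(genome = target, blocks = do.call(rbind, ledger))
  })
}

#' Project simulated reads through the block ledger into subject hits
#'
#' Ground-truth mapping for synthetic synteny analyses: every read whose
#' source span lies entirely inside a copied block yields one hit per copy,
#' at the exactly projected target coordinates (strand flipped for inverted
#' copies). This stands in for a homology search when the truth is known.
#'
#' @param reads read table from [library_reads()].
#' @param blocks block ledger from [simulate_related_genome()].
#' @param divergence the generator's substitution rate, used for the nominal
#'   hit identity.
#' @return hit data.frame in the internal convention.
#' @export
project_read_hits <- function(reads, blocks, divergence = 0) {
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks[b, ]
    sel <- reads$src_chrom == blk$src_chrom &
      reads$src_start >= blk$src_start & reads$src_end <= blk$src_end
    if (!any(sel)) next
    r <- reads[sel, , drop = FALSE]
    len <- r$src_end - r$src_start
    if (blk$orientation == "same") {
      t_start <- blk$tgt_start + (r$src_start - blk$src_start)
      t_end <- t_start + len
      strand <- r$src_strand
    } else {
      t_start <- blk$tgt_start + (blk$src_end - r$src_end)
      t_end <- t_start + len
      strand <- ifelse(r$src_strand == "+", "-", "+")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = r$id, subject_id = blk$tgt_chrom,
      pident = round_half_up(100 * (1 - divergence), 1),
      aln_len = as.integer(len), mismatches = 0L, gap_opens = 0L,
      q_start = 0L, q_end = as.integer(len),
      s_start = as.integer(t_start), s_end = as.integer(t_end),
      strand = strand,
      evalue = pmax(2^(-len), 1e-300), bitscore = 2 * len * (1 - divergence),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(hits_df())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
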