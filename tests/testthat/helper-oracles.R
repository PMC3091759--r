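# Independent oracles and fixture builders used across the suite. The SSR
# oracle re-implements maximal-run detection, primitivity, canonicalization
# and the suppression rule with explicit per-position loops; the assembly
# oracle builds the full all-pairs overlap graph and takes connected
# components with union-find.

rand_dna <- function(n, gc = 0.35, with_n = 0) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (with_n > 0) {
    i <- which(stats::runif(n) < with_n)
    b[i] <- "N"
  }
  paste(b, collapse = "")
}

# a random sequence with SSR-like runs planted at random, so oracle
# comparisons exercise true positives as well as background
rand_ssr_seq <- function(n, n_runs = 2) {
  s <- strsplit(rand_dna(n, with_n = 0.005), "", fixed = TRUE)[[1]]
  for (r in seq_len(n_runs)) {
    k <- sample(1:6, 1)
    motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
    total <- sample(8:30, 1)
    pos <- sample(seq_len(max(1, n - total)), 1)
    s[pos:(pos + total - 1)] <-
      rep_len(strsplit(motif, "", fixed = TRUE)[[1]], total)
  }
  paste(s, collapse = "")
}

oracle_primitive <- function(m) {
  k <- nchar(m)
  if (k == 1) return(TRUE)
  for (d in 1:(k - 1)) {
    if (k %% d == 0 && paste(rep(strsplit(m, "")[[1]][1:d], k / d),
                             collapse = "") == m) {
      return(FALSE)
    }
  }
  TRUE
}

oracle_canonical <- function(m) {
  rot <- function(x) {
    k <- nchar(x)
    vapply(1:k, function(i) paste0(substr(x, i, k), substr(x, 1, i - 1)),
           character(1))
  }
  rc <- chartr("ACGT", "TGCA", m)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  min(c(rot(m), rot(rc)))
}

# brute-force SSR detection: every (start, unit) extension, explicit
# maximality checks, then thresholds, primitivity and the stated
# suppression rule (longest span, then smallest unit, then leftmost)
oracle_ssrs <- function(s, thresholds = ssr_thresholds()) {
  b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(b)
  cand <- list()
  for (k in 1:6) {
    min_len <- if (k <= 3) thresholds$min_len_1_3 else thresholds$min_units_4_6 * k
    i <- 1
    while (i + k <= n) {
      ok <- function(p) b[p] != "N" && b[p + k] != "N" && b[p] == b[p + k]
      if (!ok(i)) { i <- i + 1; next }
      j <- i
      while (j + k < n && ok(j + 1)) j <- j + 1
      total <- (j - i + 1) + k
      motif <- paste(b[i:(i + k - 1)], collapse = "")
      if (total >= min_len && oracle_primitive(motif)) {
        cand[[length(cand) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + total, unit_length = k,
          total_length = total, canonical = oracle_canonical(motif),
          stringsAsFactors = FALSE)
      }
      i <- j + 2
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      unit_length = integer(), total_length = integer(),
                      canonical = character(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$total_length, cand$unit_length, cand$start), ,
               drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(nrow(cand))) {
    contained <- FALSE
    for (i in kept) {
      if (cand$start[j] >= cand$start[i] && cand$end[j] <= cand$end[i]) {
        contained <- TRUE
        break
      }
    }
    if (!contained) kept <- c(kept, j)
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start, cand$unit_length), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

ssr_key <- function(d) paste(d$start, d$end, d$unit_length)

# union-find connected components of the all-pairs accepted-overlap graph
oracle_components <- function(seqs, min_overlap = 80, min_identity = 95) {
  seqs <- as_seq_df(seqs)
  n <- nrow(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    res <- overlap_align(seqs$sequence[i], seqs$sequence[j],
                         min_overlap, min_identity)
    if (res$accepted) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(seqs$id, comp)
}

# membership partition of a greedy assembly as a list of read-id sets
assembly_partition <- function(asm) {
  split(asm$membership$id,
        ifelse(asm$membership$contig_id == "SINGLETON",
               paste0("s_", asm$membership$id), asm$membership$contig_id))
}

same_partition <- function(p1, p2) {
  norm <- function(p) {
    unname(sort(vapply(p, function(x) paste(sort(unname(x)), collapse = ","),
                       character(1))))
  }
  identical(norm(p1), norm(p2))
}

# random fragmentation of fresh templates into overlapping tiles; returns
# sequences plus the true template of each fragment
fragment_case <- function(n_templates = 2, template_len = c(900, 1400),
                          frag_len = c(260, 420), min_ov = 120) {
  seqs <- character(0)
  truth <- character(0)
  idx <- 0
  for (t in seq_len(n_templates)) {
    tl <- sample(template_len[1]:template_len[2], 1)
    tpl <- rand_dna(tl)
    pos <- 1
    repeat {
      fl <- sample(frag_len[1]:frag_len[2], 1)
      fl <- min(fl, tl - pos + 1)
      frag <- substr(tpl, pos, pos + fl - 1)
      idx <- idx + 1
      id <- sprintf("t%df%d", t, idx)
      if (stats::runif(1) < 0.4) frag <- revcomp(frag)
      seqs[id] <- frag
      truth[id] <- sprintf("t%d", t)
      if (pos + fl - 1 >= tl) break
      pos <- pos + fl - sample(min_ov:(min_ov + 60), 1)
      pos <- max(1, min(pos, tl - min_ov))
    }
  }
  list(seqs = seqs, truth = truth)
}

# pair + hit tables with randomized placements for funnel monotonicity tests
random_synteny_input <- function(n_pairs = 40) {
  subjects <- c("s1", "s2", "s3")
  pairs <- data.frame(clone_id = sprintf("c%d", seq_len(n_pairs)),
                      forward_id = sprintf("c%d.f", seq_len(n_pairs)),
                      reverse_id = sprintf("c%d.r", seq_len(n_pairs)),
                      stringsAsFactors = FALSE)
  mk_hits <- function(ids) {
    rows <- lapply(ids, function(id) {
      n <- sample(0:3, 1)
      if (n == 0) return(NULL)
      st <- sample(c("+", "-"), n, replace = TRUE)
      s0 <- sample.int(2e6, n)
      data.frame(query_id = id,
                 subject_id = sample(subjects, n, replace = TRUE),
                 pident = 98, aln_len = 500L, mismatches = 0L,
                 gap_opens = 0L, q_start = 0L, q_end = 500L,
                 s_start = s0, s_end = s0 + 500L, strand = st,
                 evalue = 10^-stats::runif(n, 25, 60), bitscore = 900,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  hits <- rbind(mk_hits(pairs$forward_id), mk_hits(pairs$reverse_id))
  list(pairs = pairs, hits = hits)
}
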