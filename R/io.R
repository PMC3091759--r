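# I/O for the standard formats the survey touches. One coordinate convention
# holds everywhere inside the package: 0-based half-open; 1-based inclusive
# coordinates exist only at file boundaries, and strand is always an explicit
# field, never encoded by swapped coordinates.

.IUPAC <- "ACGTRYSWKMBDHVN"

#' Read a FASTA file into a sequence table
#'
#' Sequences are upper-cased; line wrapping is removed. Each record id must be
#' unique within the file and sequences may only contain IUPAC nucleotide
#' codes.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`, `description` in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  full <- names(set) %||% character(0)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (anyDuplicated(id)) {
    .stopf("duplicate sequence id in %s: %s", path, id[duplicated(id)][1])
  }
  bad <- regexpr(sprintf("[^%s]", .IUPAC), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    .stopf("non-IUPAC character in record '%s' at position %d", id[i], bad[i])
  }
  data.frame(id = id, sequence = seqs, description = desc,
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' Sequences are wrapped at 60 columns. `write_fasta()` followed by
#' [read_fasta()] is the identity on `(id, sequence)`.
#'
#' @param seqs data.frame with columns `id`, `sequence` (and optionally
#'   `description`), or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_seq_df(seqs)
  hdr <- seqs$id
  if (!is.null(seqs$description)) {
    has <- nzchar(seqs$description)
    hdr[has] <- paste(seqs$id[has], seqs$description[has])
  }
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Coerce a named character vector to the canonical sequence data.frame.
#' @rdname read_fasta
#' @param x a sequence table or named character vector.
#' @export
as_seq_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(x)
  }
  if (is.character(x)) {
    if (is.null(names(x))) .stopf("sequence vector must be named")
    return(data.frame(id = names(x), sequence = unname(x),
                      stringsAsFactors = FALSE))
  }
  .stopf("cannot interpret object of class '%s' as sequences", class(x)[1])
}

#' Length-filter BES records
#'
#' Reads shorter than `min_len` are discarded (the survey discards end reads
#' under 50 bp); order is preserved.
#'
#' @param records sequence data.frame (see [read_fasta()]).
#' @param min_len minimum retained length in bp (>= 1).
#' @return the filtered data.frame.
#' @export
filter_bes <- function(records, min_len = 50L) {
  stopifnot(min_len >= 1)
  records <- as_seq_df(records)
  records[nchar(records$sequence) >= min_len, , drop = FALSE]
}

#' Default clone/end naming scheme for BES read ids
#'
#' Mated ends are recognised by a trailing suffix on the read id: `.f`/`.r`
#' or `_F`/`_R` by default. Both regexes are configurable because end-naming
#' conventions differ between sequencing centres.
#'
#' @param forward,reverse regular expressions matching the forward / reverse
#'   suffix at the end of a read id.
#' @return a list usable as the `scheme` argument of [parse_bes_ids()].
#' @export
bes_id_scheme <- function(forward = "(\\.f|_F)$", reverse = "(\\.r|_R)$") {
  list(forward = forward, reverse = reverse)
}

#' Parse clone id and end label from BES read ids
#'
#' @param ids character vector of read ids.
#' @param scheme suffix scheme from [bes_id_scheme()].
#' @return data.frame with columns `id`, `clone_id`, `end` (`"forward"`,
#'   `"reverse"` or `NA` when no suffix matches).
#' @export
parse_bes_ids <- function(ids, scheme = bes_id_scheme()) {
  end <- rep(NA_character_, length(ids))
  clone <- ids
  f <- grepl(scheme$forward, ids)
  r <- !f & grepl(scheme$reverse, ids)
  end[f] <- "forward"
  end[r] <- "reverse"
  clone[f] <- sub(scheme$forward, "", ids[f])
  clone[r] <- sub(scheme$reverse, "", ids[r])
  data.frame(id = ids, clone_id = clone, end = end, stringsAsFactors = FALSE)
}

#' Build a BES read table from sequences
#'
#' @param records sequence data.frame.
#' @param library library label attached to every read (e.g. `"BCM"`,
#'   `"RCM"`).
#' @param scheme suffix scheme from [bes_id_scheme()].
#' @return data.frame with columns `id`, `sequence`, `library`, `clone_id`,
#'   `end`.
#' @export
bes_reads <- function(records, library = "OTHER", scheme = bes_id_scheme()) {
  records <- as_seq_df(records)
  parsed <- parse_bes_ids(records$id, scheme)
  data.frame(id = records$id, sequence = records$sequence,
             library = library, clone_id = parsed$clone_id,
             end = parsed$end, stringsAsFactors = FALSE)
}

#' Pair mated BES reads by clone
#'
#' Every read appears exactly once across `pairs` and `unpaired`; a clone
#' contributes a pair iff both its ends are present. Two reads claiming the
#' same (library, clone, end) are an error.
#'
#' @param reads BES read table from [bes_reads()].
#' @return list with elements `pairs` (data.frame: `clone_id`, `library`,
#'   `forward_id`, `reverse_id`) and `unpaired` (subset of `reads`).
#' @export
pair_bes <- function(reads) {
  if (nrow(reads) == 0) {
    return(list(
      pairs = data.frame(clone_id = character(), library = character(),
                         forward_id = character(), reverse_id = character(),
                         stringsAsFactors = FALSE),
      unpaired = reads))
  }
  keyed <- !is.na(reads$end)
  key <- paste(reads$library, reads$clone_id, reads$end, sep = "\r")
  dup <- duplicated(key) & keyed
  if (any(dup)) {
    .stopf("duplicate (clone, end) in library %s: clone '%s' end %s",
           reads$library[dup][1], reads$clone_id[dup][1], reads$end[dup][1])
  }
  ck <- paste(reads$library, reads$clone_id, sep = "\r")
  fwd <- reads[keyed & reads$end == "forward", , drop = FALSE]
  rev <- reads[keyed & reads$end == "reverse", , drop = FALSE]
  fk <- paste(fwd$library, fwd$clone_id, sep = "\r")
  rk <- paste(rev$library, rev$clone_id, sep = "\r")
  both <- intersect(fk, rk)
  fi <- match(both, fk)
  ri <- match(both, rk)
  pairs <- data.frame(clone_id = fwd$clone_id[fi], library = fwd$library[fi],
                      forward_id = fwd$id[fi], reverse_id = rev$id[ri],
                      stringsAsFactors = FALSE)
  paired_ids <- c(pairs$forward_id, pairs$reverse_id)
  unpaired <- reads[!(reads$id %in% paired_ids), , drop = FALSE]
  list(pairs = pairs, unpaired = unpaired)
}

#' Read a 12-column tabular homology file
#'
#' Consumes the standard tab-separated homology dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore) with 1-based inclusive coordinates and the
#' minus strand encoded as subject start > subject end. On return all
#' coordinates are 0-based half-open with `strand` an explicit column, and
#' hits with `evalue > max_e` are dropped.
#'
#' @param path path to the tabular hit file.
#' @param max_e E-value cutoff applied on read (default keeps everything).
#' @return data.frame of hits; zero rows for an empty file.
#' @export
read_hits_tabular <- function(path, max_e = Inf) {
  if (!file.exists(path)) .stopf("hit file not found: %s", path)
  empty <- hits_df()
  if (file.size(path) == 0) return(empty)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    .stopf("malformed hit line %d in %s: expected 12 tab-separated fields, got %d",
           which(nf != 12)[1], path, nf[nf != 12][1])
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  for (j in 3:12) {
    if (anyNA(num(j))) {
      .stopf("malformed hit line %d in %s: non-numeric field %d",
             which(is.na(num(j)))[1], path, j)
    }
  }
  ss <- num(9); se <- num(10)
  minus <- ss > se
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pident = num(3), aln_len = as.integer(num(4)),
    mismatches = as.integer(num(5)), gap_opens = as.integer(num(6)),
    q_start = as.integer(num(7)) - 1L, q_end = as.integer(num(8)),
    s_start = as.integer(ifelse(minus, se, ss)) - 1L,
    s_end = as.integer(ifelse(minus, ss, se)),
    strand = ifelse(minus, "-", "+"),
    evalue = num(11), bitscore = num(12),
    stringsAsFactors = FALSE)
  hits[hits$evalue <= max_e, , drop = FALSE]
}

# canonical empty hit table
hits_df <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Write hits in the 12-column tabular dialect
#'
#' Inverse of [read_hits_tabular()]: internal 0-based half-open coordinates
#' go back to 1-based inclusive, and minus-strand hits are written with
#' subject start > subject end.
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tabular <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(hits$query_id, hits$subject_id,
                    hits$pident, hits$aln_len,
                    hits$mismatches, hits$gap_opens,
                    hits$q_start + 1L, hits$q_end,
                    ifelse(minus, hits$s_end, hits$s_start + 1L),
                    ifelse(minus, hits$s_start + 1L, hits$s_end),
                    format(hits$evalue), hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a repeat-annotation file
#'
#' Consumes the whitespace-delimited repeat screening dialect (score,
#' divergence, deletion, insertion percentages, query id, query begin/end,
#' left, strand, repeat family, repeat class/family, ...). Header lines and
#' blank lines are skipped. 1-based inclusive spans become 0-based half-open;
#' family labels are preserved verbatim. Overlapping annotations are retained
#' (no merging at parse time).
#'
#' @param path path to the annotation file.
#' @param seq_lengths optional named integer vector of sequence lengths; when
#'   supplied, spans beyond a sequence end are an error.
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `family_label`, `class_label`.
#' @export
read_repeat_annotations <- function(path, seq_lengths = NULL) {
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) &
    !grepl("^(SW|score|bit)", lines, ignore.case = TRUE) &
    !startsWith(lines, "#")
  lines <- lines[keep]
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      family_label = character(), class_label = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\\s+")
  nf <- lengths(parts)
  if (any(nf < 11)) {
    .stopf("malformed annotation line: expected >= 11 whitespace fields, got %d",
           nf[nf < 11][1])
  }
  m <- t(vapply(parts, function(p) p[1:11], character(11)))
  hits <- data.frame(
    seq_id = m[, 5],
    start = as.integer(m[, 6]) - 1L,
    end = as.integer(m[, 7]),
    strand = ifelse(m[, 9] == "C", "-", "+"),
    family_label = m[, 10],
    class_label = m[, 11],
    stringsAsFactors = FALSE)
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[hits$seq_id]
    bad <- !is.na(len) & hits$end > len
    if (any(bad)) {
      .stopf("annotation span beyond end of '%s' (%d > %d)",
             hits$seq_id[bad][1], hits$end[bad][1], len[bad][1])
    }
  }
  hits
}

#' Write repeat annotations in the screening dialect
#'
#' @param hits data.frame as returned by [read_repeat_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotations <- function(hits, path) {
  n <- nrow(hits)
  out <- data.frame(
    score = rep(1000L, n), div = 0, del = 0, ins = 0,
    seq_id = hits$seq_id,
    begin = hits$start + 1L, end = hits$end, left = "(0)",
    strand = ifelse(hits$strand == "-", "C", "+"),
    family = hits$family_label, class = hits$class_label)
  header <- c("   SW   perc perc perc  query     position in query    matching repeat",
              "score   div. del. ins.  sequence  begin end   (left)   repeat  class/family",
              "")
  writeLines(header, path)
  write.table(out, path, sep = "  ", quote = FALSE,
              row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}
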