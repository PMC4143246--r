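#' Canonical motif family of an SSR repeat unit
#'
#' SSR motifs that are cyclic rotations of each other, or of each other's
#' reverse complement, describe the same repeat on the two strands (e.g. a
#' (GA)n run read on the other strand is (TC)n, and in a different phase
#' (CT)n). The family label is the lexicographically smallest string among
#' all rotations of the motif and of its reverse complement, so e.g. "GA",
#' "AG", "CT" and "TC" all map to family "AG". The function is idempotent.
#'
#' @param motif repeat unit over A/C/G/T, length 2--4, not itself a
#'   whole-number repetition of a shorter unit ("ATAT" is rejected).
#' @return character scalar, the family label.
#' @export
canonical_family <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  if (length(chars) < 2 || length(chars) > 4 ||
      !all(chars %in% c("A", "C", "G", "T")))
    stop("motif must be a string over ACGT of length 2-4")
  if (motif_period(paste(chars, collapse = "")) < length(chars))
    stop("degenerate motif (repetition of a shorter unit): ", motif)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- rev(unname(comp[chars]))
  rots <- function(v) vapply(seq_along(v), function(k)
    paste(c(v[k:length(v)], v[seq_len(k - 1)]), collapse = ""), character(1))
  min(c(rots(chars), rots(rc)))
}

# smallest period d (d divides nchar) such that the motif is a repetition of
# its length-d prefix; equals nchar(motif) for a non-degenerate motif
motif_period <- function(motif) {
  n <- nchar(motif)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 &&
        motif == strrep(substr(motif, 1, d), n / d)) return(d)
  }
  n
}

new_ssr_hits <- function(seq_id = character(), start = integer(),
                         end = integer(), motif = character(),
                         family = character(), unit_len = integer(),
                         length = integer(), mismatches = integer()) {
  data.frame(seq_id = seq_id, start = start, end = end, motif = motif,
             family = family, unit_len = unit_len, length = length,
             mismatches = mismatches, stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  hits <- hits[order(hits$seq_id, hits$start, hits$unit_len), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# drop same-family overlapping hits, keeping the best by
# (longest, fewest mismatches, smallest start); deterministic
merge_family_overlaps <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  keep <- logical(nrow(hits))
  for (fam in unique(hits$family)) {
    idx <- which(hits$family == fam)
    h <- hits[idx, , drop = FALSE]
    o <- order(-h$length, h$mismatches, h$start)
    taken <- rep(FALSE, length(idx))
    for (k in o) {
      if (taken[k]) next
      keep[idx[k]] <- TRUE
      ov <- h$start < h$end[k] & h$end > h$start[k]
      taken[ov] <- TRUE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Find perfect SSRs in a nucleotide sequence
#'
#' Detects every maximal exact tandem run of a di-, tri- or tetra-nucleotide
#' unit with total length at least `min_len`. Runs whose unit is itself a
#' repetition of a shorter unit (e.g. ATAT) are suppressed: only the shortest
#' generating unit is reported, so a run is never double-counted across unit
#' lengths (and homopolymers are never reported). Coordinates are 0-based,
#' half-open. Characters outside A/C/G/T break runs. Overlapping hits of the
#' same motif family are resolved to the single best hit (longest, then
#' fewest mismatches, then leftmost).
#'
#' @param seq nucleotide string (uppercased on ingest).
#' @param min_len minimum run length in nt (default 15).
#' @param unit_lens repeat-unit lengths to search, subset of 2:4.
#' @param seq_id label used in the output.
#' @return data.frame of hits with columns `seq_id, start, end, motif, family,
#'   unit_len, length, mismatches` (all `mismatches` 0), sorted by position.
#' @export
find_perfect_ssrs <- function(seq, min_len = 15, unit_lens = c(2, 3, 4),
                              seq_id = "seq") {
  stopifnot(all(unit_lens %in% 2:4))
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  hits <- new_ssr_hits()
  for (u in sort(unit_lens)) {
    if (n < u + 1) next
    m <- s[seq_len(n - u)] == s[(u + 1):n] &
      ok[seq_len(n - u)] & ok[(u + 1):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      L <- r$lengths[k] + u
      if (L < min_len) next
      a <- starts[k]
      motif <- paste(s[a:(a + u - 1)], collapse = "")
      if (motif_period(motif) < u) next
      hits <- rbind(hits, new_ssr_hits(seq_id, a - 1L, a - 1L + L, motif,
                                       canonical_family(motif), as.integer(u),
                                       as.integer(L), 0L))
    }
  }
  sort_hits(merge_family_overlaps(hits))
}

#' Find imperfect SSRs in a nucleotide sequence
#'
#' An imperfect SSR is a maximal window that matches a perfect tandem array
#' of its unit (in the same phase, i.e. the array starts where the window
#' starts) at Hamming distance at most `max_mismatch`, with length at least
#' `min_len`. The reported motif is the per-phase consensus of the window
#' (alphabetical tie-break), which is the unit minimizing that Hamming
#' distance. Windows whose consensus unit degenerates to a shorter unit are
#' suppressed, perfect runs are reported with `mismatches = 0`, and
#' overlapping hits of the same family are merged to the single best hit
#' (longest, then fewest mismatches, then leftmost). With `max_mismatch = 0`
#' the output equals [find_perfect_ssrs()] hit-for-hit.
#'
#' @inheritParams find_perfect_ssrs
#' @param max_mismatch maximum Hamming distance to the perfect array.
#' @return data.frame of hits as in [find_perfect_ssrs()].
#' @export
find_imperfect_ssrs <- function(seq, min_len = 15, unit_lens = c(2, 3, 4),
                                max_mismatch = 2, seq_id = "seq") {
  stopifnot(all(unit_lens %in% 2:4), max_mismatch >= 0)
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  code <- match(s, c("A", "C", "G", "T"))   # NA for invalid chars
  hits <- new_ssr_hits()
  for (u in sort(unit_lens)) {
    prev_end <- 0L
    for (a in seq_len(n)) {
      # extend [a, e] while the consensus mismatch count stays within budget
      counts <- matrix(0L, 4, u)
      best <- integer(u)          # running max count per phase class
      e <- a - 1L
      while (e < n) {
        cc <- code[e + 1L]
        if (is.na(cc)) break
        j <- (e + 1L - a) %% u + 1L
        counts[cc, j] <- counts[cc, j] + 1L
        if (counts[cc, j] > best[j]) best[j] <- counts[cc, j]
        if ((e + 2L - a) - sum(best) > max_mismatch) break
        e <- e + 1L
      }
      if (e >= a && e > prev_end) {      # right-maximal and left-maximal
        L <- e - a + 1L
        if (L >= min_len) {
          motif <- consensus_motif(code, a, e, u)
          if (motif_period(motif) == u) {
            mm <- hamming_to_array(s, a, e, motif)
            hits <- rbind(hits, new_ssr_hits(
              seq_id, a - 1L, e, motif, canonical_family(motif),
              as.integer(u), L, as.integer(mm)))
          }
        }
      }
      if (e >= a) prev_end <- max(prev_end, e)
    }
  }
  hits <- hits[hits$length >= min_len, , drop = FALSE]
  sort_hits(merge_family_overlaps(hits))
}

# per-phase consensus unit of window [a, e] (1-based, inclusive);
# ties broken alphabetically
consensus_motif <- function(code, a, e, u) {
  bases <- c("A", "C", "G", "T")
  out <- character(u)
  for (j in seq_len(u)) {
    pos <- seq(a + j - 1L, e, by = u)
    if (!length(pos)) { out[j] <- "A"; next }
    cnt <- tabulate(code[pos], 4)
    out[j] <- bases[which.max(cnt)]
  }
  paste(out, collapse = "")
}

# Hamming distance between window [a, e] and the same-phase perfect array
# of `motif`
hamming_to_array <- function(s, a, e, motif) {
  L <- e - a + 1L
  arr <- strsplit(strrep(motif, ceiling(L / nchar(motif))), "")[[1]][seq_len(L)]
  sum(s[a:e] != arr)
}

#' Mine a FASTA file for SSRs
#'
#' Runs the imperfect-repeat finder (which subsumes perfect repeats) over
#' every record of a FASTA file and summarizes the yield: hit counts by
#' repeat-unit length and by canonical motif family, and the SSR density
#' expressed as bases of input per SSR found.
#'
#' @param path FASTA file.
#' @param min_len minimum repeat length (nt).
#' @param unit_lens repeat-unit lengths, subset of 2:4.
#' @param max_mismatch maximum mismatches per repeat (0 = perfect only).
#' @return list with `hits` (data.frame sorted by sequence then position) and
#'   `summary`: `n_sequences`, `total_bases`, `counts_by_unit_len`,
#'   `counts_by_family`, `n_hits`, and `density_bp_per_ssr`
#'   (`total_bases / n_hits`; `NULL` when there are no hits).
#' @export
mine_fasta <- function(path, min_len = 15, unit_lens = c(2, 3, 4),
                       max_mismatch = 2) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in FASTA: ", ids[duplicated(ids)][1])
  pieces <- lapply(seq_along(seqs), function(i)
    find_imperfect_ssrs(as.character(seqs[[i]]), min_len = min_len,
                        unit_lens = unit_lens, max_mismatch = max_mismatch,
                        seq_id = ids[i]))
  hits <- sort_hits(do.call(rbind, c(list(new_ssr_hits()), pieces)))
  total_bases <- sum(Biostrings::width(seqs))
  by_u <- vapply(c(2, 3, 4), function(u) sum(hits$unit_len == u), integer(1))
  names(by_u) <- c("2", "3", "4")
  by_fam <- if (nrow(hits)) table(hits$family) else table(character(0))
  list(hits = hits,
       summary = list(
         n_sequences = length(seqs),
         total_bases = total_bases,
         counts_by_unit_len = by_u,
         counts_by_family = by_fam,
         n_hits = nrow(hits),
         density_bp_per_ssr = if (nrow(hits)) total_bases / nrow(hits) else NULL))
}

#' Percentages of repeat classes
#'
#' @param counts_by_unit_len named (2/3/4) non-negative counts, not all zero.
#' @param digits decimals to round to (1, matching the usual reporting).
#' @return named numeric of percentages summing to 100 up to rounding.
#' @export
repeat_class_percentages <- function(counts_by_unit_len, digits = 1) {
  counts <- as.numeric(counts_by_unit_len)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative and not all zero")
  out <- round(100 * counts / sum(counts), digits)
  names(out) <- names(counts_by_unit_len)
  out
}

#' Check a candidate amplicon size against the marker design window
#'
#' @param size product size(s) in bp.
#' @param range acceptable window, default 90--300 bp.
#' @return logical vector.
#' @export
amplicon_size_ok <- function(size, range = c(90, 300)) {
  size >= range[1] & size <= range[2]
}

#' Write an SSR hit table to TSV
#'
#' @param hits hit data.frame from [mine_fasta()] or the finders.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssr_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
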