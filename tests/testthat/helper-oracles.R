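# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (quadratic scans, exhaustive enumeration, explicit
# algebra) and share no internals with the package implementation.

oracle_period <- function(motif) {
  n <- nchar(motif)
  for (d in 1:(n - 1)) {
    if (n %% d != 0) next
    pref <- substr(motif, 1, d)
    if (paste(rep(pref, n / d), collapse = "") == motif) return(d)
  }
  n
}

oracle_family <- function(motif) {
  v <- strsplit(motif, "")[[1]]
  rc <- rev(chartr("ACGT", "TGCA", v))
  all <- character(0)
  for (k in seq_along(v)) {
    all <- c(all,
             paste(c(v[k:length(v)], v[seq_len(k - 1)]), collapse = ""),
             paste(c(rc[k:length(rc)], rc[seq_len(k - 1)]), collapse = ""))
  }
  sort(all)[1]
}

# independent same-family overlap merge: best = longest, then fewest
# mismatches, then leftmost
oracle_merge <- function(df) {
  if (nrow(df) < 2) return(df)
  out <- df[0, ]
  for (fam in unique(df$family)) {
    h <- df[df$family == fam, , drop = FALSE]
    h <- h[order(-h$length, h$mismatches, h$start), , drop = FALSE]
    chosen <- h[0, ]
    for (r in seq_len(nrow(h))) {
      row <- h[r, ]
      clash <- any(row$start < chosen$end & row$end > chosen$start)
      if (!clash) chosen <- rbind(chosen, row)
    }
    out <- rbind(out, chosen)
  }
  out <- out[order(out$seq_id, out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quadratic scanner for maximal exact tandem runs
oracle_perfect <- function(seq, min_len = 15, unit_lens = c(2, 3, 4),
                           seq_id = "seq") {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in unit_lens) {
    for (a in seq_len(max(0, n - u + 1))) {
      if (!all(ok[a:(a + u - 1)])) next
      e <- a + u - 1
      while (e + 1 <= n && ok[e + 1] && s[e + 1] == s[e + 1 - u]) e <- e + 1
      L <- e - a + 1
      if (L < min_len) next
      if (a > 1 && ok[a - 1] && a - 1 + u <= n && s[a - 1] == s[a - 1 + u])
        next   # extendable left, not maximal
      motif <- paste(s[a:(a + u - 1)], collapse = "")
      if (oracle_period(motif) < u) next
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = seq_id, start = a - 1L, end = e, motif = motif,
        family = oracle_family(motif), unit_len = as.integer(u),
        length = as.integer(L), mismatches = 0L, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               motif = character(), family = character(),
               unit_len = integer(), length = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  oracle_merge(df)
}

oracle_consensus <- function(s, a, e, u) {
  bases <- c("A", "C", "G", "T")
  out <- character(u)
  for (j in seq_len(u)) {
    if (a + j - 1 > e) { out[j] <- "A"; next }
    pos <- seq(a + j - 1, e, by = u)
    cnt <- vapply(bases, function(b) sum(s[pos] == b), integer(1))
    out[j] <- bases[which.max(cnt)]
  }
  paste(out, collapse = "")
}

oracle_hamming <- function(s, a, e, motif) {
  L <- e - a + 1
  arr <- rep(strsplit(motif, "")[[1]], length.out = L)
  sum(s[a:e] != arr)
}

# quadratic scanner for maximal imperfect windows: recomputes the consensus
# and Hamming distance from scratch at every extension
oracle_imperfect <- function(seq, min_len = 15, unit_lens = c(2, 3, 4),
                             max_mismatch = 2, seq_id = "seq") {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in unit_lens) {
    emax <- integer(n)
    for (a in seq_len(n)) {
      best_e <- a - 1
      for (e in a:n) {
        if (!ok[e]) break
        cons <- oracle_consensus(s, a, e, u)
        if (oracle_hamming(s, a, e, cons) > max_mismatch) break
        best_e <- e
      }
      emax[a] <- best_e
    }
    for (a in seq_len(n)) {
      e <- emax[a]
      if (e < a) next
      if (a > 1 && any(emax[seq_len(a - 1)] >= e)) next  # contained
      L <- e - a + 1
      if (L < min_len) next
      motif <- oracle_consensus(s, a, e, u)
      if (oracle_period(motif) < u) next
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = seq_id, start = a - 1L, end = e, motif = motif,
        family = oracle_family(motif), unit_len = as.integer(u),
        length = as.integer(L),
        mismatches = as.integer(oracle_hamming(s, a, e, motif)),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               motif = character(), family = character(),
               unit_len = integer(), length = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  oracle_merge(df)
}

# exhaustive rarefaction: mean number of distinct alleles over all
# g-subsets of the observed gene copies
oracle_richness <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(copies), g)
  mean(apply(combs, 2, function(i) length(unique(copies[i]))))
}

# exhaustive least-squares topology search (unrooted, <= 7 tips)
oracle_ls_tree <- function(D) {
  labs <- rownames(D)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  errs <- vapply(trees, function(cand) {
    Dm <- D[cand$tip.label, cand$tip.label]
    y <- Dm[lower.tri(Dm)]
    X <- as.matrix(phangorn::designTree(cand))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  trees[[which.min(errs)]]
}

# random unrooted tree with strictly positive branch lengths and its
# additive (path-length) distance matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1.5)))
  list(tree = tr, D = stats::cophenetic(tr))
}
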