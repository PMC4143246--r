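#' Nei's DA distance between two multi-locus allele frequency profiles
#'
#' `DA = 1 - (1/r) * sum_loci sum_alleles sqrt(x_i * y_i)`, averaged over the
#' `r` loci with data in both profiles. DA is 0 for identical profiles and 1
#' when the two profiles share no alleles at any shared locus.
#'
#' @param x,y named lists locus -> `allele_spectrum` (or bare named frequency
#'   vectors).
#' @return list with `da` and `r` (number of shared loci).
#' @export
da_distance <- function(x, y) {
  shared <- intersect(names(x), names(y))
  total <- 0
  r <- 0L
  for (mid in shared) {
    px <- spectrum_freqs(x[[mid]])
    py <- spectrum_freqs(y[[mid]])
    if (!length(px) || !length(py)) next
    r <- r + 1L
    common <- intersect(names(px), names(py))
    if (length(common))
      total <- total + sum(sqrt(px[common] * py[common]))
  }
  if (r == 0) stop("no locus shared between the two profiles")
  list(da = 1 - total / r, r = r)
}

#' Per-accession allele frequency profiles
#'
#' Treats each accession as a population of one: a single-product call has
#' frequency 1 on its allele, a two-product call frequency 0.5 on each.
#' This is the coding under which all-pairs individual distances are
#' computed.
#'
#' @param table a [genotype_table()].
#' @param accessions accession ids (default all).
#' @return named list accession -> named list marker -> frequency vector.
#' @export
individual_spectra <- function(table,
                               accessions = table$accessions$accession_id) {
  mids <- table$markers$marker_id
  out <- lapply(accessions, function(aid) {
    spec <- lapply(mids, function(mid) {
      sz <- call_sizes(table, aid, mid)
      if (!length(sz)) return(numeric(0))
      p <- rep(1 / length(sz), length(sz))
      names(p) <- sz
      p
    })
    names(spec) <- mids
    spec
  })
  names(out) <- accessions
  out
}

#' All-pairs DA distance matrix
#'
#' @param spectra named list unit -> named list locus -> frequencies, where a
#'   unit is an accession ([individual_spectra()]) or a genome group
#'   ([group_spectra()]).
#' @return a `da_matrix`: list with `d` (symmetric matrix, zero diagonal),
#'   `r` (shared-locus counts per pair) and `labels`.
#' @export
pairwise_da <- function(spectra) {
  labels <- names(spectra)
  n <- length(labels)
  sims <- locus_similarities(spectra)
  pres <- sims$present            # L x n logical
  S <- sims$sim                   # n x n x L similarity per locus
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  r <- matrix(0L, n, n, dimnames = list(labels, labels))
  L <- dim(S)[3]
  tot <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    both <- outer(pres[l, ], pres[l, ], "&")
    tot <- tot + ifelse(both, S[, , l], 0)
    cnt <- cnt + both
  }
  if (any(cnt[upper.tri(cnt)] == 0))
    stop("at least one pair of units shares no typed locus")
  d <- 1 - tot / cnt
  diag(d) <- 0
  dimnames(d) <- dimnames(cnt) <- list(labels, labels)
  structure(list(d = d, r = cnt, labels = labels), class = "da_matrix")
}

# per-locus similarity matrices sum_i sqrt(x_i y_i) and presence flags;
# shared by pairwise_da and the locus bootstrap
locus_similarities <- function(spectra) {
  labels <- names(spectra)
  n <- length(labels)
  mids <- names(spectra[[1]])
  L <- length(mids)
  sim <- array(0, dim = c(n, n, L))
  present <- matrix(FALSE, L, n)
  for (l in seq_len(L)) {
    freqs <- lapply(spectra, function(u) spectrum_freqs(u[[mids[l]]]))
    alleles <- unique(unlist(lapply(freqs, names)))
    if (!length(alleles)) next
    Fm <- matrix(0, n, length(alleles), dimnames = list(labels, alleles))
    for (i in seq_len(n)) {
      p <- freqs[[i]]
      if (length(p)) {
        Fm[i, names(p)] <- p
        present[l, i] <- TRUE
      }
    }
    sq <- sqrt(Fm)
    M <- sq %*% t(sq)
    sim[, , l] <- (M + t(M)) / 2   # enforce bitwise symmetry
  }
  list(sim = sim, present = present, loci = mids)
}

#' Mean pairwise DA within groups
#'
#' The within-group analogue of the group distance matrix diagonal: the mean
#' DA over all member pairs of each group, computed from an individual-level
#' `da_matrix`.
#'
#' @param ind_da a `da_matrix` over accessions. For a sub-genome group the
#'   accession-level distances are computed on that sub-genome's assigned
#'   alleles, so pass a matrix built from the matching spectra.
#' @param members list of accession-id vectors, named by group.
#' @return named numeric of within-group mean DA (`NA` for singletons).
#' @export
within_group_da <- function(ind_da, members) {
  vapply(members, function(m) {
    m <- intersect(m, ind_da$labels)
    if (length(m) < 2) return(NA_real_)
    sub <- ind_da$d[m, m]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-criterion with Studier–Keppler distance
#' updates). Ties in Q are broken deterministically by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' leaf label), so the result does not depend on input ordering. Negative
#' branch lengths are clamped to zero by default (topology is unaffected).
#'
#' @param D a `da_matrix`, `dist`, or symmetric matrix with dimnames.
#' @param clamp_negative clamp negative branch lengths to 0.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D, clamp_negative = TRUE) {
  if (inherits(D, "da_matrix")) D <- D$d
  D <- as.matrix(D)
  D <- (D + t(D)) / 2   # bitwise symmetry, so Q-minima pair up exactly
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 labels")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  cl <- function(x) if (clamp_negative) max(x, 0) else x
  # build the newick over placeholder tokens so labels may contain spaces,
  # parentheses or other newick metacharacters; real labels are restored
  # on the parsed tree
  tokens <- sprintf("q%d", seq_len(n))
  sub <- tokens          # newick fragment per active cluster
  lab <- labels          # tie-break label per active cluster
  dimnames(D) <- NULL
  while (n > 3) {
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(ij)
        paste(sort(c(lab[ij[1]], lab[ij[2]])), collapse = "\r"))
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    frag <- paste0("(", sub[i], ":", fmt(cl(bi)), ",",
                   sub[j], ":", fmt(cl(bj)), ")")
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    sub <- c(sub[keep], frag)
    lab <- c(lab[keep], min(lab[c(i, j)]))
    n <- n - 1L
  }
  b <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
         (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
         (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- paste0("(", sub[1], ":", fmt(cl(b[1])), ",",
                   sub[2], ":", fmt(cl(b[2])), ",",
                   sub[3], ":", fmt(cl(b[3])), ");")
  phy <- ape::read.tree(text = newick)
  phy$tip.label <- labels[match(phy$tip.label, tokens)]
  phy
}

# canonical non-trivial bipartitions of an unrooted tree, as strings;
# each split is represented by the side not containing the alphabetically
# first tip, sorted and pasted
tree_bipartitions <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(phy)
  out <- character(0)
  for (k in seq_along(pp)) {
    side <- sort(phy$tip.label[pp[[k]]])
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > length(tips) - 2) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Locus-bootstrap support for a neighbor-joining tree
#'
#' Resamples loci with replacement, recomputes the DA matrix and NJ tree for
#' each replicate, and reports, for every internal edge of the original
#' tree, the percentage of replicate trees containing the same bipartition.
#' Reproducible for a fixed seed and invariant to locus ordering.
#'
#' @param spectra unit -> locus -> frequency profiles, as in [pairwise_da()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @param clamp_negative passed to [neighbor_joining()].
#' @return list with `tree` (the original NJ tree with node labels set to
#'   support percentages) and `support` (named numeric per bipartition).
#' @export
bootstrap_support <- function(spectra, n_reps, seed, clamp_negative = TRUE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  sims <- locus_similarities(spectra)
  labels <- names(spectra)
  n <- length(labels)
  L <- dim(sims$sim)[3]
  if (L < 2) stop("locus bootstrap needs at least 2 loci")
  # deterministic per-locus order: sort by locus name so input order is moot
  o <- order(sims$loci)
  # flatten to n^2 x L so a replicate is a weighted matrix-vector product
  Sm <- matrix(sims$sim[, , o, drop = FALSE], n * n, L)
  pres <- sims$present[o, , drop = FALSE]
  Pm <- matrix(0, n * n, L)
  for (l in seq_len(L))
    Pm[, l] <- as.numeric(outer(pres[l, ], pres[l, ], "&"))
  Sm <- Sm * Pm    # zero out similarities where either unit is untyped
  da_from <- function(w) {
    tot <- Sm %*% w
    cnt <- Pm %*% w
    d <- matrix(1 - tot / cnt, n, n, dimnames = list(labels, labels))
    d[matrix(cnt == 0, n, n)] <- NA
    diag(d) <- 0
    d
  }
  orig <- neighbor_joining(da_from(rep(1, L)), clamp_negative)
  splits <- tree_bipartitions(orig)
  hits <- stats::setNames(numeric(length(splits)), splits)
  set.seed(seed)
  used <- 0L
  for (b in seq_len(n_reps)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), L)
    d <- da_from(w)
    if (anyNA(d)) next   # a pair lost all shared loci; skip replicate
    used <- used + 1L
    bs <- tree_bipartitions(neighbor_joining(d, clamp_negative))
    hit <- splits %in% bs
    hits[hit] <- hits[hit] + 1
  }
  if (used == 0) stop("all bootstrap replicates were degenerate")
  support <- 100 * hits / used
  # annotate internal nodes of the original tree
  tips <- sort(orig$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(orig)
  node_lab <- character(orig$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(orig$tip.label[pp[[k]]])
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    node_lab[k] <- if (key %in% names(support))
      sprintf("%.1f", support[key]) else ""
  }
  orig$node.label <- node_lab
  list(tree = orig, support = support, n_used = used)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are included; bootstrap supports (if present) are carried
#' as internal node labels. Re-parsing with [ape::read.tree()] reproduces
#' topology, lengths and labels.
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a labelled distance matrix to TSV
#'
#' @param da a `da_matrix`.
#' @param path output path for the distances; the shared-locus counts go to
#'   `<path>.r` alongside.
#' @return `path`, invisibly.
#' @export
write_da_matrix <- function(da, path) {
  utils::write.table(cbind(label = da$labels, as.data.frame(da$d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(label = da$labels, as.data.frame(da$r)),
                     paste0(path, ".r"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
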