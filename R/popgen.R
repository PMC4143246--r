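#' Gene diversity (expected heterozygosity) of an allele spectrum
#'
#' `H = 1 - sum(p_i^2)` over the allele frequencies of one locus in one
#' group. With `unbiased = TRUE` the small-sample correction `n/(n-1)` is
#' applied, where `n` is the number of gene copies.
#'
#' @param spectrum an `allele_spectrum` (or a bare named frequency vector).
#' @param unbiased apply the `n/(n-1)` correction.
#' @return numeric scalar in `[0, 1]`; `NA` for an empty spectrum (missing
#'   locus, excluded from means upstream).
#' @export
gene_diversity <- function(spectrum, unbiased = FALSE) {
  p <- spectrum_freqs(spectrum)
  if (!length(p)) return(NA_real_)
  h <- 1 - sum(p^2)
  if (unbiased) {
    n <- spectrum_n(spectrum)
    if (is.na(n) || n < 2) return(NA_real_)
    h <- h * n / (n - 1)
  }
  h
}

#' Polymorphic information content (PIC)
#'
#' Botstein convention:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#' Always `PIC <= H`, with equality only for a monomorphic locus.
#'
#' @inheritParams gene_diversity
#' @return numeric scalar; `NA` for an empty spectrum.
#' @export
pic <- function(spectrum) {
  p <- spectrum_freqs(spectrum)
  if (!length(p)) return(NA_real_)
  p2 <- p^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

spectrum_freqs <- function(spectrum) {
  if (inherits(spectrum, "allele_spectrum")) spectrum$freqs else spectrum
}
spectrum_n <- function(spectrum) {
  if (inherits(spectrum, "allele_spectrum")) spectrum$n_copies else NA_integer_
}

#' Observed heterozygosity of a group at one marker
#'
#' Fraction of non-missing accessions in the group whose call carries two
#' distinct allele sizes. Meaningful only under two-allele coding; under the
#' single-allele scoring used for tetraploid sub-genomes it is 0 by
#' construction.
#'
#' @param table a [genotype_table()].
#' @param group accession ids.
#' @param marker_id marker.
#' @return numeric scalar; `NA` if no member has a call.
#' @export
observed_heterozygosity <- function(table, group, marker_id) {
  cl <- table$calls
  cl <- cl[cl$marker_id == marker_id & cl$accession_id %in% group, , drop = FALSE]
  if (!nrow(cl)) return(NA_real_)
  n_products <- table(cl$accession_id)
  mean(n_products >= 2)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random sample of `g` gene copies
#' drawn without replacement from the observed copies (hypergeometric
#' rarefaction):
#' `A_g = sum_i [1 - choose(N - N_i, g) / choose(N, g)]`
#' where `N_i` is the observed copy count of allele `i` and `N = sum(N_i)`.
#'
#' @param allele_copy_counts integer vector of copy counts per allele
#'   (an `allele_spectrum`'s `counts` element works).
#' @param g rarefaction sample size, `1 <= g <= N`.
#' @return numeric scalar in `[1, k]` (k = number of distinct alleles);
#'   `NA` if `g > N` or the locus has no copies.
#' @export
allelic_richness <- function(allele_copy_counts, g) {
  if (inherits(allele_copy_counts, "allele_spectrum"))
    allele_copy_counts <- allele_copy_counts$counts
  N <- sum(allele_copy_counts)
  if (N == 0 || g > N || g < 1) return(NA_real_)
  # lchoose keeps this stable for large N
  sum(1 - exp(lchoose(N - allele_copy_counts, g) - lchoose(N, g)))
}

# per-locus rarefaction depths: smallest per-group copy count at each locus
# among groups with data
rarefaction_depths <- function(spectra) {
  mids <- names(spectra[[1]])
  vapply(mids, function(mid) {
    ns <- vapply(spectra, function(gs) gs[[mid]]$n_copies, integer(1))
    ns <- ns[ns > 0]
    if (!length(ns)) NA_integer_ else min(ns)
  }, integer(1))
}

#' Per-locus summary across genome groups
#'
#' One row per marker: total number of distinct alleles across all groups,
#' allele size range (min, max, span = max - min), and per-group PIC and
#' rarefied allelic richness plus the pooled (overall) values. Loci
#' monomorphic within a group contribute `PIC = 0` and richness 1; groups
#' with no data at a locus get `NA`. Group columns are rarefied per locus to
#' the smallest per-group copy count at that locus; the overall column is
#' rarefied to the smallest pooled copy count across loci.
#'
#' @param spectra output of [group_spectra()].
#' @return data.frame with `marker_id`, `n_alleles`, `size_min`, `size_max`,
#'   `size_span`, `PIC_<group>` and `AR_<group>` columns, and `PIC_overall`,
#'   `AR_overall`.
#' @export
locus_summary <- function(spectra) {
  gids <- names(spectra)
  mids <- names(spectra[[1]])
  depths <- rarefaction_depths(spectra)
  pooled <- pooled_spectra(spectra)
  g_overall <- min(vapply(pooled, function(s) s$n_copies, integer(1)))
  rows <- lapply(mids, function(mid) {
    sizes <- unlist(lapply(spectra, function(gs)
      as.numeric(names(gs[[mid]]$freqs))))
    row <- data.frame(marker_id = mid,
                      n_alleles = length(unique(sizes)),
                      size_min = if (length(sizes)) min(sizes) else NA,
                      size_max = if (length(sizes)) max(sizes) else NA,
                      stringsAsFactors = FALSE)
    row$size_span <- row$size_max - row$size_min
    for (gid in gids) {
      sp <- spectra[[gid]][[mid]]
      row[[paste0("PIC_", gid)]] <- pic(sp)
      row[[paste0("AR_", gid)]] <-
        if (is.na(depths[mid])) NA_real_ else allelic_richness(sp, depths[mid])
    }
    row$PIC_overall <- pic(pooled[[mid]])
    row$AR_overall <- allelic_richness(pooled[[mid]], g_overall)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pool group spectra into one spectrum per locus (summed copy counts)
pooled_spectra <- function(spectra) {
  mids <- names(spectra[[1]])
  out <- lapply(mids, function(mid) {
    counts <- list()
    for (gs in spectra) {
      cnt <- gs[[mid]]$counts
      for (a in names(cnt))
        counts[[a]] <- (if (is.null(counts[[a]])) 0L else counts[[a]]) + cnt[[a]]
    }
    copies <- rep(as.integer(names(counts)), times = unlist(counts))
    spectrum_from_copies(copies, mid, "overall")
  })
  names(out) <- mids
  out
}

#' Per-group diversity summary
#'
#' One row per genome group: number of accessions, loci typed, distinct
#' alleles (distinct (marker, size) pairs observed in the group), mean gene
#' diversity, mean observed heterozygosity (0 for sub-genome groups, which
#' are scored single-allele), mean PIC, and mean rarefied allelic richness.
#' A final `Total` row pools all groups: its allele count is the distinct
#' (marker, size) pairs over the pooled data and its H/PIC come from the
#' pooled spectra.
#'
#' @param spectra output of [group_spectra()].
#' @param table the underlying [genotype_table()] (for Ho).
#' @param groups group table from [build_genome_groups()].
#' @return data.frame, one row per group plus `Total`.
#' @export
group_summary <- function(spectra, table, groups) {
  gids <- names(spectra)
  mids <- names(spectra[[1]])
  depths <- rarefaction_depths(spectra)
  rows <- lapply(gids, function(gid) {
    gs <- spectra[[gid]]
    g <- groups[groups$group_id == gid, ]
    H <- vapply(gs, gene_diversity, numeric(1))
    P <- vapply(gs, pic, numeric(1))
    AR <- vapply(mids, function(mid)
      if (is.na(depths[mid])) NA_real_
      else allelic_richness(gs[[mid]], depths[mid]), numeric(1))
    Ho <- if (!is.na(g$subgenome)) {
      0
    } else {
      mean(vapply(mids, function(mid)
        observed_heterozygosity(table, g$members[[1]], mid), numeric(1)),
        na.rm = TRUE)
    }
    n_alleles <- sum(vapply(gs, function(s) length(s$freqs), integer(1)))
    data.frame(group_id = gid,
               n_accessions = length(g$members[[1]]),
               n_loci_typed = sum(vapply(gs, function(s) s$n_copies > 0,
                                         logical(1))),
               n_alleles = n_alleles,
               gene_diversity = mean(H, na.rm = TRUE),
               observed_heterozygosity = Ho,
               mean_PIC = mean(P, na.rm = TRUE),
               mean_allelic_richness = mean(AR, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- pooled_spectra(spectra)
  g_overall <- min(vapply(pooled, function(s) s$n_copies, integer(1)))
  Ho_all <- stats::weighted.mean(
    out$observed_heterozygosity, out$n_accessions)
  total <- data.frame(
    group_id = "Total",
    n_accessions = sum(out$n_accessions),
    n_loci_typed = sum(vapply(pooled, function(s) s$n_copies > 0, logical(1))),
    n_alleles = sum(vapply(pooled, function(s) length(s$freqs), integer(1))),
    gene_diversity = mean(vapply(pooled, gene_diversity, numeric(1)),
                          na.rm = TRUE),
    observed_heterozygosity = Ho_all,
    mean_PIC = mean(vapply(pooled, pic, numeric(1)), na.rm = TRUE),
    mean_allelic_richness = mean(vapply(pooled, function(s)
      allelic_richness(s, g_overall), numeric(1)), na.rm = TRUE),
    stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
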