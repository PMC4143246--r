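spec_of <- function(freqs, n = 10L) {
  structure(list(group_id = "g", marker_id = "m", freqs = freqs,
                 counts = stats::setNames(as.integer(round(freqs * n)),
                                          names(freqs)),
                 n_copies = n),
            class = "allele_spectrum")
}

test_that("gene diversity and PIC have their closed forms", {
  expect_equal(gene_diversity(c(a = 1)), 0)
  expect_equal(gene_diversity(c(a = 0.5, b = 0.5)), 0.5)
  expect_equal(pic(c(a = 1)), 0)
  expect_equal(pic(c(a = 0.5, b = 0.5)), 0.375)  # 1 - 0.5 - 2*(0.25*0.25)

  # unbiased correction multiplies by n/(n-1)
  sp <- spec_of(c(a = 0.5, b = 0.5), n = 10L)
  expect_equal(gene_diversity(sp, unbiased = TRUE), 0.5 * 10 / 9)

  # random spectra agree with direct algebraic evaluation and PIC <= H
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    p <- stats::runif(k)
    p <- p / sum(p)
    names(p) <- seq_len(k)
    H <- 1 - sum(p^2)
    P <- 1 - sum(p^2) - sum(outer(p^2, p^2)[upper.tri(diag(k))] * 2)
    expect_equal(gene_diversity(p), H, tolerance = 1e-12)
    expect_equal(pic(p), P, tolerance = 1e-12)
    expect_lte(pic(p), gene_diversity(p) + 1e-12)
    expect_lte(H, 1 - 1 / k + 1e-12)
  }
})

test_that("observed heterozygosity counts two-product calls", {
  acc <- data.frame(accession_id = paste0("A", 1:4), taxon = "t", ploidy = 2L)
  calls <- data.frame(
    accession_id = c("A1", "A2", "A2", "A3"),
    marker_id = "M1",
    size = c(153, 153, 156, 156))
  tab <- genotype_table(acc, data.frame(marker_id = "M1"), calls)
  expect_equal(observed_heterozygosity(tab, paste0("A", 1:4), "M1"), 1 / 3)
  # all homozygous
  hom <- genotype_table(acc, data.frame(marker_id = "M1"),
                        data.frame(accession_id = paste0("A", 1:4),
                                   marker_id = "M1", size = 150))
  expect_equal(observed_heterozygosity(hom, paste0("A", 1:4), "M1"), 0)
})

test_that("selfing keeps simulated heterozygosity near its residual", {
  # with selfing rate s, equilibrium Ho ~ H * (1-s)/(2-s) scale; at s = 0.98
  # that is a few percent of H, so mean Ho across loci stays tiny
  sim <- small_sim(seed = 21, n_loci = 12)
  acc <- sim$table$accessions
  dip <- acc$accession_id[acc$ploidy == 2]
  ho <- vapply(sim$table$markers$marker_id, function(m)
    observed_heterozygosity(sim$table, dip, m), numeric(1))
  expect_lt(mean(ho, na.rm = TRUE), 0.1)
})

test_that("rarefied allelic richness matches exhaustive enumeration", {
  # worked example: counts {3, 1}, g = 2 -> 1.5
  expect_equal(allelic_richness(c(a = 3, b = 1), 2), 1.5)
  expect_equal(oracle_richness(c(3, 1), 2), 1.5)
  # monomorphic and full-sample limits
  expect_equal(allelic_richness(c(a = 5), 3), 1)
  counts <- c(a = 4, b = 2, c = 1)
  expect_equal(allelic_richness(counts, sum(counts)), 3)
  expect_true(is.na(allelic_richness(counts, 10)))

  set.seed(31)
  for (i in 1:12) {
    k <- sample(2:4, 1)
    counts <- stats::setNames(sample(1:5, k, replace = TRUE), seq_len(k))
    N <- sum(counts)
    if (N > 12) counts[1] <- counts[1] - (N - 12)
    N <- sum(counts)
    gs <- sort(sample(seq_len(N), min(3, N)))
    prev <- -Inf
    for (g in gs) {
      got <- allelic_richness(counts, g)
      expect_equal(got, oracle_richness(counts, g), tolerance = 1e-12)
      expect_gte(got + 1e-12, prev)   # monotone in g
      prev <- got
    }
  }
})

test_that("locus and group summaries tally alleles, ranges and means", {
  sim <- small_sim(seed = 8)
  pt <- partition_table(sim$table, "V. trinervia")
  groups <- build_genome_groups(sim$table, pt)
  sp <- group_spectra(sim$table, groups, pt)

  ls <- locus_summary(sp)
  expect_equal(nrow(ls), nrow(sim$table$markers))
  expect_equal(ls$size_span, ls$size_max - ls$size_min)
  # independent recount of distinct alleles per locus from raw materials
  for (i in seq_len(nrow(ls))) {
    m <- ls$marker_id[i]
    seen <- unique(unlist(lapply(sp, function(gs) names(gs[[m]]$freqs))))
    expect_equal(ls$n_alleles[i], length(seen))
  }

  gs <- group_summary(sp, sim$table, groups)
  expect_equal(nrow(gs), nrow(groups) + 1)
  body <- gs[gs$group_id != "Total", ]
  expect_true(all(body$gene_diversity >= 0 & body$gene_diversity <= 1))
  expect_true(all(body$mean_PIC <= body$gene_diversity + 1e-9))
  # sub-genome groups are scored single-allele: Ho identically zero
  subg <- groups$group_id[!is.na(groups$subgenome)]
  expect_true(all(gs$observed_heterozygosity[gs$group_id %in% subg] == 0))

  # two groups sharing no alleles: group counts add up in the pooled row
  s1 <- list(M1 = spectrum_from_copies(c(1, 1, 2, 2), "M1", "g1"),
             M2 = spectrum_from_copies(c(5, 6), "M2", "g1"))
  s2 <- list(M1 = spectrum_from_copies(c(7, 7, 8), "M1", "g2"),
             M2 = spectrum_from_copies(c(9, 10), "M2", "g2"))
  pooled <- pooled_spectra(list(g1 = s1, g2 = s2))
  expect_equal(length(pooled$M1$freqs) + length(pooled$M2$freqs), 8)
})

test_that("group means are invariant to accession and marker order", {
  sim <- small_sim(seed = 9, n_loci = 6)
  tab <- sim$table
  pt <- partition_table(tab, "V. trinervia")
  groups <- build_genome_groups(tab, pt)
  sp1 <- group_spectra(tab, groups, pt)
  gs1 <- group_summary(sp1, tab, groups)

  # permute calls and markers
  set.seed(99)
  tab2 <- genotype_table(
    tab$accessions[sample(nrow(tab$accessions)), ],
    tab$markers[sample(nrow(tab$markers)), , drop = FALSE],
    tab$calls[sample(nrow(tab$calls)), ])
  pt2 <- partition_table(tab2, "V. trinervia")
  groups2 <- build_genome_groups(tab2, pt2)
  sp2 <- group_spectra(tab2, groups2, pt2)
  gs2 <- group_summary(sp2, tab2, groups2)
  o1 <- gs1[order(gs1$group_id), ]
  o2 <- gs2[order(gs2$group_id), ]
  expect_equal(o1$gene_diversity, o2$gene_diversity, tolerance = 1e-12)
  expect_equal(o1$mean_PIC, o2$mean_PIC, tolerance = 1e-12)
  expect_equal(o1$n_alleles, o2$n_alleles)
})
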