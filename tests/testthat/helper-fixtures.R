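# Small in-code fixtures shared across tests.

# 4 diploids in 2 taxa plus 2 tetraploids, 3 markers. The reference taxon
# ("ref") sits near 310 bp; tetraploids carry one ref-like and one distant
# product per marker.
toy_table <- function() {
  acc <- data.frame(
    accession_id = c("D1", "D2", "D3", "D4", "T1", "T2"),
    taxon = c("ref", "ref", "other", "other", "tet", "tet"),
    ploidy = c(2L, 2L, 2L, 2L, 4L, 4L),
    stringsAsFactors = FALSE)
  mk <- data.frame(marker_id = c("M1", "M2", "M3"), stringsAsFactors = FALSE)
  calls <- data.frame(
    accession_id = c("D1", "D2", "D3", "D4", "T1", "T1", "T2", "T2",
                     "D1", "D2", "D3", "D4", "T1", "T1", "T2", "T2",
                     "D1", "D2", "D3", "D4", "T1", "T1", "T2", "T2"),
    marker_id = rep(c("M1", "M2", "M3"), each = 8),
    size = c(310, 310, 313, 316, 310, 348, 313, 351,
             200, 203, 221, 224, 203, 224, 200, 221,
             150, 150, 150, 150, 150, 162, 150, 162),
    stringsAsFactors = FALSE)
  genotype_table(acc, mk, calls)
}

# random valid genotype table for round-trip property tests
random_table <- function(n_acc = 10, n_mark = 5, seed = 1) {
  set.seed(seed)
  acc <- data.frame(
    accession_id = sprintf("A%02d", seq_len(n_acc)),
    taxon = sample(c("tx1", "tx2", "tet"), n_acc, replace = TRUE),
    ploidy = 2L, stringsAsFactors = FALSE)
  acc$ploidy[acc$taxon == "tet"] <- 4L
  mk <- data.frame(marker_id = sprintf("M%02d", seq_len(n_mark)),
                   stringsAsFactors = FALSE)
  rows <- list()
  for (a in acc$accession_id) for (m in mk$marker_id) {
    k <- sample(0:2, 1, prob = c(0.15, 0.5, 0.35))
    if (k == 0) next
    sizes <- sort(sample(seq(100, 160, by = 3), k))
    rows[[length(rows) + 1]] <- data.frame(
      accession_id = a, marker_id = m, size = sizes,
      stringsAsFactors = FALSE)
  }
  genotype_table(acc, mk, do.call(rbind, rows))
}

# scaled-down simulation (fast enough for per-test use)
small_sim <- function(seed = 1, n_loci = 10) {
  t <- default_taxa()
  t$n_accessions <- c(8L, 4L, 8L, 4L, 6L, 6L, 8L, 3L)
  generate_dataset(simulation_config(n_loci = n_loci, taxa = t,
                                     pop_size = 40, seed = seed))
}

expect_same_table <- function(a, b) {
  expect_equal(a$accessions[order(a$accessions$accession_id),
                            c("accession_id", "taxon", "ploidy")],
               b$accessions[order(b$accessions$accession_id),
                            c("accession_id", "taxon", "ploidy")],
               ignore_attr = TRUE)
  expect_setequal(a$markers$marker_id, b$markers$marker_id)
  ka <- a$calls[order(a$calls$accession_id, a$calls$marker_id, a$calls$size),
                c("accession_id", "marker_id", "size")]
  kb <- b$calls[order(b$calls$accession_id, b$calls$marker_id, b$calls$size),
                c("accession_id", "marker_id", "size")]
  expect_equal(ka, kb, ignore_attr = TRUE)
}
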