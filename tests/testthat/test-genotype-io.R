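test_that("long and wide CSV round-trips reproduce the table", {
  tab <- toy_table()
  for (dialect in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_genotype_table(tab, f, dialect)
    expect_same_table(read_genotype_table(f, dialect), tab)
  }
  # property: random tables round-trip in both dialects
  for (seed in 1:5) {
    tab <- random_table(seed = seed)
    for (dialect in c("long", "wide")) {
      f <- withr::local_tempfile(fileext = ".csv")
      write_genotype_table(tab, f, dialect)
      expect_same_table(read_genotype_table(f, dialect), tab)
    }
  }
})

test_that("wide homozygote coding collapses to a single product", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,taxon,ploidy,M1_1,M1_2",
               "ACC1,Vt,2,153,153",
               "ACC2,Vt,2,153,156",
               "ACC3,Vt,2,,"), f)
  tab <- read_genotype_table(f, "wide")
  expect_equal(call_sizes(tab, "ACC1", "M1"), 153L)
  expect_equal(call_sizes(tab, "ACC2", "M1"), c(153L, 156L))
  expect_length(call_sizes(tab, "ACC3", "M1"), 0)
})

test_that("reader flags bad cells and rejects conflicts and bad ploidy", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,taxon,ploidy,marker_id,allele1",
               "A1,t,2,M1,153", "A2,t,2,M1,xx"), f)
  expect_warning(tab <- read_genotype_table(f, "long"), "unparseable")
  expect_length(call_sizes(tab, "A2", "M1"), 0)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,taxon,ploidy,marker_id,allele1",
               "A1,t,2,M1,153", "A1,t,2,M1,156"), f2)
  expect_error(read_genotype_table(f2, "long"), "conflicting")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession_id,taxon,ploidy,marker_id,allele1",
               "A1,t,3,M1,153"), f3)
  expect_error(read_genotype_table(f3, "long"), "ploidy")
})

test_that("an empty table writes a header-only file", {
  tab <- genotype_table(
    data.frame(accession_id = character(), taxon = character(),
               ploidy = integer()),
    data.frame(marker_id = character()),
    data.frame())
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(tab, f, "long")
  expect_length(readLines(f), 1)
})

test_that("allele frequencies count gene copies and sum to one", {
  acc <- data.frame(accession_id = paste0("A", 1:5), taxon = "t", ploidy = 2L)
  mk <- data.frame(marker_id = "M1")
  calls <- data.frame(accession_id = paste0("A", 1:4), marker_id = "M1",
                      size = c(153, 153, 156, 159))
  tab <- genotype_table(acc, mk, calls)
  sp <- allele_frequencies(tab, paste0("A", 1:4), "M1", copies_per_call = 1)
  expect_equal(sp$freqs, c("153" = 0.5, "156" = 0.25, "159" = 0.25))
  expect_equal(sp$n_copies, 4L)

  # all calls missing -> empty spectrum, not an error
  sp0 <- allele_frequencies(tab, "A5", "M1")
  expect_equal(sp0$n_copies, 0L)
  expect_length(sp0$freqs, 0)

  # two-allele coding doubles homozygote copies
  sp2 <- allele_frequencies(tab, paste0("A", 1:4), "M1", copies_per_call = 2)
  expect_equal(sp2$n_copies, 8L)
  expect_equal(unname(sp2$freqs["153"]), 0.5)

  # property: frequencies of every non-empty spectrum sum to 1
  for (seed in 1:5) {
    rt <- random_table(seed = seed)
    for (m in rt$markers$marker_id) {
      sp <- allele_frequencies(rt, rt$accessions$accession_id, m)
      if (sp$n_copies > 0) expect_equal(sum(sp$freqs), 1, tolerance = 1e-9)
    }
  }
})

test_that("marker classification follows the category precedence", {
  tab <- toy_table()
  # M1: one product per diploid, two discrete in both tetraploids, polymorphic
  expect_equal(as.character(classify_marker(tab, "M1")), "TWO_IN_TETRAPLOID")
  expect_equal(as.character(classify_marker(tab, "M2")), "TWO_IN_TETRAPLOID")
  # M3: diploids monomorphic but tetraploids polymorphic -> still TWO_IN
  expect_equal(as.character(classify_marker(tab, "M3")), "TWO_IN_TETRAPLOID")

  add_call <- function(t, a, m, s) {
    calls <- rbind(t$calls[, c("accession_id", "marker_id", "size")],
                   data.frame(accession_id = a, marker_id = m, size = s))
    genotype_table(t$accessions, t$markers, calls)
  }
  drop_calls <- function(t, a, m) {
    keep <- !(t$calls$accession_id %in% a & t$calls$marker_id == m)
    genotype_table(t$accessions, t$markers, t$calls[keep, ])
  }
  # a 520 bp product anywhere -> OVER_SIZE
  expect_equal(as.character(classify_marker(add_call(tab, "T1", "M1", 520),
                                            "M1")), "OVER_SIZE")
  # two products in a diploid -> MULTIPLE_PRODUCTS
  expect_equal(as.character(classify_marker(add_call(tab, "D1", "M1", 340),
                                            "M1")), "MULTIPLE_PRODUCTS")
  # single product in a tetraploid -> SINGLE_IN_TETRAPLOID
  t2 <- drop_calls(tab, "T1", "M1")
  t2 <- add_call(t2, "T1", "M1", 310)
  expect_equal(as.character(classify_marker(t2, "M1")), "SINGLE_IN_TETRAPLOID")
  # missing in one accession -> AMPLIFIED_SOME
  expect_equal(as.character(classify_marker(drop_calls(tab, "D1", "M1"),
                                            "M1")), "AMPLIFIED_SOME")
  # no calls at all -> NOT_AMPLIFIED
  expect_equal(as.character(classify_marker(
    drop_calls(tab, tab$accessions$accession_id, "M1"), "M1")),
    "NOT_AMPLIFIED")
  # one identical product everywhere -> MONOMORPHIC
  mono <- genotype_table(tab$accessions, data.frame(marker_id = "Mx"),
                         data.frame(accession_id = tab$accessions$accession_id,
                                    marker_id = "Mx", size = 150))
  expect_equal(as.character(classify_marker(mono, "Mx")), "MONOMORPHIC")
  expect_error(classify_marker(tab, "nope"), "unknown marker")
})

test_that("selection report tabulates all categories and the pass list", {
  tab <- toy_table()
  rep <- selection_report(tab)
  expect_equal(sum(rep$counts), nrow(tab$markers))
  expect_setequal(rep$pass, c("M1", "M2", "M3"))
  expect_equal(names(rep$counts),
               c("NOT_AMPLIFIED", "AMPLIFIED_SOME", "OVER_SIZE",
                 "MULTIPLE_PRODUCTS", "MONOMORPHIC",
                 "SINGLE_IN_TETRAPLOID", "TWO_IN_TETRAPLOID"))
  # no tetraploids: tetraploid categories empty, with a note
  dips <- subset_accessions(tab, c("D1", "D2", "D3", "D4"))
  expect_message(rep2 <- selection_report(dips), "no tetraploid")
  expect_equal(unname(rep2$counts["SINGLE_IN_TETRAPLOID"]), 0L)
})

test_that("simulated screening panel reproduces the constructed category mix", {
  sim <- small_sim(seed = 3)
  panel <- screening_panel(sim$table, 2)
  expect_equal(nrow(panel$accessions), 16)
  rep <- selection_report(panel)
  expect_equal(sum(rep$counts), nrow(sim$table$markers))
  # every simulated marker amplifies everywhere (no missingness simulated)
  expect_equal(unname(rep$counts["NOT_AMPLIFIED"] +
                        rep$counts["AMPLIFIED_SOME"]), 0L)
})
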