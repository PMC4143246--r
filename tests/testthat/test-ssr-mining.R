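test_that("canonical families are closed under rotation and reverse complement", {
  expect_equal(canonical_family("GA"), "AG")
  expect_equal(canonical_family("CT"), "AG")
  expect_equal(canonical_family("AT"), "AT")
  expect_error(canonical_family("ATAT"), "degenerate")
  expect_error(canonical_family("AXG"), "ACGT")

  # exhaustive closure over every non-degenerate 2/3/4-mer
  bases <- c("A", "C", "G", "T")
  for (u in 2:4) {
    motifs <- apply(expand.grid(rep(list(bases), u)), 1, paste, collapse = "")
    motifs <- motifs[vapply(motifs, oracle_period, integer(1)) == u]
    for (m in motifs) {
      fam <- canonical_family(m)
      expect_equal(fam, oracle_family(m))
      expect_equal(canonical_family(fam), fam)  # idempotent
    }
  }
})

test_that("perfect finder reports maximal runs above the length threshold", {
  h <- find_perfect_ssrs("ATATATATATATATAT")
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 16L)
  expect_equal(h$family, "AT")
  expect_equal(h$unit_len, 2L)

  expect_equal(nrow(find_perfect_ssrs("AAGAAGAAGAAGA")), 0)  # 13 nt < 15
  expect_equal(nrow(find_perfect_ssrs("")), 0)
  # N breaks runs
  expect_equal(nrow(find_perfect_ssrs(
    paste0(strrep("AG", 5), "N", strrep("AG", 5)))), 0)
})

test_that("perfect finder matches the naive quadratic scanner on random input", {
  set.seed(101)
  for (rep in 1:8) {
    # random background with planted runs so hits actually occur
    bg <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
    s <- paste(bg, collapse = "")
    ins <- c(strrep("AG", 9), strrep("TCA", 6), strrep("GATC", 4))
    for (x in ins) {
      at <- sample(300, 1)
      s <- paste0(substr(s, 1, at), x, substr(s, at + 1, nchar(s)))
    }
    got <- find_perfect_ssrs(s)
    want <- oracle_perfect(s)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("imperfect finder detects mismatched arrays and honors the budget", {
  # (AAG)5 with one C substitution, 15 nt
  h <- find_imperfect_ssrs("AAGAAGAAGAACAAG")
  expect_equal(nrow(h), 1)
  expect_equal(h$family, canonical_family("AAG"))
  expect_equal(h$length, 15L)
  expect_equal(h$mismatches, 1L)

  # zero-mismatch mode equals the perfect finder hit-for-hit
  set.seed(77)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    s <- paste0(s, strrep("AG", 8), strrep("CTT", 6))
    expect_equal(find_imperfect_ssrs(s, max_mismatch = 0),
                 find_perfect_ssrs(s), ignore_attr = TRUE)
  }
})

test_that("imperfect finder matches the naive quadratic scanner", {
  set.seed(202)
  for (rep in 1:5) {
    bg <- sample(c("A", "C", "G", "T"), 250, replace = TRUE)
    s <- paste(bg, collapse = "")
    # plant mutated arrays
    plant <- function(unit, n_rep, n_mut) {
      x <- strsplit(strrep(unit, n_rep), "")[[1]]
      pos <- sample(length(x), n_mut)
      x[pos] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
      paste(x, collapse = "")
    }
    for (x in c(plant("AG", 10, 1), plant("ACT", 7, 2), plant("AAAG", 5, 1))) {
      at <- sample(200, 1)
      s <- paste0(substr(s, 1, at), x, substr(s, at + 1, nchar(s)))
    }
    got <- find_imperfect_ssrs(s)
    want <- oracle_imperfect(s)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("planted arrays are recalled with correct coordinates", {
  set.seed(303)
  for (rep in 1:10) {
    bg <- sample(c("C", "G"), 120, replace = TRUE)  # AT-free background
    unit <- sample(c("AT", "AAT", "AATT"), 1)
    n_rep <- ceiling(18 / nchar(unit))
    arr <- strsplit(strrep(unit, n_rep), "")[[1]]
    mut_at <- sample(seq(2, length(arr) - 1), 1)
    arr[mut_at] <- "G"
    at <- sample(60, 1)
    s <- paste0(paste(bg[1:at], collapse = ""), paste(arr, collapse = ""),
                paste(bg[(at + 1):120], collapse = ""))
    h <- find_imperfect_ssrs(s)
    h <- h[h$family == canonical_family(unit), , drop = FALSE]
    expect_gte(nrow(h), 1)
    # the planted array is covered by the reported hit
    expect_lte(h$start[1], at + 1)
    expect_gte(h$end[1], at + length(arr) - 1)
  }
})

test_that("hits never overlap within a family and slice to their length", {
  set.seed(404)
  s <- paste0(paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
              strrep("AG", 10), "T", strrep("GA", 9))
  h <- find_imperfect_ssrs(s)
  expect_true(all(h$end - h$start == h$length))
  for (fam in unique(h$family)) {
    hf <- h[h$family == fam, ]
    if (nrow(hf) < 2) next
    hf <- hf[order(hf$start), ]
    expect_true(all(hf$start[-1] >= hf$end[-nrow(hf)]))
  }
})

test_that("FASTA mining summarizes planted repeats and density", {
  f <- withr::local_tempfile(fileext = ".fa")
  set.seed(9)
  bg <- function(n) paste(sample(c("C", "G"), n, TRUE), collapse = "")
  writeLines(c(
    ">s1 first", paste0(bg(50), strrep("AT", 10), bg(50)),
    ">s2", paste0(bg(40), strrep("AAG", 6), bg(40)),
    ">s3 empty-ish", bg(80)), f)
  res <- mine_fasta(f, max_mismatch = 0)
  expect_equal(res$summary$n_sequences, 3)
  expect_equal(unname(res$summary$counts_by_unit_len), c(1L, 1L, 0L))
  expect_equal(res$summary$n_hits, 2)
  expect_equal(res$summary$density_bp_per_ssr,
               res$summary$total_bases / 2)
  expect_setequal(res$hits$seq_id, c("s1", "s2"))

  # no repeats -> no hits, density reported as NULL
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", bg(60)), f2)
  res2 <- mine_fasta(f2, max_mismatch = 0)
  expect_equal(res2$summary$n_hits, 0)
  expect_null(res2$summary$density_bp_per_ssr)

  # duplicate ids rejected
  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f3)
  expect_error(mine_fasta(f3), "duplicate")
})

test_that("repeat-class percentages reproduce printed proportions", {
  # published worked example: 137/1400/140 di/tri/tetra out of 1677
  expect_equal(unname(repeat_class_percentages(c("2" = 137, "3" = 1400,
                                                 "4" = 140))),
               c(8.2, 83.5, 8.3))
  expect_equal(unname(repeat_class_percentages(c(1, 0, 0))), c(100, 0, 0))
  expect_error(repeat_class_percentages(c(0, 0, 0)), "not all zero")
  # cross-check rounding against exact rational arithmetic
  x <- c(71, 27, 2)
  expect_equal(unname(repeat_class_percentages(x)),
               round(100 * x / sum(x), 1))
  expect_equal(sum(repeat_class_percentages(c(1, 1, 1))), 100, tolerance = 0.2)
  # an EST set of 4.3 Mbp with 1188 SSRs has one SSR per ~3.6 kb
  expect_equal(round(4.3e6 / 1188 / 1000, 1), 3.6)
})

test_that("amplicon size helper applies the design window", {
  expect_true(amplicon_size_ok(153))
  expect_false(amplicon_size_ok(89))
  expect_false(amplicon_size_ok(301))
})
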