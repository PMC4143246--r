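#' Construct a genotype table
#'
#' The central container of the package: co-dominant SSR allele-size calls for
#' a panel of accessions at a set of markers, plus the accession metadata
#' (taxon, ploidy) that downstream partitioning and diversity statistics need.
#' Calls are stored long, one row per discrete PCR product, so a call may hold
#' zero (missing), one, two, or more products.
#'
#' @param accessions data.frame with columns `accession_id`, `taxon`,
#'   `ploidy` (2 or 4), and optionally `subtaxon` and `origin`.
#' @param markers data.frame with column `marker_id` and optionally `motif`,
#'   `size_min`, `size_max` (expected product-size range in bp, within
#'   90--500) and `fluor`.
#' @param calls data.frame with columns `accession_id`, `marker_id`, `size`
#'   (integer bp, one row per discrete product) and optionally `peak_height`
#'   (RFU). Sizes are rounded to integer bp on ingest; duplicate sizes within
#'   a call are collapsed (a homozygote is one product).
#' @param rfu_window length-2 numeric; products whose `peak_height` is present
#'   and falls outside this window are dropped with a warning.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(accessions, markers, calls,
                           rfu_window = c(500, 10000)) {
  accessions <- as.data.frame(accessions, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  need(accessions, c("accession_id", "taxon", "ploidy"), "accessions")
  need(markers, "marker_id", "markers")
  if (nrow(calls)) need(calls, c("accession_id", "marker_id", "size"), "calls")

  if (anyDuplicated(accessions$accession_id))
    stop("duplicate accession_id in accessions")
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker_id in markers")
  if (!all(accessions$ploidy %in% c(2L, 4L)))
    stop("unknown ploidy: ploidy must be 2 or 4")
  if (is.null(accessions$subtaxon))
    accessions$subtaxon <- rep(NA_character_, nrow(accessions))
  if (is.null(accessions$origin))
    accessions$origin <- rep(NA_character_, nrow(accessions))
  if (!is.null(markers$size_min)) {
    bad <- !is.na(markers$size_min) & !is.na(markers$size_max) &
      (markers$size_min > markers$size_max |
         markers$size_min < 90 | markers$size_max > 500)
    if (any(bad))
      stop("expected size range must satisfy 90 <= min <= max <= 500 for: ",
           paste(markers$marker_id[bad], collapse = ", "))
  }

  if (nrow(calls)) {
    if (!all(calls$accession_id %in% accessions$accession_id))
      stop("calls reference unknown accession_id")
    if (!all(calls$marker_id %in% markers$marker_id))
      stop("calls reference unknown marker_id")
    calls$size <- as.integer(round(as.numeric(calls$size)))
    if (any(is.na(calls$size)) || any(calls$size <= 0))
      stop("allele sizes must be positive integers")
    if (is.null(calls$peak_height)) calls$peak_height <- NA_real_
    out_of_window <- !is.na(calls$peak_height) &
      (calls$peak_height < rfu_window[1] | calls$peak_height > rfu_window[2])
    if (any(out_of_window)) {
      warning(sum(out_of_window), " product(s) outside the RFU validity window [",
              rfu_window[1], ", ", rfu_window[2], "] dropped")
      calls <- calls[!out_of_window, , drop = FALSE]
    }
    # collapse duplicate sizes within a call, sort ascending within call
    key <- paste(calls$accession_id, calls$marker_id, sep = "\r")
    dup <- duplicated(paste(key, calls$size, sep = "\r"))
    calls <- calls[!dup, , drop = FALSE]
    o <- order(calls$accession_id, calls$marker_id, calls$size)
    calls <- calls[o, , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(accession_id = character(), marker_id = character(),
                        size = integer(), peak_height = numeric(),
                        stringsAsFactors = FALSE)
  }

  structure(list(accessions = accessions,
                 markers = markers[, intersect(
                   c("marker_id", "motif", "size_min", "size_max", "fluor"),
                   names(markers)), drop = FALSE],
                 calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$accessions), "accessions x",
      nrow(x$markers), "markers;",
      nrow(x$calls), "allele-size products\n")
  tp <- table(x$accessions$taxon, x$accessions$ploidy)
  cat("taxa:\n")
  print(tp)
  invisible(x)
}

# products of one call as a sorted integer vector (length 0 = missing)
call_sizes <- function(table, accession_id, marker_id) {
  cl <- table$calls
  cl$size[cl$accession_id == accession_id & cl$marker_id == marker_id]
}

#' Read a genotype table from CSV
#'
#' Two dialects are supported. `long`: one row per call, columns
#' `accession_id, taxon, ploidy, marker_id, allele1[, allele2, peak1, peak2]`
#' (blank `allele2` = single product). `wide`: one row per accession with
#' leading columns `accession_id, taxon, ploidy[, subtaxon, origin]` followed
#' by two columns `<marker>_1`, `<marker>_2` per marker; a blank pair is a
#' missing call and a duplicated size is a single product (homozygote coding).
#'
#' Unparseable allele cells are recorded as missing; the number of such cells
#' is reported in a warning. Rows that restate an existing
#' (accession, marker) call with conflicting sizes are a hard error.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  n_bad <- 0L
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    n_bad <<- n_bad + sum(!is.na(x) & nzchar(trimws(x)) & is.na(v))
    v
  }

  if (dialect == "long") {
    need <- c("accession_id", "taxon", "ploidy", "marker_id", "allele1")
    if (!all(need %in% names(raw)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    acc <- unique(raw[, intersect(c("accession_id", "taxon", "ploidy",
                                    "subtaxon", "origin"), names(raw))])
    if (anyDuplicated(acc$accession_id))
      stop("conflicting accession metadata for the same accession_id")
    acc$ploidy <- as.integer(acc$ploidy)
    if (any(is.na(acc$ploidy))) stop("unknown ploidy value")
    markers <- data.frame(marker_id = unique(raw$marker_id),
                          stringsAsFactors = FALSE)
    key <- paste(raw$accession_id, raw$marker_id, sep = "\r")
    if (anyDuplicated(key)) {
      cols <- intersect(c("allele1", "allele2"), names(raw))
      conflict <- vapply(split(seq_len(nrow(raw)), key), function(i)
        length(i) > 1 && nrow(unique(raw[i, cols, drop = FALSE])) > 1,
        logical(1))
      if (any(conflict))
        stop("duplicate (accession, marker) rows with conflicting sizes")
      raw <- raw[!duplicated(key), , drop = FALSE]
    }
    a1 <- num(raw$allele1)
    a2 <- if ("allele2" %in% names(raw)) num(raw$allele2) else rep(NA_real_, nrow(raw))
    p1 <- if ("peak1" %in% names(raw)) num(raw$peak1) else rep(NA_real_, nrow(raw))
    p2 <- if ("peak2" %in% names(raw)) num(raw$peak2) else rep(NA_real_, nrow(raw))
    calls <- data.frame(
      accession_id = c(raw$accession_id, raw$accession_id),
      marker_id = c(raw$marker_id, raw$marker_id),
      size = c(a1, a2), peak_height = c(p1, p2),
      stringsAsFactors = FALSE)
    calls <- calls[!is.na(calls$size), , drop = FALSE]
  } else {
    lead <- intersect(c("accession_id", "taxon", "ploidy", "subtaxon", "origin"),
                      names(raw))
    if (!all(c("accession_id", "taxon", "ploidy") %in% lead))
      stop("wide dialect requires leading columns accession_id, taxon, ploidy")
    acc <- raw[, lead, drop = FALSE]
    acc$ploidy <- as.integer(acc$ploidy)
    if (any(is.na(acc$ploidy))) stop("unknown ploidy value")
    allele_cols <- setdiff(names(raw), lead)
    mk <- sub("_[12]$", "", allele_cols)
    if (!all(grepl("_[12]$", allele_cols)))
      stop("wide dialect allele columns must be named <marker>_1 / <marker>_2")
    markers <- data.frame(marker_id = unique(mk), stringsAsFactors = FALSE)
    pieces <- lapply(allele_cols, function(cn) {
      data.frame(accession_id = raw$accession_id,
                 marker_id = sub("_[12]$", "", cn),
                 size = num(raw[[cn]]),
                 peak_height = NA_real_, stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, pieces)
    calls <- calls[!is.na(calls$size), , drop = FALSE]
  }
  if (n_bad > 0)
    warning(n_bad, " unparseable allele cell(s) recorded as missing")
  genotype_table(acc, markers, calls)
}

#' Write a genotype table to CSV
#'
#' `read_genotype_table(write_genotype_table(x, ...))` reproduces `x` exactly.
#' Single-product calls are written with the size duplicated in both allele
#' columns (the usual co-dominant convention); calls with more than two
#' discrete products cannot be represented in either dialect and are an error.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  acc <- table$accessions
  cl <- table$calls
  key <- paste(cl$accession_id, cl$marker_id, sep = "\r")
  if (any(table(key) > 2))
    stop("calls with more than two discrete products cannot be written")
  first <- !duplicated(key)
  second <- duplicated(key)
  base <- cl[first, , drop = FALSE]
  a2 <- cl$size[second][match(key[first], key[second])]
  p2 <- cl$peak_height[second][match(key[first], key[second])]
  a2[is.na(a2)] <- base$size[is.na(a2)]        # homozygote coding
  if (dialect == "long") {
    m <- match(base$accession_id, acc$accession_id)
    out <- data.frame(accession_id = base$accession_id,
                      taxon = acc$taxon[m], ploidy = acc$ploidy[m],
                      subtaxon = acc$subtaxon[m], origin = acc$origin[m],
                      marker_id = base$marker_id,
                      allele1 = base$size, allele2 = a2,
                      peak1 = base$peak_height, peak2 = p2,
                      stringsAsFactors = FALSE)
    out <- out[order(out$accession_id, out$marker_id), , drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    out <- acc[, c("accession_id", "taxon", "ploidy", "subtaxon", "origin")]
    for (mid in table$markers$marker_id) {
      i <- match(paste(out$accession_id, mid, sep = "\r"), key[first])
      out[[paste0(mid, "_1")]] <- base$size[i]
      out[[paste0(mid, "_2")]] <- a2[i]
    }
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Allele frequencies for a group of accessions at one marker
#'
#' @param table a [genotype_table()].
#' @param group character vector of accession ids (nonempty).
#' @param marker_id marker to tabulate.
#' @param copies_per_call 1 or 2. With 1 each non-missing call contributes a
#'   single gene copy (the paper-style single-allele scoring; for a call with
#'   two products the one with the highest recorded peak is used, falling back
#'   to the smaller size). With 2 both alleles are counted and a
#'   single-product call counts as a homozygote (two copies).
#' @return An `allele_spectrum`: list with `marker_id`, `freqs` (named numeric,
#'   names = allele sizes in bp, all > 0, summing to 1), `counts` (gene-copy
#'   counts per allele) and `n_copies`. An all-missing group yields an empty
#'   spectrum with `n_copies = 0` (flagged, not an error).
#' @export
allele_frequencies <- function(table, group, marker_id, copies_per_call = 1) {
  stopifnot(length(group) >= 1)
  if (!marker_id %in% table$markers$marker_id)
    stop("unknown marker: ", marker_id)
  if (!all(group %in% table$accessions$accession_id))
    stop("unknown accession id(s) in group")
  if (!copies_per_call %in% c(1, 2)) stop("copies_per_call must be 1 or 2")
  cl <- table$calls
  cl <- cl[cl$marker_id == marker_id & cl$accession_id %in% group, , drop = FALSE]
  copies <- integer(0)
  for (aid in unique(cl$accession_id)) {
    rows <- cl[cl$accession_id == aid, , drop = FALSE]
    sz <- rows$size
    if (copies_per_call == 1) {
      if (length(sz) == 1L) pick <- sz
      else if (any(!is.na(rows$peak_height)))
        pick <- sz[which.max(ifelse(is.na(rows$peak_height), -Inf,
                                    rows$peak_height))]
      else pick <- min(sz)
      copies <- c(copies, pick)
    } else {
      if (length(sz) == 1L) copies <- c(copies, sz, sz)
      else if (length(sz) == 2L) copies <- c(copies, sz)
      else {
        warning("call with >2 products at ", marker_id, " for ", aid,
                " skipped under two-allele coding")
      }
    }
  }
  spectrum_from_copies(copies, marker_id)
}

# build an allele_spectrum from a vector of gene copies (allele sizes)
spectrum_from_copies <- function(copies, marker_id = NA_character_,
                                 group_id = NA_character_) {
  copies <- copies[!is.na(copies)]
  if (!length(copies)) {
    return(structure(list(group_id = group_id, marker_id = marker_id,
                          freqs = numeric(0), counts = integer(0),
                          n_copies = 0L),
                     class = "allele_spectrum"))
  }
  tab <- table(copies)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(group_id = group_id, marker_id = marker_id,
                 freqs = counts / sum(counts), counts = counts,
                 n_copies = sum(counts)),
            class = "allele_spectrum")
}

#' Classify a marker into the screening categories
#'
#' Reproduces the marker-quality screen used to pick donor-informative
#' markers: a usable marker amplifies one product in every diploid and two
#' discrete products in every tetraploid, and is polymorphic. Categories are
#' assigned with a fixed precedence so that classification is total and
#' deterministic:
#' `NOT_AMPLIFIED` > `AMPLIFIED_SOME` > `OVER_SIZE` > `MULTIPLE_PRODUCTS` >
#' `MONOMORPHIC` > `SINGLE_IN_TETRAPLOID` > `TWO_IN_TETRAPLOID`.
#'
#' @param table a [genotype_table()] (typically a small screening panel).
#' @param marker_id marker to classify.
#' @param size_cap products larger than this (bp) make the marker `OVER_SIZE`.
#' @return character scalar, one of the seven categories above, with attribute
#'   `n_amplified` (number of accessions with at least one product).
#' @export
classify_marker <- function(table, marker_id, size_cap = 500) {
  if (!marker_id %in% table$markers$marker_id)
    stop("unknown marker: ", marker_id)
  acc <- table$accessions
  cl <- table$calls[table$calls$marker_id == marker_id, , drop = FALSE]
  n_products <- vapply(acc$accession_id, function(a)
    sum(cl$accession_id == a), integer(1))
  n_amp <- sum(n_products > 0)
  out <- if (n_amp == 0) "NOT_AMPLIFIED"
  else if (n_amp < nrow(acc)) "AMPLIFIED_SOME"
  else if (any(cl$size > size_cap)) "OVER_SIZE"
  else if (any(n_products > 2) ||
           any(n_products[acc$ploidy == 2] > 1)) "MULTIPLE_PRODUCTS"
  else if (length(unique(cl$size)) == 1L) "MONOMORPHIC"
  else if (any(acc$ploidy == 4) &&
           any(n_products[acc$ploidy == 4] == 1)) "SINGLE_IN_TETRAPLOID"
  else "TWO_IN_TETRAPLOID"
  attr(out, "n_amplified") <- n_amp
  out
}

marker_categories <- c("NOT_AMPLIFIED", "AMPLIFIED_SOME", "OVER_SIZE",
                       "MULTIPLE_PRODUCTS", "MONOMORPHIC",
                       "SINGLE_IN_TETRAPLOID", "TWO_IN_TETRAPLOID")

#' Marker screening report
#'
#' Classifies every marker and tabulates the categories; the pass list
#' contains the markers suitable for sub-genome analysis
#' (`TWO_IN_TETRAPLOID`).
#'
#' @inheritParams classify_marker
#' @return list with `counts` (named integer over all seven categories, in
#'   precedence order, summing to the number of markers), `categories`
#'   (per-marker assignment) and `pass` (character vector of marker ids).
#' @export
selection_report <- function(table, size_cap = 500) {
  cats <- vapply(table$markers$marker_id, function(m)
    as.character(classify_marker(table, m, size_cap)), character(1))
  counts <- vapply(marker_categories, function(k) sum(cats == k), integer(1))
  if (!any(table$accessions$ploidy == 4))
    message("no tetraploid accessions: SINGLE/TWO_IN_TETRAPLOID are empty")
  list(counts = counts, categories = cats,
       pass = names(cats)[cats == "TWO_IN_TETRAPLOID"])
}

#' Extract a screening panel
#'
#' Returns a sub-table holding the first `per_taxon` accessions of each taxon
#' (by accession id order), mirroring the small multi-taxon panels used for
#' marker screening before full genotyping.
#'
#' @param table a [genotype_table()].
#' @param per_taxon accessions retained per taxon.
#' @return a [genotype_table()] restricted to the panel accessions.
#' @export
screening_panel <- function(table, per_taxon = 2) {
  acc <- table$accessions[order(table$accessions$accession_id), , drop = FALSE]
  keep <- unlist(lapply(split(acc$accession_id, acc$taxon),
                        utils::head, per_taxon))
  subset_accessions(table, keep)
}

# restrict a genotype table to a set of accessions and/or markers
subset_accessions <- function(table, accession_ids,
                              marker_ids = table$markers$marker_id) {
  genotype_table(
    table$accessions[table$accessions$accession_id %in% accession_ids, ,
                     drop = FALSE],
    table$markers[table$markers$marker_id %in% marker_ids, , drop = FALSE],
    table$calls[table$calls$accession_id %in% accession_ids &
                  table$calls$marker_id %in% marker_ids, , drop = FALSE])
}
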