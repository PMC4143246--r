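#' Reference allele profile of the anchor taxon
#'
#' Collects, per marker, the set of allele sizes observed in the diploid
#' reference (anchor) taxon. The anchor is the diploid species against which
#' tetraploid products are compared: the product closest to the anchor's
#' alleles is scored as sub-genome A.
#'
#' @param table a [genotype_table()].
#' @param ref_taxon taxon name; must be present and diploid.
#' @return list with `profile` (named list marker_id -> sorted integer sizes,
#'   only markers with at least one reference call) and `no_reference`
#'   (marker ids with no reference data).
#' @export
reference_profile <- function(table, ref_taxon) {
  acc <- table$accessions
  ref_acc <- acc$accession_id[acc$taxon == ref_taxon]
  if (!length(ref_acc)) stop("reference taxon not present: ", ref_taxon)
  if (any(acc$ploidy[acc$taxon == ref_taxon] != 2))
    stop("only diploid taxa can anchor the partition: ", ref_taxon)
  cl <- table$calls[table$calls$accession_id %in% ref_acc, , drop = FALSE]
  prof <- lapply(split(cl$size, cl$marker_id), function(s) sort(unique(s)))
  list(profile = prof,
       no_reference = setdiff(table$markers$marker_id, names(prof)))
}

#' Partition one tetraploid call into sub-genomes A and B
#'
#' Given the two discrete products of a tetraploid call, the product nearer
#' (in bp) to the reference allele set is scored A, the other B. Distance is
#' nearest-neighbor distance `d(s) = min |s - r|` over reference alleles `r`.
#' If the two products are equidistant the call is flagged `tied` and A is
#' the product whose minimizing reference allele is numerically smaller,
#' falling back to assigning the smaller product size to A. Two identical
#' sizes yield status `single_product` with the size in both slots.
#'
#' @param products numeric vector of the two product sizes.
#' @param ref_sizes nonempty numeric vector of reference allele sizes.
#' @return list with `A`, `B` (sizes) and `status` (`"assigned"`, `"tied"`,
#'   or `"single_product"`).
#' @export
partition_call <- function(products, ref_sizes) {
  stopifnot(length(products) == 2, length(ref_sizes) >= 1)
  s <- sort(products)
  if (s[1] == s[2])
    return(list(A = s[1], B = s[1], status = "single_product"))
  d <- vapply(s, function(x) min(abs(x - ref_sizes)), numeric(1))
  nearest <- vapply(s, function(x)
    min(ref_sizes[abs(x - ref_sizes) == min(abs(x - ref_sizes))]), numeric(1))
  if (d[1] < d[2]) list(A = s[1], B = s[2], status = "assigned")
  else if (d[2] < d[1]) list(A = s[2], B = s[1], status = "assigned")
  else if (nearest[1] < nearest[2]) list(A = s[1], B = s[2], status = "tied")
  else if (nearest[2] < nearest[1]) list(A = s[2], B = s[1], status = "tied")
  else list(A = s[1], B = s[2], status = "tied")
}

#' Partition every tetraploid call of a genotype table
#'
#' Applies [partition_call()] to each (tetraploid accession, marker) pair,
#' anchored on the allele profile of `ref_taxon`. Diploid calls are left
#' untouched. Markers without reference data get status `no_reference` for
#' all their tetraploid entries (excluded from downstream statistics), and
#' missing tetraploid calls get status `missing`.
#'
#' @inheritParams reference_profile
#' @return A `partitioned_table`: list with `base` (the input table),
#'   `assignments` (data.frame `accession_id, marker_id, allele_A, allele_B,
#'   status`, one row per tetraploid accession x marker) and `status_counts`.
#' @export
partition_table <- function(table, ref_taxon) {
  acc <- table$accessions
  tets <- acc$accession_id[acc$ploidy == 4]
  if (!length(tets)) stop("no tetraploid accessions to partition")
  rp <- reference_profile(table, ref_taxon)
  mids <- table$markers$marker_id
  rows <- vector("list", length(tets) * length(mids))
  k <- 0L
  for (aid in tets) {
    for (mid in mids) {
      k <- k + 1L
      sz <- call_sizes(table, aid, mid)
      if (mid %in% rp$no_reference) {
        rows[[k]] <- data.frame(accession_id = aid, marker_id = mid,
                                allele_A = NA_integer_, allele_B = NA_integer_,
                                status = "no_reference")
      } else if (length(sz) == 0) {
        rows[[k]] <- data.frame(accession_id = aid, marker_id = mid,
                                allele_A = NA_integer_, allele_B = NA_integer_,
                                status = "missing")
      } else if (length(sz) == 1) {
        rows[[k]] <- data.frame(accession_id = aid, marker_id = mid,
                                allele_A = sz, allele_B = sz,
                                status = "single_product")
      } else if (length(sz) == 2) {
        pc <- partition_call(sz, rp$profile[[mid]])
        rows[[k]] <- data.frame(accession_id = aid, marker_id = mid,
                                allele_A = pc$A, allele_B = pc$B,
                                status = pc$status)
      } else {
        warning("tetraploid call with >2 products at ", mid, " for ", aid,
                " treated as missing")
        rows[[k]] <- data.frame(accession_id = aid, marker_id = mid,
                                allele_A = NA_integer_, allele_B = NA_integer_,
                                status = "missing")
      }
    }
  }
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  statuses <- c("assigned", "tied", "single_product", "missing", "no_reference")
  status_counts <- vapply(statuses, function(s)
    sum(assignments$status == s), integer(1))
  structure(list(base = table, ref_taxon = ref_taxon,
                 assignments = assignments, status_counts = status_counts),
            class = "partitioned_table")
}

#' @export
print.partitioned_table <- function(x, ...) {
  cat("partitioned_table anchored on", x$ref_taxon, "\n")
  print(x$status_counts)
  invisible(x)
}

#' Build genome groups
#'
#' Every diploid taxon forms one genome group; every tetraploid taxon forms
#' two (sub-genomes A and B, identical member lists). If `subgroup_labels`
#' (accession_id -> label) is supplied, the labelled diploid accessions are
#' split into one group per label — e.g. splitting one polymorphic species
#' into its sub-taxa turns a 10-group layout into 12 groups.
#'
#' @param table a [genotype_table()].
#' @param partitioned optional `partitioned_table` (required when the table
#'   has tetraploids).
#' @param subgroup_labels optional named character vector mapping accession
#'   ids to sub-group labels.
#' @return data.frame with `group_id`, `taxon`, `subgenome` (`"A"`, `"B"` or
#'   `NA`) and list-column `members`, sorted by `group_id`.
#' @export
build_genome_groups <- function(table, partitioned = NULL,
                                subgroup_labels = NULL) {
  acc <- table$accessions
  if (!is.null(subgroup_labels)) {
    unknown <- setdiff(names(subgroup_labels), acc$accession_id)
    if (length(unknown))
      stop("subgroup label references unknown accession: ",
           paste(unknown, collapse = ", "))
  }
  if (any(acc$ploidy == 4) && is.null(partitioned))
    stop("a partitioned_table is required when tetraploids are present")
  rows <- list()
  for (tx in sort(unique(acc$taxon))) {
    a <- acc[acc$taxon == tx, , drop = FALSE]
    ploidy <- unique(a$ploidy)
    if (length(ploidy) > 1)
      stop("taxon with mixed ploidy: ", tx)
    labels <- if (!is.null(subgroup_labels) &&
                  any(a$accession_id %in% names(subgroup_labels))) {
      if (!all(a$accession_id %in% names(subgroup_labels)))
        stop("subgroup labels must cover every accession of taxon ", tx)
      subgroup_labels[a$accession_id]
    } else rep(NA_character_, nrow(a))
    for (lab in sort(unique(labels), na.last = TRUE)) {
      sel <- if (is.na(lab)) is.na(labels) else !is.na(labels) & labels == lab
      members <- a$accession_id[sel]
      base_id <- if (is.na(lab)) tx else paste0(tx, " (", lab, ")")
      if (ploidy == 2) {
        rows[[length(rows) + 1]] <- list(group_id = base_id, taxon = tx,
                                         subgenome = NA_character_,
                                         members = members)
      } else {
        for (sg in c("A", "B"))
          rows[[length(rows) + 1]] <- list(group_id = paste0(base_id, " (", sg, ")"),
                                           taxon = tx, subgenome = sg,
                                           members = members)
      }
    }
  }
  out <- data.frame(group_id = vapply(rows, `[[`, character(1), "group_id"),
                    taxon = vapply(rows, `[[`, character(1), "taxon"),
                    subgenome = vapply(rows, `[[`, character(1), "subgenome"),
                    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group, per-locus allele frequency spectra
#'
#' For diploid groups, frequencies come from [allele_frequencies()] on the
#' member accessions. For sub-genome groups, each member contributes one gene
#' copy: its assigned A (or B) allele. Entries with status `assigned` or
#' `tied` are used; `single_product` calls are excluded by default (they may
#' be homoeolog homozygosity or allele dropout), as are `missing` and
#' `no_reference` entries.
#'
#' @param table a [genotype_table()].
#' @param groups group table from [build_genome_groups()].
#' @param partitioned `partitioned_table` (required for sub-genome groups).
#' @param copies_per_call copy coding for diploid groups (see
#'   [allele_frequencies()]).
#' @param include_single_product count `single_product` tetraploid calls as a
#'   copy in both sub-genomes.
#' @return named list group_id -> named list marker_id -> `allele_spectrum`.
#' @export
group_spectra <- function(table, groups, partitioned = NULL,
                          copies_per_call = 1,
                          include_single_product = FALSE) {
  mids <- table$markers$marker_id
  out <- vector("list", nrow(groups))
  names(out) <- groups$group_id
  keep_status <- c("assigned", "tied",
                   if (include_single_product) "single_product")
  for (g in seq_len(nrow(groups))) {
    members <- groups$members[[g]]
    sg <- groups$subgenome[g]
    spec <- vector("list", length(mids))
    names(spec) <- mids
    if (is.na(sg)) {
      for (mid in mids)
        spec[[mid]] <- allele_frequencies(table, members, mid, copies_per_call)
    } else {
      if (is.null(partitioned))
        stop("partitioned table required for sub-genome groups")
      asg <- partitioned$assignments
      asg <- asg[asg$accession_id %in% members &
                   asg$status %in% keep_status, , drop = FALSE]
      col <- if (sg == "A") "allele_A" else "allele_B"
      for (mid in mids) {
        copies <- asg[[col]][asg$marker_id == mid]
        spec[[mid]] <- spectrum_from_copies(copies, mid,
                                            groups$group_id[g])
      }
    }
    for (mid in mids) spec[[mid]]$group_id <- groups$group_id[g]
    out[[g]] <- spec
  }
  out
}

#' Write partition assignments to TSV
#'
#' @param partitioned a `partitioned_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partitioned, path) {
  utils::write.table(partitioned$assignments, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
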