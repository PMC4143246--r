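#' Pipeline configuration
#'
#' @param ref_taxon diploid reference-anchor taxon: tetraploid products
#'   nearest this taxon's alleles are scored sub-genome A.
#' @param copies_per_call copy coding for diploid allele frequencies
#'   (see [allele_frequencies()]).
#' @param size_cap marker screening size cap in bp.
#' @param panel_per_taxon accessions per taxon in the marker screening panel.
#' @param boot_individual,boot_group bootstrap replicates for the
#'   accession-level and group-level trees.
#' @param k_axes PCoA axes to retain.
#' @param subgroup_labels optional named vector accession_id -> label used to
#'   split a diploid taxon into sub-groups (see [build_genome_groups()]).
#' @param seed integer seed for the bootstrap resampling.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ref_taxon = "V. trinervia",
                            copies_per_call = 1,
                            size_cap = 500,
                            panel_per_taxon = 2,
                            boot_individual = 1000,
                            boot_group = 400,
                            k_axes = 3,
                            subgroup_labels = NULL,
                            seed = 1) {
  structure(list(ref_taxon = ref_taxon, copies_per_call = copies_per_call,
                 size_cap = size_cap, panel_per_taxon = panel_per_taxon,
                 boot_individual = boot_individual, boot_group = boot_group,
                 k_axes = k_axes, subgroup_labels = subgroup_labels,
                 seed = seed),
            class = "pipeline_config")
}

#' Rank diploid groups by distance to each tetraploid sub-genome
#'
#' For each sub-genome group of the distance matrix, ranks all diploid
#' groups by DA; the donor call is the nearest diploid group, with the
#' margin to the runner-up. An exact tie yields no call (both candidates
#' are listed). Because the reference anchor is itself a donor candidate
#' for sub-genome A, the report also carries, for every sub-genome, the
#' nearest diploid excluding the anchor, so anchor-induced circularity is
#' visible.
#'
#' @param da a `da_matrix` over genome groups.
#' @param groups group table from [build_genome_groups()].
#' @param ref_taxon the anchor taxon (excluded in the `call_no_anchor`
#'   column).
#' @return data.frame of class `donor_report`: one row per sub-genome group
#'   with `group_id`, `subgenome`, `call`, `margin`, `runner_up`,
#'   `call_no_anchor`, `n_loci`, and attribute `ranking` (full ranked list
#'   per sub-genome).
#' @export
donor_call <- function(da, groups, ref_taxon) {
  sub_ids <- groups$group_id[!is.na(groups$subgenome)]
  dip <- groups[is.na(groups$subgenome), , drop = FALSE]
  dip_ids <- dip$group_id
  missing <- setdiff(c(sub_ids, dip_ids), da$labels)
  if (length(missing))
    stop("group(s) absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  ranking <- list()
  rows <- lapply(sub_ids, function(gid) {
    dd <- da$d[gid, dip_ids]
    o <- order(dd, dip_ids)
    ranking[[gid]] <<- data.frame(candidate = dip_ids[o], da = dd[o],
                                  stringsAsFactors = FALSE)
    tie <- sum(dd == min(dd)) > 1
    non_anchor <- dip_ids[dip$taxon != ref_taxon]
    dna <- dd[non_anchor]
    data.frame(group_id = gid,
               subgenome = groups$subgenome[groups$group_id == gid],
               call = if (tie) NA_character_ else dip_ids[o][1],
               da_call = min(dd),
               margin = dd[o][2] - dd[o][1],
               runner_up = dip_ids[o][2],
               call_no_anchor = non_anchor[order(dna, non_anchor)][1],
               n_loci = min(da$r[gid, dip_ids]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ranking") <- ranking
  class(out) <- c("donor_report", class(out))
  out
}

#' Run the full donor-identification pipeline
#'
#' Chains the stages: marker screening on a small per-taxon panel,
#' restriction to the markers amplifying one product in diploids and two in
#' tetraploids, sub-genome partitioning anchored on the reference taxon,
#' genome-group construction, diversity summaries, DA distance matrices
#' (accession- and group-level), neighbor-joining trees with locus-bootstrap
#' support, PCoA and the donor-call report. All artifacts are written under
#' `out_dir` as TSV/Newick plus a plain-text log; the run is a deterministic
#' function of the inputs and the seed. With no tetraploid accessions the
#' pipeline stops after the diversity, tree and PCoA stages with a notice.
#'
#' @param table a [genotype_table()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param verbose log to the console as well.
#' @return list with `selection`, `selected_markers`, `partitioned`,
#'   `groups`, `spectra`, `group_summary`, `locus_summary`, `group_da`,
#'   `individual_da`, `group_tree`, `individual_tree`, `pcoa`, `donor_report`
#'   (the tetraploid-specific elements are `NULL` when absent).
#' @export
run_pipeline <- function(table, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  logf <- function(...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    paste0(...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  has_tets <- any(table$accessions$ploidy == 4)

  logf("screening ", nrow(table$markers), " markers on a panel of ",
       config$panel_per_taxon, " accession(s) per taxon")
  selection <- stage("marker_screen", {
    panel <- screening_panel(table, config$panel_per_taxon)
    selection_report(panel, config$size_cap)
  })
  selected <- selection$pass
  logf("category counts: ",
       paste(names(selection$counts), selection$counts, sep = "=",
             collapse = ", "))
  if (!length(selected))
    stop("pipeline stage 'marker_screen' failed: no marker passed the screen")
  logf(length(selected), " markers selected")
  table <- subset_accessions(table, table$accessions$accession_id, selected)

  partitioned <- NULL
  if (has_tets) {
    partitioned <- stage("partition", partition_table(table, config$ref_taxon))
    logf("partition status counts: ",
         paste(names(partitioned$status_counts), partitioned$status_counts,
               sep = "=", collapse = ", "))
  } else {
    logf("no tetraploid accessions: partition and donor stages skipped")
  }

  groups <- stage("genome_groups",
                  build_genome_groups(table, partitioned,
                                      config$subgroup_labels))
  logf(nrow(groups), " genome groups")
  spectra <- stage("group_spectra",
                   group_spectra(table, groups, partitioned,
                                 config$copies_per_call))
  gsum <- stage("group_summary", group_summary(spectra, table, groups))
  lsum <- stage("locus_summary", locus_summary(spectra))

  group_da <- stage("group_da", pairwise_da(spectra))
  ind_spec <- stage("individual_spectra", individual_spectra(table))
  ind_da <- stage("individual_da", pairwise_da(ind_spec))
  within <- within_group_da(ind_da,
                            stats::setNames(groups$members, groups$group_id))

  logf("group tree: ", config$boot_group, " bootstrap replicates")
  gboot <- stage("group_tree",
                 bootstrap_support(spectra, config$boot_group, config$seed))
  logf("individual tree: ", config$boot_individual, " bootstrap replicates")
  iboot <- stage("individual_tree",
                 bootstrap_support(ind_spec, config$boot_individual,
                                   config$seed + 1L))
  ord <- stage("pcoa", pcoa(ind_da, k = config$k_axes))
  logf("PCoA percent variance (first ", config$k_axes, " axes): ",
       paste(sprintf("%.1f", utils::head(ord$percent_variance,
                                         config$k_axes)), collapse = ", "))

  report <- NULL
  if (has_tets) {
    report <- stage("donor_call", donor_call(group_da, groups,
                                             config$ref_taxon))
    for (i in seq_len(nrow(report)))
      logf("donor call for ", report$group_id[i], ": ",
           ifelse(is.na(report$call[i]), "tie (no call)", report$call[i]),
           " (margin ", sprintf("%.3f", report$margin[i]), ")")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    utils::write.table(data.frame(category = names(selection$counts),
                                  n = selection$counts),
                       p("marker_screen.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(selected, p("selected_markers.txt"))
    if (has_tets) write_partition(partitioned, p("partition.tsv"))
    gdef <- data.frame(group_id = groups$group_id, taxon = groups$taxon,
                       subgenome = groups$subgenome,
                       members = vapply(groups$members, paste,
                                        character(1), collapse = ","))
    utils::write.table(gdef, p("genome_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gsum_out <- gsum
    gsum_out$within_group_da <- c(within[gsum$group_id[-nrow(gsum)]], NA)
    utils::write.table(gsum_out, p("group_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lsum, p("locus_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_da_matrix(group_da, p("group_da.tsv"))
    write_da_matrix(ind_da, p("individual_da.tsv"))
    write_newick(gboot$tree, p("group_tree.nwk"))
    write_newick(iboot$tree, p("individual_tree.nwk"))
    write_pcoa(ord, p("pcoa.tsv"))
    if (has_tets)
      utils::write.table(as.data.frame(report), p("donor_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    logf("artifacts written to ", out_dir)
    writeLines(log_lines, p("run.log"))
  }

  invisible(list(selection = selection, selected_markers = selected,
                 partitioned = partitioned, groups = groups,
                 spectra = spectra, group_summary = gsum,
                 locus_summary = lsum, group_da = group_da,
                 individual_da = ind_da, within_group_da = within,
                 group_tree = gboot, individual_tree = iboot, pcoa = ord,
                 donor_report = report, log = log_lines))
}
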