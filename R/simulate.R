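#' Default taxon layout for the simulator
#'
#' Eight taxa of a diploid species complex plus a wild and a cultivated
#' variety of one amphidiploid, with the accession counts of the study
#' design this generator emulates (268 accessions in total). The two donor
#' taxa of the amphidiploid are the reference-anchor species (donor of
#' sub-genome A) and a second diploid (donor of sub-genome B). Each taxon
#' draws its ancestral allele pool from a window on a shared size ladder;
#' windows overlap within the two species groups but the two donor windows
#' are disjoint by default, so sub-genome assignment has a clean regime.
#'
#' @return data.frame with `taxon`, `n_accessions`, `ploidy`, `pool_offset`
#'   (window start on the ladder, in repeat units).
#' @export
default_taxa <- function() {
  data.frame(
    taxon = c("V. trinervia", "V. radiata var. sublobata",
              "V. hirtella", "V. exilis", "V. minima", "V. tenuicaulis",
              "V. reflexo-pilosa var. reflexo-pilosa",
              "V. reflexo-pilosa var. glabra"),
    n_accessions = c(46L, 13L, 47L, 13L, 49L, 42L, 51L, 7L),
    ploidy = c(2L, 2L, 2L, 2L, 2L, 2L, 4L, 4L),
    pool_offset = c(0L, 2L, 10L, 12L, 14L, 16L, NA, NA),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the study conditions for [generate_dataset()]: locus set, taxon
#' layout, selfing rate, stepwise-mutation rates, generation counts and the
#' amphidiploid origin. Defaults reproduce the shape of the emulated study:
#' 38 multi-allelic loci, 8 taxa (268 accessions), highly selfing diploids,
#' one monophyletic amphidiploid whose two homoeologous products per locus
#' derive from two diploid donor pools, and a faster-mutating sub-genome B.
#'
#' @param n_loci number of SSR loci.
#' @param taxa taxon table as in [default_taxa()].
#' @param selfing_rate probability an offspring is produced by selfing.
#' @param mutation_rate per-allele, per-generation stepwise mutation rate in
#'   the diploids (steps of one repeat unit, reflecting at the pool bounds).
#' @param n_generations diploid generations simulated after founding from
#'   the ancestral pool.
#' @param pool_size alleles per taxon ancestral pool.
#' @param pool_concentration symmetric Dirichlet concentration of the
#'   ancestral pool frequencies; values below 1 give skewed, realistic SSR
#'   spectra with some near-monomorphic loci.
#' @param pop_size census size of each simulated population; accessions are
#'   sampled from it, so small germplasm panels do not imply tiny
#'   populations.
#' @param donor_A,donor_B diploid donor taxa of the amphidiploid sub-genomes;
#'   `donor_A` is also the pipeline's reference anchor.
#' @param n_founders number of independent hybrid origins (1 = monophyletic).
#' @param post_origin_generations tetraploid generations after the origin.
#' @param mutation_rate_A,mutation_rate_B per-sub-genome stepwise mutation
#'   rates in the tetraploid; B defaults to twice A, emulating a faster
#'   evolving sub-genome B (the roughly twofold diversity contrast seen in
#'   such amphidiploids).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 38,
                              taxa = default_taxa(),
                              selfing_rate = 0.98,
                              mutation_rate = 1e-3,
                              n_generations = 20,
                              pool_size = 8,
                              pool_concentration = 0.2,
                              pop_size = 100,
                              donor_A = "V. trinervia",
                              donor_B = "V. hirtella",
                              n_founders = 1,
                              post_origin_generations = 30,
                              mutation_rate_A = 1e-3,
                              mutation_rate_B = 2e-3,
                              seed = 1) {
  bad <- character(0)
  if (!donor_A %in% taxa$taxon[taxa$ploidy == 2]) bad <- c(bad, "donor_A")
  if (!donor_B %in% taxa$taxon[taxa$ploidy == 2]) bad <- c(bad, "donor_B")
  if (donor_A == donor_B) bad <- c(bad, "donor_A == donor_B")
  if (selfing_rate < 0 || selfing_rate > 1) bad <- c(bad, "selfing_rate")
  if (n_loci < 1) bad <- c(bad, "n_loci")
  if (n_founders < 1) bad <- c(bad, "n_founders")
  if (length(bad))
    stop("inconsistent simulation config: ", paste(bad, collapse = ", "))
  structure(list(n_loci = n_loci, taxa = taxa, selfing_rate = selfing_rate,
                 mutation_rate = mutation_rate,
                 n_generations = n_generations, pool_size = pool_size,
                 pool_concentration = pool_concentration,
                 pop_size = pop_size,
                 donor_A = donor_A, donor_B = donor_B,
                 n_founders = n_founders,
                 post_origin_generations = post_origin_generations,
                 mutation_rate_A = mutation_rate_A,
                 mutation_rate_B = mutation_rate_B, seed = seed),
            class = "simulation_config")
}

# per-locus marker definitions: motif unit length and base size, plus the
# shared allele ladder each taxon windows into
make_locus_specs <- function(n_loci, pool_size) {
  unit <- sample(c(2L, 3L, 4L), n_loci, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  base <- sample(100:280, n_loci, replace = TRUE)
  data.frame(marker_id = sprintf("SIM%04d", seq_len(n_loci)),
             unit = unit, base = base, stringsAsFactors = FALSE)
}

#' Simulate one selfing diploid population
#'
#' Founds `n` individuals by drawing genotypes from a Dirichlet(1)-weighted
#' ancestral allele pool, then runs `n_generations` of Wright–Fisher
#' reproduction with selfing probability `selfing_rate` and stepwise
#' mutation (one repeat unit up or down, reflecting at the pool bounds).
#' High selfing drives observed heterozygosity toward its
#' `(1-s)/(2-s)`-scale residual.
#'
#' @param loci locus-spec data.frame (`marker_id`, `unit`, `base`).
#' @param n census population size.
#' @param pool_offset window start of this taxon's ancestral pool on the
#'   allele ladder, in repeat units.
#' @param pool_size number of pool alleles.
#' @param pool_concentration Dirichlet concentration of pool frequencies.
#' @param selfing_rate,mutation_rate,n_generations see [simulation_config()].
#' @return list with `a1`, `a2` (n x n_loci integer matrices of allele
#'   sizes) and `pools` (list of per-locus pool size vectors).
#' @export
simulate_diploid_population <- function(loci, n, pool_offset, pool_size,
                                        selfing_rate, mutation_rate,
                                        n_generations,
                                        pool_concentration = 0.2) {
  if (pool_size < 1) stop("empty ancestral pool")
  L <- nrow(loci)
  pools <- lapply(seq_len(L), function(l)
    loci$base[l] + loci$unit[l] * (pool_offset + seq_len(pool_size) - 1L))
  a1 <- matrix(0L, n, L)
  a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    w <- stats::rgamma(pool_size, pool_concentration)  # Dirichlet pool freqs
    while (all(w == 0)) w <- stats::rgamma(pool_size, pool_concentration)
    w <- w / sum(w)
    a1[, l] <- sample(pools[[l]], n, replace = TRUE, prob = w)
    a2[, l] <- sample(pools[[l]], n, replace = TRUE, prob = w)
  }
  lo <- vapply(pools, min, numeric(1))
  hi <- vapply(pools, max, numeric(1))
  step <- loci$unit
  mutate <- function(mat, rate) {
    hit <- matrix(stats::runif(length(mat)) < rate, nrow(mat))
    if (any(hit)) {
      dir <- matrix(sample(c(-1L, 1L), length(mat), replace = TRUE), nrow(mat))
      stepm <- matrix(rep(step, each = nrow(mat)), nrow(mat))
      cand <- mat + dir * stepm
      lom <- matrix(rep(lo, each = nrow(mat)), nrow(mat))
      him <- matrix(rep(hi, each = nrow(mat)), nrow(mat))
      cand <- ifelse(cand > him, him - (cand - him), cand)  # reflect
      cand <- ifelse(cand < lom, lom + (lom - cand), cand)
      mat[hit] <- cand[hit]
    }
    mat
  }
  for (g in seq_len(n_generations)) {
    p1 <- sample.int(n, n, replace = TRUE)
    selfed <- stats::runif(n) < selfing_rate
    p2 <- ifelse(selfed, p1, sample.int(n, n, replace = TRUE))
    pick1 <- matrix(stats::runif(n * L) < 0.5, n, L)
    pick2 <- matrix(stats::runif(n * L) < 0.5, n, L)
    na1 <- ifelse(pick1, a1[p1, , drop = FALSE], a2[p1, , drop = FALSE])
    na2 <- ifelse(pick2, a1[p2, , drop = FALSE], a2[p2, , drop = FALSE])
    a1 <- mutate(na1, mutation_rate)
    a2 <- mutate(na2, mutation_rate)
  }
  list(a1 = a1, a2 = a2, pools = pools)
}

#' Simulate the amphidiploid population
#'
#' Draws `n_founders` hybrid origins: each founder takes one gamete (one
#' allele per locus) from a random individual of the donor-A population and
#' one from donor-B, fixing the sub-genome identity of every allele. The
#' tetraploid population then drifts for `post_origin_generations` with
#' per-sub-genome stepwise mutation. Because the species is highly selfing,
#' each sub-genome is modelled as effectively homozygous within an
#' accession, so one allele per sub-genome per accession is tracked.
#'
#' @param donor_A_pop,donor_B_pop outputs of
#'   [simulate_diploid_population()] for the two donors.
#' @param loci locus-spec data.frame.
#' @param n number of tetraploid accessions.
#' @param n_founders number of independent origins.
#' @param generations post-origin generations.
#' @param mutation_rate_A,mutation_rate_B per-sub-genome mutation rates.
#' @return list with `A`, `B` (n x n_loci matrices of allele sizes, the
#'   ground truth of every product's sub-genome).
#' @export
simulate_amphidiploid <- function(donor_A_pop, donor_B_pop, loci, n,
                                  n_founders, generations,
                                  mutation_rate_A, mutation_rate_B) {
  L <- nrow(loci)
  nA <- nrow(donor_A_pop$a1)
  nB <- nrow(donor_B_pop$a1)
  founders_A <- matrix(0L, n_founders, L)
  founders_B <- matrix(0L, n_founders, L)
  for (f in seq_len(n_founders)) {
    ia <- sample.int(nA, 1); ib <- sample.int(nB, 1)
    pa <- stats::runif(L) < 0.5
    pb <- stats::runif(L) < 0.5
    founders_A[f, ] <- ifelse(pa, donor_A_pop$a1[ia, ], donor_A_pop$a2[ia, ])
    founders_B[f, ] <- ifelse(pb, donor_B_pop$a1[ib, ], donor_B_pop$a2[ib, ])
  }
  origin <- sample.int(n_founders, n, replace = TRUE)
  A <- founders_A[origin, , drop = FALSE]
  B <- founders_B[origin, , drop = FALSE]
  step <- loci$unit
  drift_mutate <- function(mat, rate, pools) {
    nr <- nrow(mat)
    lo <- vapply(pools, min, numeric(1))
    hi <- vapply(pools, max, numeric(1))
    for (g in seq_len(generations)) {
      mat <- mat[sample.int(nr, nr, replace = TRUE), , drop = FALSE]
      hit <- matrix(stats::runif(length(mat)) < rate, nr)
      if (any(hit)) {
        dir <- matrix(sample(c(-1L, 1L), length(mat), replace = TRUE), nr)
        stepm <- matrix(rep(step, each = nr), nr)
        cand <- mat + dir * stepm
        lom <- matrix(rep(lo, each = nr), nr)
        him <- matrix(rep(hi, each = nr), nr)
        cand <- ifelse(cand > him, him - (cand - him), cand)
        cand <- ifelse(cand < lom, lom + (lom - cand), cand)
        mat[hit] <- cand[hit]
      }
    }
    mat
  }
  # mutation bounds follow each donor's pool (one reflecting step of slack)
  widen <- function(pools, u) lapply(seq_along(pools), function(l)
    c(min(pools[[l]]) - u[l], pools[[l]], max(pools[[l]]) + u[l]))
  A <- drift_mutate(A, mutation_rate_A, widen(donor_A_pop$pools, step))
  B <- drift_mutate(B, mutation_rate_B, widen(donor_B_pop$pools, step))
  list(A = A, B = B)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Runs the diploid and amphidiploid simulators for every taxon of the
#' configuration and assembles a [genotype_table()] (diploids carry both
#' alleles of their genotype; tetraploids carry their two homoeologous
#' products) plus a truth record giving the sub-genome of every tetraploid
#' allele. The same seed yields an identical dataset.
#'
#' @param config a [simulation_config()].
#' @return list of class `donor_sim` with `table` (genotype_table), `truth`
#'   (data.frame `accession_id, marker_id, allele_A, allele_B`), `loci`
#'   (locus specs), and `config`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  taxa <- config$taxa
  loci <- make_locus_specs(config$n_loci, config$pool_size)
  # short unique code per taxon: letters of the last name token
  codes <- make.unique(vapply(strsplit(taxa$taxon, " +"), function(w)
    gsub("[^A-Za-z]", "", w[length(w)]), character(1)), sep = "")
  dip <- list()
  keep <- list()   # which population members become accessions
  for (i in which(taxa$ploidy == 2)) {
    tx <- taxa$taxon[i]
    dip[[tx]] <- simulate_diploid_population(
      loci, config$pop_size, taxa$pool_offset[i], config$pool_size,
      config$selfing_rate, config$mutation_rate, config$n_generations,
      config$pool_concentration)
    keep[[tx]] <- sample.int(config$pop_size,
                             min(taxa$n_accessions[i], config$pop_size))
  }
  tet_idx <- which(taxa$ploidy == 4)
  n_tet <- sum(taxa$n_accessions[tet_idx])
  tet <- NULL
  if (n_tet > 0)
    tet <- simulate_amphidiploid(dip[[config$donor_A]], dip[[config$donor_B]],
                                 loci, n_tet, config$n_founders,
                                 config$post_origin_generations,
                                 config$mutation_rate_A,
                                 config$mutation_rate_B)
  acc_rows <- list()
  call_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(taxa))) {
    tx <- taxa$taxon[i]
    n <- taxa$n_accessions[i]
    ids <- sprintf("%s_%03d", codes[i], seq_len(n))
    acc_rows[[i]] <- data.frame(accession_id = ids, taxon = tx,
                                ploidy = taxa$ploidy[i],
                                stringsAsFactors = FALSE)
    if (taxa$ploidy[i] == 2) {
      a1 <- dip[[tx]]$a1[keep[[tx]], , drop = FALSE]
      a2 <- dip[[tx]]$a2[keep[[tx]], , drop = FALSE]
      call_rows[[i]] <- data.frame(
        accession_id = rep(ids, times = 2 * nrow(loci)),
        marker_id = rep(rep(loci$marker_id, each = n), 2),
        size = c(as.vector(a1), as.vector(a2)),
        stringsAsFactors = FALSE)
    } else {
      done <- sum(taxa$n_accessions[tet_idx][seq_len(match(i, tet_idx) - 1)])
      rowsel <- done + seq_len(n)
      A <- tet$A[rowsel, , drop = FALSE]
      B <- tet$B[rowsel, , drop = FALSE]
      call_rows[[i]] <- data.frame(
        accession_id = rep(ids, times = 2 * nrow(loci)),
        marker_id = rep(rep(loci$marker_id, each = n), 2),
        size = c(as.vector(A), as.vector(B)),
        stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        accession_id = rep(ids, times = nrow(loci)),
        marker_id = rep(loci$marker_id, each = n),
        allele_A = as.vector(A), allele_B = as.vector(B),
        stringsAsFactors = FALSE)
    }
  }
  table <- genotype_table(do.call(rbind, acc_rows),
                          data.frame(marker_id = loci$marker_id,
                                     stringsAsFactors = FALSE),
                          do.call(rbind, call_rows))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  structure(list(table = table, truth = truth, loci = loci, config = config),
            class = "donor_sim")
}

#' @export
print.donor_sim <- function(x, ...) {
  cat("donor_sim (seed", x$config$seed, "):\n")
  print(x$table)
  invisible(x)
}

#' Score partition assignments against simulator truth
#'
#' @param partitioned a `partitioned_table` on a simulated dataset.
#' @param truth the `truth` element of a `donor_sim`.
#' @return list with `accuracy` (fraction of assigned/tied entries whose
#'   (A, B) pair matches the truth; entries whose two products are identical
#'   in truth are excluded as undecidable) and `n_scored`.
#' @export
partition_accuracy <- function(partitioned, truth) {
  asg <- partitioned$assignments
  asg <- asg[asg$status %in% c("assigned", "tied"), , drop = FALSE]
  key <- paste(asg$accession_id, asg$marker_id, sep = "\r")
  tkey <- paste(truth$accession_id, truth$marker_id, sep = "\r")
  m <- match(key, tkey)
  ok <- !is.na(m) & truth$allele_A[m] != truth$allele_B[m]
  asg <- asg[ok, , drop = FALSE]
  m <- m[ok]
  correct <- asg$allele_A == truth$allele_A[m] &
    asg$allele_B == truth$allele_B[m]
  list(accuracy = if (nrow(asg)) mean(correct) else NA_real_,
       n_scored = nrow(asg))
}
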