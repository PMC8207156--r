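#' Simulate a SNP dataset under a divergence scenario
#'
#' Coalescent simulation of unlinked biallelic SNPs for the three-lineage
#' divergence model. Each locus is an independent genealogy of all sampled
#' gene copies under the scenario's population tree (exponential-rate
#' pairwise coalescence within demes; merges, size changes and admixture as
#' the scenario dictates); exactly one mutation is placed on a branch
#' chosen with probability proportional to its length, so every locus is a
#' single SNP. Loci whose pooled minor allele frequency falls below
#' `maf_min` are redrawn, emulating SNP-panel ascertainment. Gene copies
#' are paired within demes into diploid individuals.
#'
#' @param scenario_id scenario 1-4 (see [default_priors()])
#' @param params named vector/list with `N1, N2, N3, Na, Nc, t1, t2` and,
#'   for scenarios 3-4, `ra`
#' @param sample_sizes diploid individuals per lineage, length 3
#'   (Dson, Dvov-S, Dvov-N)
#' @param n_loci number of SNP loci to emit
#' @param maf_min pooled minor-allele-frequency threshold (default 0.05;
#'   0 disables the ascertainment filter)
#' @param max_tries redraw bound per locus (default 1000)
#' @return a [genotype_matrix()] with populations `pop1`-`pop3` mapped to
#'   lineages `Dson`, `Dvov-S`, `Dvov-N` and the two species
#' @export
simulate_snp_dataset <- function(scenario_id, params, sample_sizes,
                                 n_loci, maf_min = 0.05, max_tries = 1000) {
  stopifnot(scenario_id %in% 1:4, length(sample_sizes) == 3,
            all(sample_sizes >= 1), n_loci >= 1)
  p <- as.list(params)
  need <- c("N1", "N2", "N3", "Na", "Nc", "t1", "t2")
  if (!all(need %in% names(p)))
    stop("params must name ", paste(need, collapse = ", "))
  if (scenario_id %in% 3:4 && (is.null(p$ra) || is.na(p$ra)))
    stop("scenarios 3-4 require the admixture proportion ra")
  if (p$t2 < p$t1) stop("t2 must be >= t1")
  ev <- scenario_events(scenario_id, p)
  hap <- .sim_snp_cpp(
    deme_sizes = c(p$N1, p$N2, p$N3),
    samples_per_deme = as.integer(2 * sample_sizes),
    event_time = ev$time, event_type = ev$type, event_from = ev$from,
    event_to = ev$to, event_to2 = ev$to2, event_prob = ev$prob,
    event_newsize = ev$newsize,
    n_loci = as.integer(n_loci), maf_min = maf_min,
    max_tries = as.integer(max_tries))
  odd <- seq(1, nrow(hap), by = 2)
  geno <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  pop <- rep(c("pop1", "pop2", "pop3"), times = sample_sizes)
  meta <- data.frame(
    population = c("pop1", "pop2", "pop3"),
    lineage = c("Dson", "Dvov-S", "Dvov-N"),
    species = c("sonorense", "vovidesii", "vovidesii"),
    stringsAsFactors = FALSE)
  genotype_matrix(geno, pop, meta)
}

#' Names of the ABC summary-statistic vector
#' @return character vector of length 9
#' @export
abc_stat_names <- function() {
  c("He_1", "He_2", "He_3", "Fst_12", "Fst_13", "Fst_23",
    "Nei_12", "Nei_13", "Nei_23")
}

#' Lineage-level summary statistics for ABC
#'
#' Nine statistics: mean expected heterozygosity of each of the three
#' lineages, the three pairwise lineage Fst values (ratio-of-means Wright
#' estimator over loci), and the three pairwise Nei standard distances
#' (infinities replaced by [NEI_D_SENTINEL]). Lineages are taken in the
#' order they appear in `pop_meta`.
#'
#' @param g a [genotype_matrix()] with three lineages
#' @return named numeric vector, see [abc_stat_names()]
#' @export
lineage_summary_stats <- function(g) {
  lin_levels <- unique(g$pop_meta$lineage)
  if (length(lin_levels) != 3) stop("expected exactly 3 lineages")
  lin <- factor(lineage_of_individuals(g), levels = lin_levels)
  freq <- t(vapply(lin_levels, function(lv) {
    colMeans(g$geno[lin == lv, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(g$geno))))

  he <- rowMeans(2 * freq * (1 - freq), na.rm = TRUE)

  pair_fst <- function(i, j) {
    hs <- colMeans(2 * freq[c(i, j), ] * (1 - freq[c(i, j), ]), na.rm = TRUE)
    pbar <- colMeans(freq[c(i, j), ], na.rm = TRUE)
    ht <- 2 * pbar * (1 - pbar)
    mht <- mean(ht, na.rm = TRUE)
    if (mht <= 0) return(0)
    max(0, min(1, (mht - mean(hs, na.rm = TRUE)) / mht))
  }
  fst <- c(pair_fst(1, 2), pair_fst(1, 3), pair_fst(2, 3))

  D <- nei_distance(freq)
  nei <- c(D[1, 2], D[1, 3], D[2, 3])

  setNames(c(he, fst, nei), abc_stat_names())
}

#' Build an ABC reference table of simulated summary statistics
#'
#' Simulations are allocated equally across the candidate scenarios
#' (remainder to the lower scenario ids). Each row records the scenario id,
#' the accepted prior draw and the nine summary statistics. Reproducible
#' from the R random seed.
#'
#' @param n_sims total number of simulations (>= number of scenarios)
#' @param scenarios candidate scenario ids (default 1:4)
#' @param sample_sizes diploid individuals per lineage (default
#'   c(10, 5, 25): a 40-sample design with five individuals per population
#'   aggregated into the three lineages)
#' @param n_loci SNP loci per simulated dataset (default 200)
#' @param maf_min ascertainment MAF threshold (default 0.05)
#' @param priors prior set (default [default_priors()])
#' @param progress print a progress message every 1000 rows
#' @return data frame with columns `scenario`, the eight parameters and
#'   the nine statistics
#' @export
build_reference_table <- function(n_sims, scenarios = 1:4,
                                  sample_sizes = c(10, 5, 25),
                                  n_loci = 200, maf_min = 0.05,
                                  priors = default_priors(),
                                  progress = FALSE) {
  stopifnot(n_sims >= length(scenarios))
  alloc <- rep(floor(n_sims / length(scenarios)), length(scenarios))
  rem <- n_sims - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  scen_col <- rep(scenarios, times = alloc)

  draws <- do.call(rbind, lapply(seq_along(scenarios), function(i)
    draw_priors(priors, scenarios[i], alloc[i])))
  stats <- matrix(NA_real_, nrow = n_sims, ncol = 9,
                  dimnames = list(NULL, abc_stat_names()))
  for (r in seq_len(n_sims)) {
    g <- simulate_snp_dataset(scen_col[r], draws[r, ], sample_sizes,
                              n_loci, maf_min)
    stats[r, ] <- lineage_summary_stats(g)
    if (progress && r %% 1000 == 0)
      message("reference table: ", r, " / ", n_sims)
  }
  cbind(data.frame(scenario = scen_col), draws, as.data.frame(stats))
}
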