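#' Configuration for the synthetic gradient dataset
#'
#' Defaults emulate the study design the package targets: 8 populations
#' (after merging two small neighbouring ones) in three lineages
#' (Dson = 2 pops, Dvov-S = 1, Dvov-N = 5), 89 individuals with per
#' -population sample depths mirroring the field design, 809 neutral +
#' 62 outlier loci (871 total), 5% missing data, latitudes spanning
#' 27-29.5 degrees N, and scenario-2 divergence at the published-scale
#' point values.
#'
#' @param n_neutral_loci,n_outlier_loci locus counts (defaults 809, 62)
#' @param pops_per_lineage named integer vector over
#'   `Dson`, `Dvov-S`, `Dvov-N` (default 2, 1, 5)
#' @param diploids_per_pop diploid sample size per population (default
#'   `c(16, 16, 5, 16, 7, 8, 10, 11)`)
#' @param scenario_id divergence scenario for the neutral loci (default 2)
#' @param scenario_params named parameter vector (default
#'   [default_scenario2_params()])
#' @param pop_split_frac within-lineage population split time as a
#'   fraction of `t1` (default 0.1, a shallow split)
#' @param outlier_effect logistic allele-frequency shift per unit of the
#'   standardized seasonality covariate (default 3)
#' @param pop_noise_sd per-population logit noise on outlier loci
#'   (default 0.2)
#' @param missing_rate MCAR missingness fraction (default 0.05)
#' @param maf_min pooled MAF threshold enforced on emitted loci
#'   (default 0.05)
#' @param lat_range latitude span of the gradient (default c(27, 29.5))
#' @param lon_center longitude around which populations scatter
#' @param seasonality_slope gradient slope of the seasonality covariate
#'   per degree latitude, in covariate SD units (default 1)
#' @param seasonality_noise_sd noise added to the per-population
#'   seasonality covariate (default 0.3)
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(n_neutral_loci = 809, n_outlier_loci = 62,
                             pops_per_lineage = c(Dson = 2, "Dvov-S" = 1,
                                                  "Dvov-N" = 5),
                             diploids_per_pop = c(16, 16, 5, 16, 7, 8, 10, 11),
                             scenario_id = 2,
                             scenario_params = default_scenario2_params(),
                             pop_split_frac = 0.1,
                             outlier_effect = 3,
                             pop_noise_sd = 0.2,
                             missing_rate = 0.05,
                             maf_min = 0.05,
                             lat_range = c(27, 29.5),
                             lon_center = -109,
                             seasonality_slope = 1,
                             seasonality_noise_sd = 0.3) {
  n_pops <- sum(pops_per_lineage)
  stopifnot(length(diploids_per_pop) == n_pops,
            all(diploids_per_pop >= 2),
            missing_rate >= 0, missing_rate < 1,
            pop_split_frac > 0, pop_split_frac < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# coalescent simulation of neutral loci for populations nested in
# lineages: populations of a lineage merge into the lineage's head deme at
# a shallow time pop_split_frac * t1, then the three lineage demes follow
# the configured divergence scenario.
simulate_nested_neutral <- function(cfg, n_loci) {
  p <- as.list(cfg$scenario_params)
  ppl <- cfg$pops_per_lineage
  n_pops <- sum(ppl)
  lin_of_pop <- rep(1:3, times = ppl)
  lin_sizes <- c(p$N1, p$N2, p$N3)
  sizes <- lin_sizes[lin_of_pop]
  heads <- c(which(lin_of_pop == 1)[1], which(lin_of_pop == 2)[1],
             which(lin_of_pop == 3)[1]) - 1L  # 0-based deme ids
  t_pop <- cfg$pop_split_frac * p$t1

  ev <- data.frame(time = numeric(0), type = integer(0), from = integer(0),
                   to = integer(0), to2 = integer(0), prob = numeric(0),
                   newsize = numeric(0))
  add <- function(time, type, from, to = 0L, to2 = 0L, prob = 1,
                  newsize = 0) {
    ev <<- rbind(ev, data.frame(time, type, from, to, to2, prob, newsize))
  }
  for (d in seq_len(n_pops) - 1L) {
    h <- heads[lin_of_pop[d + 1]]
    if (d != h) add(t_pop, 0L, d, to = h)
  }
  sc <- cfg$scenario_id
  if (sc %in% 1:2) {
    add(p$t1, 0L, heads[2], to = heads[3])
  } else {
    add(p$t1, 0L, heads[2], to = heads[1], to2 = heads[3], prob = p$ra)
  }
  add(p$t1, 1L, heads[1], newsize = p$Na)
  add(p$t1, 1L, heads[3], newsize = p$Nc)
  if (sc %in% c(1, 3)) {
    add(p$t2, 0L, heads[3], to = heads[1])
  } else {
    add(p$t2, 0L, heads[1], to = heads[3])
  }
  ev <- ev[order(ev$time), , drop = FALSE]

  hap <- .sim_snp_cpp(
    deme_sizes = sizes,
    samples_per_deme = as.integer(2 * cfg$diploids_per_pop),
    event_time = ev$time, event_type = ev$type, event_from = ev$from,
    event_to = ev$to, event_to2 = ev$to2, event_prob = ev$prob,
    event_newsize = ev$newsize,
    n_loci = as.integer(n_loci), maf_min = cfg$maf_min, max_tries = 1000L)
  odd <- seq(1, nrow(hap), by = 2)
  hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
}

# environment-coupled outlier loci: per-population allele frequencies are
# logit-shifted along the seasonality covariate, genotypes drawn binomially
simulate_outlier_loci <- function(cfg, n_loci, z_pop) {
  n_pops <- length(z_pop)
  n_ind <- sum(cfg$diploids_per_pop)
  pop_of_ind <- rep(seq_len(n_pops), times = cfg$diploids_per_pop)
  out <- matrix(NA_integer_, n_ind, n_loci)
  l <- 1
  tries <- 0
  while (l <= n_loci) {
    tries <- tries + 1
    if (tries > 50 * n_loci)
      stop("MAF filtering cannot be satisfied for outlier loci")
    p0 <- runif(1, 0.2, 0.8)
    logit_p <- log(p0 / (1 - p0)) + cfg$outlier_effect * z_pop +
      rnorm(n_pops, 0, cfg$pop_noise_sd)
    p_pop <- 1 / (1 + exp(-logit_p))
    geno <- rbinom(n_ind, 2, p_pop[pop_of_ind])
    pbar <- mean(geno) / 2
    if (min(pbar, 1 - pbar) < cfg$maf_min) next
    out[, l] <- geno
    l <- l + 1
  }
  out
}

#' Generate a synthetic gradient dataset
#'
#' Produces a full synthetic analogue of a ddRAD-seq gradient study:
#' neutral loci simulated under the configured coalescent divergence
#' scenario with populations nested in lineages, environment-coupled
#' outlier loci (allele-frequency logits shifted along a latitude-driven
#' seasonality covariate), MCAR missingness, per-population coordinates
#' and an environmental table, plus ground-truth locus labels.
#'
#' @param cfg a [synthetic_config()]
#' @return list: `genotypes` (a [genotype_matrix()]), `coords`
#'   (population, lat, lon), `env` (population environmental table with
#'   `bio4` and two noise variables), `truth` (locus types, covariate,
#'   generative parameters)
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ppl <- cfg$pops_per_lineage
  n_pops <- sum(ppl)
  pops <- paste0("pop", seq_len(n_pops))
  lin_of_pop <- rep(names(ppl), times = ppl)
  species_of_pop <- ifelse(lin_of_pop == "Dson", "sonorense", "vovidesii")

  lat <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = n_pops)
  lon <- cfg$lon_center + runif(n_pops, -0.4, 0.4)
  seas_raw <- cfg$seasonality_slope * (lat - mean(lat)) +
    rnorm(n_pops, 0, cfg$seasonality_noise_sd)
  z_pop <- as.numeric(scale(seas_raw))

  neu <- simulate_nested_neutral(cfg, cfg$n_neutral_loci)
  outl <- simulate_outlier_loci(cfg, cfg$n_outlier_loci, z_pop)
  geno <- cbind(neu, outl)
  colnames(geno) <- sprintf("L%04d", seq_len(ncol(geno)))
  locus_type <- rep(c("neutral", "outlier"),
                    c(cfg$n_neutral_loci, cfg$n_outlier_loci))

  if (cfg$missing_rate > 0) {
    mask <- runif(length(geno)) < cfg$missing_rate
    geno[mask] <- NA_integer_
  }

  pop_of_ind <- rep(pops, times = cfg$diploids_per_pop)
  meta <- data.frame(population = pops, lineage = lin_of_pop,
                     species = species_of_pop, stringsAsFactors = FALSE)
  g <- genotype_matrix(geno, pop_of_ind, meta)

  coords <- data.frame(population = pops, lat = lat, lon = lon)
  env <- data.frame(population = pops,
                    bio4 = 700 + 120 * seas_raw,
                    env_noise1 = rnorm(n_pops),
                    env_noise2 = rnorm(n_pops))
  list(genotypes = g, coords = coords, env = env,
       truth = list(locus_type = locus_type, seasonality_z = z_pop,
                    scenario_id = cfg$scenario_id,
                    scenario_params = cfg$scenario_params))
}

#' Generate synthetic environmental raster layers and occurrences
#'
#' Builds a small raster stack over the gradient's bounding box: a
#' seasonality layer that increases deterministically with latitude
#' (emulating the zonation of temperature seasonality) plus `n_noise`
#' independent noise layers, and draws occurrence points for two species
#' from Gaussian climate envelopes. In `conserved_niche` mode both species
#' share one climate envelope but occupy geographically split halves of
#' the grid (the generative situation in which a background test should
#' report conservatism); otherwise the envelopes are centred on opposite
#' ends of the seasonality axis.
#'
#' @param cfg a [synthetic_config()]
#' @param n_cells grid cells per axis (default 40)
#' @param n_noise number of noise layers (default 2)
#' @param n_occ_x,n_occ_y occurrence counts (defaults 9 and 14)
#' @param conserved_niche logical (default TRUE)
#' @return list: `layers` (named list of [ascii_raster()]), `occ_x`,
#'   `occ_y` (data frames with `lon`, `lat`)
#' @export
generate_env_layers <- function(cfg = synthetic_config(), n_cells = 40,
                                n_noise = 2, n_occ_x = 9, n_occ_y = 14,
                                conserved_niche = TRUE,
                                seas_noise_sd = 30) {
  cs <- (cfg$lat_range[2] - cfg$lat_range[1]) / n_cells
  xll <- cfg$lon_center - n_cells / 2 * cs
  yll <- cfg$lat_range[1]
  lat_of_row <- yll + (n_cells - seq_len(n_cells) + 0.5) * cs
  gradient <- matrix(rep(100 * (lat_of_row - yll), n_cells),
                     nrow = n_cells)
  seas <- gradient + matrix(rnorm(n_cells^2, 0, seas_noise_sd), n_cells)
  layers <- list(seasonality = ascii_raster(seas, xll, yll, cs))
  for (k in seq_len(n_noise)) {
    layers[[paste0("noise", k)]] <-
      ascii_raster(matrix(rnorm(n_cells^2), n_cells), xll, yll, cs)
  }

  cc <- raster_coords(layers[[1]])
  seas_v <- as.vector(seas)
  draw_occ <- function(n, center, sd, geo_keep = rep(TRUE, nrow(cc))) {
    w <- exp(-(seas_v - center)^2 / (2 * sd^2)) * geo_keep
    pick <- sample(nrow(cc), n, prob = w / sum(w))
    data.frame(lon = cc$lon[pick], lat = cc$lat[pick])
  }
  mid_lat <- mean(cfg$lat_range)
  rng <- range(gradient)
  if (conserved_niche) {
    # one shared climate envelope; ranges split geographically. The
    # latitude-independent part of the seasonality layer lets both halves
    # reach the shared climate band, the generative meaning of a
    # conserved niche across a range boundary.
    center <- mean(rng); sdv <- seas_noise_sd / 2
    occ_x <- draw_occ(n_occ_x, center, sdv, cc$lat < mid_lat)
    occ_y <- draw_occ(n_occ_y, center, sdv, cc$lat >= mid_lat)
  } else {
    sdv <- diff(rng) / 8
    occ_x <- draw_occ(n_occ_x, rng[1] + diff(rng) / 4, sdv)
    occ_y <- draw_occ(n_occ_y, rng[2] - diff(rng) / 4, sdv)
  }
  list(layers = layers, gradient = ascii_raster(gradient, xll, yll, cs),
       occ_x = occ_x, occ_y = occ_y)
}
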