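#' Fill missing dosages by within-population locus means
#'
#' Deterministic interpolation used before computing genotype distances:
#' each missing dosage is replaced by the mean dosage of that locus within
#' the individual's population, falling back to the global locus mean when
#' the population has no typed individual there.
#'
#' @param g a [genotype_matrix()]
#' @return numeric matrix of dosages with no missing values
#' @export
interpolate_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$geno
  storage.mode(X) <- "double"
  if (!anyNA(X)) return(X)
  glob <- colMeans(X, na.rm = TRUE)
  glob[is.nan(glob)] <- 0
  for (pp in levels(g$population)) {
    idx <- which(g$population == pp)
    sub <- X[idx, , drop = FALSE]
    pm <- colMeans(sub, na.rm = TRUE)
    pm[is.nan(pm)] <- glob[is.nan(pm)]
    na_at <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_at)) X[cbind(idx[na_at[, 1]], na_at[, 2])] <- pm[na_at[, 2]]
  }
  X
}

# squared allele-dosage distance matrix (codominant-genotypic metric)
dosage_dist2 <- function(g, loci = NULL, interpolate = TRUE) {
  gg <- if (is.null(loci)) g else subset_loci(g, loci)
  if (anyNA(gg$geno)) {
    if (!interpolate)
      stop("missing genotypes present; use interpolate_missing = TRUE")
    X <- interpolate_missing(gg)
  } else {
    X <- gg$geno
    storage.mode(X) <- "double"
  }
  as.matrix(dist(X))^2
}

# sum of squared distances within each level of fac, each divided by group n
ss_within <- function(D2, fac) {
  s <- 0
  for (lv in levels(fac)) {
    i <- which(fac == lv)
    if (length(i) > 1) s <- s + sum(D2[i, i]) / (2 * length(i))
  }
  s
}

# two-level variance components from a squared-distance matrix
phi_components <- function(D2, fac) {
  N <- nrow(D2)
  ng <- nlevels(fac)
  sst <- sum(D2) / (2 * N)
  ssw <- ss_within(D2, fac)
  ssa <- sst - ssw
  df_a <- ng - 1
  df_w <- N - ng
  n_g <- tabulate(fac)
  n0 <- (N - sum(n_g^2) / N) / df_a
  ms_w <- if (df_w > 0) ssw / df_w else 0
  ms_a <- if (df_a > 0) ssa / df_a else 0
  s2_w <- ms_w
  s2_a <- (ms_a - ms_w) / n0
  c(among = s2_a, within = s2_w)
}

phi_from_components <- function(comp) {
  tot <- comp["among"] + comp["within"]
  if (tot <= 0) return(0)
  min(1, max(0, unname(comp["among"] / tot)))
}

#' Pairwise Phi distances between populations
#'
#' For each population pair, a two-level AMOVA on squared inter-individual
#' allele-dosage distances (the squared difference of 0/1/2 dosages summed
#' over loci) partitions variance among vs within the two populations;
#' `Phi = sigma2_among / (sigma2_among + sigma2_within)`, clamped to
#' `[0, 1]`. Permutation p-values reshuffle individuals between the two
#' populations and use the `(b + 1) / (m + 1)` estimator.
#'
#' @param g a [genotype_matrix()]
#' @param loci optional locus subset (index into columns)
#' @param interpolate_missing replace missing dosages by population locus
#'   means before computing distances (default TRUE)
#' @param n_perm number of label permutations per pair (0 skips the test)
#' @param loci_used tag recorded on the result (`"all"`, `"neutral"`,
#'   `"outlier"`, ...)
#' @return list of class `phi_matrix`: `phi` (symmetric matrix), `p`
#'   (permutation p-values, `NA` if `n_perm = 0`), `loci_used`
#' @export
pairwise_phi <- function(g, loci = NULL, interpolate_missing = TRUE,
                         n_perm = 999, loci_used = "all") {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- levels(g$population)
  if (length(pops) < 2) stop("need at least 2 populations")
  D2 <- dosage_dist2(g, loci, interpolate_missing)
  np <- length(pops)
  phi <- matrix(0, np, np, dimnames = list(pops, pops))
  pval <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  diag(pval) <- 0
  for (a in seq_len(np - 1)) for (b in (a + 1):np) {
    idx <- which(g$population %in% pops[c(a, b)])
    sub <- D2[idx, idx, drop = FALSE]
    fac <- droplevels(g$population[idx])
    obs <- phi_from_components(phi_components(sub, fac))
    phi[a, b] <- phi[b, a] <- obs
    if (n_perm > 0) {
      hits <- 0L
      for (r in seq_len(n_perm)) {
        perm <- sample(length(idx))
        stat <- phi_from_components(phi_components(sub[perm, perm], fac))
        if (stat >= obs) hits <- hits + 1L
      }
      pval[a, b] <- pval[b, a] <- (hits + 1) / (n_perm + 1)
    }
  }
  structure(list(phi = phi, p = pval, loci_used = loci_used),
            class = "phi_matrix")
}

#' @export
print.phi_matrix <- function(x, ...) {
  cat("pairwise Phi (", x$loci_used, " loci)\n", sep = "")
  print(round(x$phi, 4))
  invisible(x)
}

# three-level variance components (species / populations / individuals)
amova3_components <- function(D2, species, pop) {
  N <- nrow(D2)
  s <- nlevels(species)
  p <- nlevels(pop)
  sst <- sum(D2) / (2 * N)
  ss_wp <- ss_within(D2, pop)
  ss_ws <- ss_within(D2, species)
  ss_ap <- ss_ws - ss_wp
  ss_as <- sst - ss_ws

  df_as <- s - 1
  df_ap <- p - s
  df_wp <- N - p

  n_p <- tabulate(pop)
  # population -> species sizes
  sp_of_pop <- vapply(levels(pop), function(lv)
    as.character(species[which(pop == lv)[1]]), character(1))
  N_s <- tabulate(species)
  names(N_s) <- levels(species)

  sum_np2_over_Ns <- sum(vapply(levels(species), function(sv) {
    sum(n_p[sp_of_pop == sv]^2) / N_s[sv]
  }, numeric(1)))
  n_c <- (N - sum_np2_over_Ns) / df_ap
  n_b <- (sum_np2_over_Ns - sum(n_p^2) / N) / df_as
  n_a <- (N - sum(N_s^2) / N) / df_as

  ms_wp <- if (df_wp > 0) ss_wp / df_wp else 0
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else 0
  ms_as <- if (df_as > 0) ss_as / df_as else 0

  s2_c <- ms_wp
  s2_b <- if (df_ap > 0) (ms_ap - s2_c) / n_c else 0
  s2_a <- (ms_as - s2_c - n_b * s2_b) / n_a
  c(between_species = s2_a, among_pops = s2_b, within_pops = s2_c)
}

amova3_phis <- function(comp) {
  comp <- pmax(comp, 0)
  tot <- sum(comp)
  if (tot <= 0)
    return(c(Phi_RT = 0, Phi_PR = 0, Phi_PT = 0))
  c(Phi_RT = unname(comp[1] / tot),
    Phi_PR = unname(if (comp[2] + comp[3] > 0) comp[2] / (comp[2] + comp[3]) else 0),
    Phi_PT = unname((comp[1] + comp[2]) / tot))
}

#' Hierarchical AMOVA (species / populations / individuals)
#'
#' Three-level analysis of molecular variance on squared allele-dosage
#' distances. Variance components use the standard unequal-sample-size
#' expected-mean-square coefficients; negative components are truncated at
#' zero before percentages. Permutation tests: individuals are permuted
#' freely among populations for the between-species and total statistics
#' (`Phi_RT`, `Phi_PT`), and within species for the among-population
#' statistic (`Phi_PR`); p-values use `(b + 1) / (m + 1)`.
#'
#' @param g a [genotype_matrix()] whose `pop_meta` assigns each population
#'   to a species (at least two species)
#' @param loci optional locus subset
#' @param interpolate_missing see [pairwise_phi()]
#' @param n_perm number of permutations (default 999; 0 skips tests)
#' @return list of class `amova_result`: `components` data frame (variance,
#'   percent), `phi` (Phi_RT, Phi_PR, Phi_PT), `p` (permutation p-values),
#'   `n_perm`
#' @export
amova <- function(g, loci = NULL, interpolate_missing = TRUE, n_perm = 999) {
  stopifnot(inherits(g, "genotype_matrix"))
  species <- factor(species_of_individuals(g))
  pop <- g$population
  if (nlevels(species) < 2) stop("need at least 2 species for hierarchical AMOVA")
  D2 <- dosage_dist2(g, loci, interpolate_missing)
  comp <- amova3_components(D2, species, pop)
  comp_t <- pmax(comp, 0)
  tot <- sum(comp_t)
  pct <- if (tot > 0) 100 * comp_t / tot else c(0, 0, 100)
  phis <- amova3_phis(comp)

  pvals <- c(Phi_RT = NA_real_, Phi_PR = NA_real_, Phi_PT = NA_real_)
  if (n_perm > 0) {
    hits <- c(0L, 0L, 0L)
    N <- nrow(D2)
    sp_idx <- split(seq_len(N), species)
    for (r in seq_len(n_perm)) {
      perm_free <- sample(N)
      st_free <- amova3_phis(amova3_components(
        D2[perm_free, perm_free], species, pop))
      perm_ws <- seq_len(N)
      for (ii in sp_idx) perm_ws[ii] <- ii[sample(length(ii))]
      st_ws <- amova3_phis(amova3_components(
        D2[perm_ws, perm_ws], species, pop))
      if (st_free["Phi_RT"] >= phis["Phi_RT"]) hits[1] <- hits[1] + 1L
      if (st_ws["Phi_PR"] >= phis["Phi_PR"]) hits[2] <- hits[2] + 1L
      if (st_free["Phi_PT"] >= phis["Phi_PT"]) hits[3] <- hits[3] + 1L
    }
    pvals[] <- (hits + 1) / (n_perm + 1)
  }

  structure(list(
    components = data.frame(
      level = c("between_species", "among_pops_within_species",
                "within_populations"),
      variance = unname(comp_t),
      percent = unname(pct)),
    phi = phis,
    p = pvals,
    n_perm = n_perm), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$n_perm, " permutations)\n", sep = "")
  df <- x$components
  df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE)
  cat("Phi: ", paste(names(x$phi), round(x$phi, 4), sep = " = ",
                     collapse = ", "), "\n")
  if (!all(is.na(x$p)))
    cat("p:   ", paste(names(x$p), round(x$p, 4), sep = " = ",
                       collapse = ", "), "\n")
  invisible(x)
}
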