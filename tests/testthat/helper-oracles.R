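# Small fixture builders and naive reference implementations used as
# independent oracles. All deliberately written as plain double loops,
# independent of the package's vectorized code paths.

# genotype_matrix from a plain dosage matrix and a population vector
toy_gm <- function(geno, pop, lineage = NULL, species = NULL) {
  pops <- unique(as.character(pop))
  meta <- data.frame(
    population = pops,
    lineage = if (is.null(lineage)) pops else lineage,
    species = if (is.null(species)) "sp" else species,
    stringsAsFactors = FALSE)
  genotype_matrix(geno, pop, meta)
}

# squared dosage distance by explicit loops
oracle_dist2 <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(ncol(X))) s <- s + (X[i, l] - X[j, l])^2
    D[i, j] <- s
  }
  D
}

# two-level AMOVA variance components, naive double-loop version
oracle_phi2 <- function(X, pop) {
  pop <- factor(pop)
  D <- oracle_dist2(X)
  N <- nrow(X)
  sst <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) sst <- sst + D[i, j]
  sst <- sst / N
  ssw <- 0
  for (lv in levels(pop)) {
    idx <- which(pop == lv)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + D[idx[a], idx[b]]
    ssw <- ssw + s / length(idx)
  }
  ssa <- sst - ssw
  g <- nlevels(pop)
  n_g <- as.numeric(table(pop))
  n0 <- (N - sum(n_g^2) / N) / (g - 1)
  ms_w <- ssw / (N - g)
  ms_a <- ssa / (g - 1)
  s2w <- ms_w
  s2a <- (ms_a - ms_w) / n0
  phi <- if (s2a + s2w <= 0) 0 else min(1, max(0, s2a / (s2a + s2w)))
  list(s2a = s2a, s2w = s2w, phi = phi)
}

# three-level AMOVA components, naive version
oracle_amova3 <- function(X, species, pop) {
  species <- factor(species); pop <- factor(pop)
  D <- oracle_dist2(X)
  N <- nrow(X)
  ss_of <- function(idx) {
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + D[idx[a], idx[b]]
    s / length(idx)
  }
  sst <- ss_of(seq_len(N))
  ss_wp <- 0
  for (lv in levels(pop)) ss_wp <- ss_wp + ss_of(which(pop == lv))
  ss_ws <- 0
  for (lv in levels(species)) ss_ws <- ss_ws + ss_of(which(species == lv))
  ss_ap <- ss_ws - ss_wp
  ss_as <- sst - ss_ws
  s <- nlevels(species); p <- nlevels(pop)
  n_p <- as.numeric(table(pop))
  N_s <- as.numeric(table(species))
  sp_of_pop <- sapply(levels(pop), function(lv)
    as.character(species[which(pop == lv)[1]]))
  sum_np2_Ns <- 0
  for (k in seq_along(levels(species))) {
    sv <- levels(species)[k]
    sum_np2_Ns <- sum_np2_Ns + sum(n_p[sp_of_pop == sv]^2) / N_s[k]
  }
  n_c <- (N - sum_np2_Ns) / (p - s)
  n_b <- (sum_np2_Ns - sum(n_p^2) / N) / (s - 1)
  n_a <- (N - sum(N_s^2) / N) / (s - 1)
  ms_wp <- ss_wp / (N - p)
  ms_ap <- ss_ap / (p - s)
  ms_as <- ss_as / (s - 1)
  s2c <- ms_wp
  s2b <- (ms_ap - s2c) / n_c
  s2a <- (ms_as - s2c - n_b * s2b) / n_a
  comp <- pmax(c(s2a, s2b, s2c), 0)
  list(components = comp,
       percent = if (sum(comp) > 0) 100 * comp / sum(comp) else c(0, 0, 100))
}

# a random dataset with species/population structure for oracle checks
random_structured_gm <- function(n_per_pop, n_loci, seed) {
  set.seed(seed)
  npop <- length(n_per_pop)
  pop <- rep(paste0("p", seq_len(npop)), times = n_per_pop)
  sp <- rep(c("A", "B"), length.out = npop)
  freqs <- matrix(runif(npop * n_loci, 0.1, 0.9), npop)
  geno <- do.call(rbind, lapply(seq_len(npop), function(k) {
    matrix(rbinom(n_per_pop[k] * n_loci, 2, rep(freqs[k, ],
                                                each = n_per_pop[k])),
           nrow = n_per_pop[k])
  }))
  toy_gm(geno, pop, species = sp)
}

# all permutations of 1..n, independent recursion for the Mantel oracle
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in oracle_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos - 1)
    }
  }
  out
}
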