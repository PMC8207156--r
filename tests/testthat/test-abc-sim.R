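test_that("every emitted locus satisfies the MAF condition", {
  set.seed(41)
  g <- simulate_snp_dataset(2, default_scenario2_params(), c(5, 5, 5),
                            n_loci = 80, maf_min = 0.1)
  cnt <- colSums(g$geno)
  n_hap <- 2 * nrow(g$geno)
  expect_true(all(pmin(cnt, n_hap - cnt) / n_hap >= 0.1 - 1e-12))
  expect_true(all(g$geno %in% 0:2))
})

test_that("simulation is reproducible from the seed", {
  par <- default_scenario2_params()
  set.seed(42); g1 <- simulate_snp_dataset(1, par, c(4, 4, 4), 30)
  set.seed(42); g2 <- simulate_snp_dataset(1, par, c(4, 4, 4), 30)
  expect_identical(g1$geno, g2$geno)
})

test_that("degenerate merge at time zero is panmixia", {
  set.seed(43)
  par <- c(N1 = 5000, N2 = 5000, N3 = 5000, Na = 5000, Nc = 5000,
           t1 = 0, t2 = 0)
  g <- simulate_snp_dataset(2, par, c(8, 8, 8), 200, maf_min = 0.05)
  st <- lineage_summary_stats(g)
  fst <- st[c("Fst_12", "Fst_13", "Fst_23")]
  # across 200 loci the mean pairwise Fst of a panmictic sample is tiny;
  # allow generous Monte-Carlo scatter around 0
  expect_true(all(fst < 0.05))
})

test_that("two-population split matches an independent plain-R coalescent", {
  # oracle: naive two-deme coalescent with one branch-proportional
  # mutation per locus, written with per-lineage bookkeeping only
  oracle_two_pop <- function(n_per_deme, N, t_split, n_loci) {
    n <- 2 * n_per_deme
    sapply(seq_len(n_loci), function(l) {
      nodes <- list()
      for (i in 1:n) nodes[[i]] <- list(tips = i, t = 0)
      act <- list(which(seq_len(n) <= n_per_deme),
                  which(seq_len(n) > n_per_deme))
      t_cur <- 0
      edges <- list()
      close_edges <- function(nodes, parent_t, children) {
        for (ch in children)
          edges[[length(edges) + 1]] <<- list(
            tips = nodes[[ch]]$tips, len = parent_t - nodes[[ch]]$t)
      }
      # phase 1: within demes until t_split
      repeat {
        rates <- sapply(act, function(a)
          if (length(a) >= 2) choose(length(a), 2) / (2 * N) else 0)
        if (sum(rates) == 0) { t_cur <- t_split; break }
        w <- rexp(1, sum(rates))
        if (t_cur + w >= t_split) { t_cur <- t_split; break }
        t_cur <- t_cur + w
        d <- sample(1:2, 1, prob = rates)
        pair <- sample(act[[d]], 2)
        close_edges(nodes, t_cur, pair)
        nodes[[length(nodes) + 1]] <- list(
          tips = c(nodes[[pair[1]]]$tips, nodes[[pair[2]]]$tips), t = t_cur)
        act[[d]] <- c(setdiff(act[[d]], pair), length(nodes))
      }
      # phase 2: single ancestral deme
      a <- c(act[[1]], act[[2]])
      while (length(a) > 1) {
        t_cur <- t_cur + rexp(1, choose(length(a), 2) / (2 * N))
        pair <- sample(a, 2)
        close_edges(nodes, t_cur, pair)
        nodes[[length(nodes) + 1]] <- list(
          tips = c(nodes[[pair[1]]]$tips, nodes[[pair[2]]]$tips), t = t_cur)
        a <- c(setdiff(a, pair), length(nodes))
      }
      lens <- sapply(edges, `[[`, "len")
      e <- sample(length(edges), 1, prob = lens)
      derived <- seq_len(n) %in% edges[[e]]$tips
      c(p1 = mean(derived[1:n_per_deme]),
        p2 = mean(derived[-(1:n_per_deme)]))
    })
  }
  wright_fst <- function(p) {
    hs <- colMeans(rbind(2 * p[1, ] * (1 - p[1, ]),
                         2 * p[2, ] * (1 - p[2, ])))
    pbar <- colMeans(p)
    ht <- 2 * pbar * (1 - pbar)
    (mean(ht) - mean(hs)) / mean(ht)
  }
  N <- 2000; t_split <- 1200; n_loci <- 600
  set.seed(44)
  p_oracle <- oracle_two_pop(10, N, t_split, n_loci)
  fst_oracle <- wright_fst(p_oracle)

  # same demography through the package simulator: lineage 2 sampled with
  # 0 individuals, split t1 = t2 = t_split, all sizes N
  par <- c(N1 = N, N2 = N, N3 = N, Na = N, Nc = N,
           t1 = t_split, t2 = t_split)
  fst_pkg <- replicate(6, {
    g <- simulate_snp_dataset(2, par, c(10, 1, 10), n_loci, maf_min = 0)
    lin <- factor(lineage_of_individuals(g))
    keep <- lin %in% c("Dson", "Dvov-N")
    p <- rbind(colMeans(g$geno[lin == "Dson", ]) / 2,
               colMeans(g$geno[lin == "Dvov-N", ]) / 2)
    wright_fst(p)
  })
  se <- sd(fst_pkg) / sqrt(length(fst_pkg))
  expect_lt(abs(mean(fst_pkg) - fst_oracle), 4 * max(se, 0.01))
  # the classical 1 - exp(-t/2N) anchor assumes infinite-sites
  # heterozygosity; the one-SNP-per-locus model is length-biased, so the
  # anchor holds only loosely. Divergence-time monotonicity is exact.
  expected <- 1 - exp(-t_split / (2 * N))
  expect_gt(mean(fst_pkg), 0.4 * expected)
  expect_lt(mean(fst_pkg), 1.3 * expected)
  fst_at <- function(t, seed) {
    set.seed(seed)
    par_t <- c(N1 = N, N2 = N, N3 = N, Na = N, Nc = N, t1 = t, t2 = t)
    g <- simulate_snp_dataset(2, par_t, c(10, 1, 10), 500, maf_min = 0)
    lin <- factor(lineage_of_individuals(g))
    p <- rbind(colMeans(g$geno[lin == "Dson", ]) / 2,
               colMeans(g$geno[lin == "Dvov-N", ]) / 2)
    wright_fst(p)
  }
  expect_lt(fst_at(200, 46), fst_at(1500, 47))
  expect_lt(fst_at(1500, 47), fst_at(8000, 48))
})

test_that("scenarios 1 and 2 coincide when Na = Nc (label symmetry)", {
  set.seed(45)
  par <- c(N1 = 20000, N2 = 5000, N3 = 30000, Na = 12000, Nc = 12000,
           t1 = 5000, t2 = 9000)
  stats <- function(sc) replicate(250, {
    g <- simulate_snp_dataset(sc, par, c(5, 5, 5), 40)
    lineage_summary_stats(g)[["Fst_13"]]
  })
  s1 <- stats(1); s2 <- stats(2)
  ks <- suppressWarnings(ks.test(s1, s2))
  expect_gt(ks$p.value, 0.01)
})
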