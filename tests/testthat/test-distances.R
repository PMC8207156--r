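toy_coords <- function() {
  data.frame(population = c("a", "b", "c", "d"),
             lat = c(27, 28, 28.5, 29.5),
             lon = c(-109, -109, -109.5, -110))
}

toy_env <- function() {
  set.seed(61)
  data.frame(population = c("a", "b", "c", "d"),
             bio4 = c(600, 700, 760, 860),
             v1 = rnorm(4), v2 = rnorm(4))
}

test_that("geographic and latitudinal matrices follow the formulas", {
  co <- data.frame(population = c("x", "y", "z"),
                   lat = c(28, 28, 29), lon = c(-109, -109, -109))
  env <- data.frame(population = c("x", "y", "z"), v1 = 1:3, v2 = c(2, 1, 4))
  dm <- build_distances(co, env)
  expect_equal(dm$Geo["x", "y"], 0)
  # one degree of latitude on a meridian on the mean-radius sphere
  expect_equal(dm$Geo["y", "z"], 111.195, tolerance = 1e-3)
  expect_equal(dm$Lat["x", "z"], 1)
  expect_equal(dm$Lat, t(dm$Lat))
  # populations with missing environmental data are dropped with a warning
  env$v1[2] <- NA
  expect_warning(dm2 <- build_distances(co, env), "missing")
  expect_equal(rownames(dm2$Geo), c("x", "z"))
})

test_that("Mantel r and p behave on exact cases and match vegan", {
  set.seed(62)
  A <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_equal(mantel_test(A, A, n_perm = 99)$r, 1)
  expect_equal(mantel_test(A, -A, n_perm = 0)$r, -1)
  B <- as.matrix(dist(matrix(rnorm(12), 6)))
  r_pkg <- mantel_test(A, B, n_perm = 0)$r
  r_veg <- vegan::mantel(A, B, permutations = 99)$statistic
  expect_equal(r_pkg, unname(r_veg), tolerance = 1e-12)
})

test_that("exhaustive Mantel p matches an independent enumeration", {
  set.seed(63)
  A <- as.matrix(dist(matrix(rnorm(8), 4)))
  B <- as.matrix(dist(matrix(rnorm(8), 4)))
  res <- mantel_test(A, B, exhaustive = TRUE)
  expect_equal(res$n_perm, 24)
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  rs <- sapply(oracle_perms(4), function(pp) cor(A[lt], B[pp, pp][lt]))
  expect_equal(res$p, mean(rs >= r_obs - 1e-12))
  # random-permutation p approaches the exhaustive value
  set.seed(64)
  res_mc <- mantel_test(A, B, n_perm = 9999)
  expect_lt(abs(res_mc$p - res$p), 0.03)
})

test_that("AICc matches a from-scratch computation on a toy regression", {
  set.seed(65)
  n <- 6
  x <- 1:6
  y <- 2 + 0.5 * x + c(0.1, -0.2, 0.05, 0.12, -0.08, 0.01)
  M <- function(v) {
    m <- matrix(0, 4, 4)
    m[lower.tri(m)] <- v
    m + t(m)
  }
  dms <- list(resp = M(y), Geo = M(x))
  rk <- rank_models(dms, "resp", model_set = "Geo")
  fit <- lm(y ~ x)
  rss <- sum(fit$residuals^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- 3  # slope, intercept, residual variance
  aicc_hand <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(rk$AICc, aicc_hand, tolerance = 1e-9)
})

test_that("model ranking recovers a planted interaction model", {
  set.seed(66)
  npop <- 9
  co <- data.frame(population = paste0("p", 1:npop),
                   lat = seq(27, 29.5, length.out = npop),
                   lon = -109 + runif(npop, -0.3, 0.3))
  env <- data.frame(population = co$population,
                    bio4 = 600 + 100 * co$lat + rnorm(npop, 0, 5),
                    v1 = rnorm(npop), v2 = rnorm(npop))
  dm <- build_distances(co, env)
  lt <- lower.tri(dm$Geo)
  resp <- dm$Geo
  resp[] <- 0
  vals <- 1.05 + 0.004 * dm$Lat[lt] * dm$Geo[lt] +
    rnorm(sum(lt), 0, 0.02)
  resp[lower.tri(resp)] <- vals
  resp <- resp + t(resp)
  dm$resp <- resp
  rk <- rank_models(dm, "resp")
  expect_equal(rk$formula[1], "Lat * Geo")
  # nesting: a model with an extra predictor never fits worse in RSS
  fits <- attr(rk, "fits")
  rss <- function(f) sum(fits[[f]]$residuals^2)
  expect_lte(rss("Geo + Lat"), rss("Geo") + 1e-10)
  expect_lte(rss("Geo + Env + Lat"), rss("Geo + Lat") + 1e-10)
  # a duplicated model gets an identical AICc and adjacent rank
  rk2 <- rank_models(dm, "resp", model_set = c("Lat * Geo", "Lat * Geo"))
  expect_equal(rk2$AICc[1], rk2$AICc[2])
})

test_that("diversity-covariate correlations: exactness and invariance", {
  set.seed(67)
  div <- data.frame(population = paste0("p", 1:8),
                    Ae = runif(8, 1, 2), Ho = runif(8, .1, .4))
  cov <- data.frame(population = div$population,
                    latitude = seq(27, 29.5, length.out = 8))
  cov$mirror <- div$Ae
  res <- diversity_correlations(div, cov)
  expect_equal(res$r[res$metric == "Ae" & res$covariate == "mirror"], 1,
               tolerance = 1e-12)
  # z-scoring leaves r unchanged: compare against plain cor
  r_plain <- cor(div$Ho, cov$latitude)
  expect_equal(res$r[res$metric == "Ho" & res$covariate == "latitude"],
               r_plain, tolerance = 1e-12)
})
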