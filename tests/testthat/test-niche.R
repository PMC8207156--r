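grid_raster <- function(m, xll = -110, yll = 27, cs = 0.1) {
  ascii_raster(m, xll, yll, cs)
}

test_that("ESRI ASCII grids round trip with nodata", {
  set.seed(71)
  m <- matrix(round(runif(20), 3), 4, 5)
  m[2, 3] <- NA
  r <- grid_raster(m)
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(r, f)
  r2 <- read_esri_ascii(f)
  expect_equal(r2$values, r$values)
  expect_equal(r2$cellsize, r$cellsize)
  # extraction hits the written cells
  cc <- raster_coords(r)
  v <- extract_raster(r, cc$lon, cc$lat)
  expect_equal(v, as.vector(r$values))
})

test_that("layer pruning removes exactly the duplicated layers", {
  set.seed(72)
  a <- grid_raster(matrix(rnorm(100), 10))
  b <- grid_raster(a$values * 2 + 1)          # perfectly correlated with a
  c_ <- grid_raster(matrix(rnorm(100), 10))   # independent
  pr <- prune_correlated_layers(list(A = a, B = b, C = c_), 0.9)
  expect_equal(length(pr$removed), 1)
  expect_true(pr$removed %in% c("A", "B"))
  expect_true("C" %in% pr$retained)
  # independent noise layers: nothing removed
  d <- grid_raster(matrix(rnorm(100), 10))
  pr2 <- prune_correlated_layers(list(C = c_, D = d), 0.9)
  expect_equal(pr2$removed, character(0))
})

test_that("climate PCA: variance shares, orthonormality, hand oracle", {
  x <- c(1, 2, 3, 4)
  tab <- data.frame(v1 = x, v2 = 3 * x + 2)
  pc <- suppressWarnings(climate_pca(tab))
  expect_equal(pc$explained[1], 1)
  set.seed(73)
  tab2 <- as.data.frame(matrix(rnorm(40), 10))
  pc2 <- climate_pca(tab2)
  expect_equal(crossprod(pc2$loadings), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # 3 x 2 hand computation via the correlation-matrix eigendecomposition
  tab3 <- data.frame(a = c(1, 2, 4), b = c(2, 1, 3))
  Z <- scale(as.matrix(tab3))
  eg <- eigen(cor(tab3))
  sc_hand <- Z %*% eg$vectors
  pc3 <- climate_pca(tab3)
  for (k in 1:2)
    expect_equal(abs(pc3$scores[, k]), abs(sc_hand[, k]), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("Levins B1 matches the closed forms and is scale-invariant", {
  expect_equal(levins_b1(grid_raster(matrix(1, 5, 4))), 1)
  m0 <- matrix(0, 3, 3); m0[2, 2] <- 7
  expect_equal(levins_b1(grid_raster(m0)), 0)
  m2 <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(levins_b1(grid_raster(m2)), 1 / 3)
  set.seed(74)
  m <- matrix(runif(30), 5)
  expect_equal(levins_b1(grid_raster(m)), levins_b1(grid_raster(m * 17)))
})

test_that("Warren's I matches closed forms, symmetry, scale invariance", {
  set.seed(75)
  m <- matrix(runif(20), 4)
  expect_equal(warren_i(grid_raster(m), grid_raster(m)), 1)
  a <- matrix(c(1, 0, 0, 0), 2); b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(warren_i(grid_raster(a), grid_raster(b)), 0)
  p <- matrix(c(1, 0), 1); q <- matrix(c(0.5, 0.5), 1)
  expect_equal(round(warren_i(grid_raster(p), grid_raster(q)), 4), 0.7071)
  m2 <- matrix(runif(20), 4)
  expect_equal(warren_i(grid_raster(m), grid_raster(m2)),
               warren_i(grid_raster(m2), grid_raster(m)))
  expect_equal(warren_i(grid_raster(m), grid_raster(m2 * 5)),
               warren_i(grid_raster(m), grid_raster(m2)))
  expect_error(warren_i(grid_raster(m), grid_raster(matrix(1, 2, 2))),
               "same grid")
})

test_that("the Mahalanobis envelope estimator follows its formula", {
  # climate grid on a 0.2 lattice so -1, 0, 1 and 2 occur exactly;
  # occurrences at -1, 0, 1 give mean 0 and unit sample variance
  vals <- matrix(seq(-3.4, 3.6, length.out = 36), 6)
  lay <- list(clim = grid_raster(vals))
  cc <- raster_coords(lay$clim)
  pick <- sapply(c(-1, 0, 1), function(v)
    which(abs(as.vector(vals) - v) < 1e-9)[1])
  occ <- data.frame(lon = cc$lon[pick], lat = cc$lat[pick])
  S <- envelope_estimator(occ, lay, ridge = 0)
  sv <- as.vector(S$values)
  # cell at the climate centroid scores 1
  expect_equal(sv[which(abs(as.vector(vals)) < 1e-9)], 1)
  # suitability strictly decreasing in squared distance from the centroid
  ordv <- order(abs(as.vector(vals)))
  expect_true(all(diff(sv[ordv]) <= 1e-12))
  # a cell two occurrence-SDs away scores exp(-2)
  expect_equal(sv[which(abs(as.vector(vals) - 2) < 1e-9)], exp(-2))
})

test_that("background test verdicts: degenerate null and conservatism", {
  set.seed(76)
  cfg <- synthetic_config()
  env <- generate_env_layers(cfg, n_cells = 25, conserved_niche = TRUE)
  # degenerate estimator: every replicate (and both empirical surfaces)
  # collapse onto Y's envelope, so the null is a point mass at the
  # empirical overlap and similarity cannot be rejected
  forced <- function(occ, layers, ...) envelope_estimator(env$occ_y, layers)
  bt0 <- background_test(env$occ_x, env$occ_y, env$layers,
                         estimator = forced, n_reps = 5)
  expect_equal(length(bt0$null$x_vs_background_y), 5)
  expect_true(all(bt0$null$x_vs_background_y == bt0$I_empirical))
  expect_true(all(bt0$verdict == "similarity not rejected"))

  # conserved-niche generative mode: repeated seeded runs call conservatism
  hits <- 0L
  for (s in 1:8) {
    set.seed(700 + s)
    ev <- generate_env_layers(cfg, n_cells = 25, conserved_niche = TRUE)
    bt <- background_test(ev$occ_x, ev$occ_y, ev$layers, n_reps = 30)
    if (any(bt$verdict == "conservatism")) hits <- hits + 1L
  }
  expect_gte(hits, 7)
  # reproducibility from seed
  set.seed(777)
  b1 <- background_test(env$occ_x, env$occ_y, env$layers, n_reps = 10)
  set.seed(777)
  b2 <- background_test(env$occ_x, env$occ_y, env$layers, n_reps = 10)
  expect_identical(b1$null, b2$null)
})
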