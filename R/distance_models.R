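#' Build the population-pair distance matrices
#'
#' Assembles the symmetric population x population matrices used in the
#' distance-matrix regressions: great-circle geographic distance (km,
#' haversine on the mean Earth radius), absolute latitudinal difference
#' (degrees), Euclidean environmental dissimilarity on z-scored variables,
#' absolute difference in temperature seasonality (`bio4`, when present),
#' absolute difference in climate-PCA PC1 scores, and any genetic Phi
#' matrices passed through. All matrices share one population ordering.
#'
#' @param coords data frame with columns `population`, `lat`, `lon`
#'   (decimal degrees)
#' @param env_table data frame with a `population` column and numeric
#'   environmental variables; an optional `pc1` column supplies PC1 scores
#'   directly, otherwise PC1 is computed from the z-scored variables
#' @param phi_matrices optional named list of `phi_matrix` objects or
#'   plain symmetric matrices (e.g. `list(neutral = ..., outlier = ...)`)
#' @return named list of matrices: `Geo`, `Lat`, `Env`, `PC1`, `bio4`
#'   (when available) and one entry per element of `phi_matrices`;
#'   populations with missing environmental values are dropped with a
#'   warning
#' @export
build_distances <- function(coords, env_table, phi_matrices = NULL) {
  stopifnot(all(c("population", "lat", "lon") %in% names(coords)))
  env <- as.data.frame(env_table)
  stopifnot("population" %in% names(env))
  m <- merge(coords, env, by = "population", sort = TRUE)
  num_cols <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                      c("lat", "lon"))
  ok <- complete.cases(m[, c("lat", "lon", num_cols)])
  if (!all(ok)) {
    warning("dropping populations with missing values: ",
            paste(m$population[!ok], collapse = ", "))
    m <- m[ok, , drop = FALSE]
  }
  pops <- m$population
  n <- length(pops)
  if (n < 2) stop("need at least 2 populations with complete data")

  geo <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- geosphere::distHaversine(c(m$lon[i], m$lat[i]),
                                  c(m$lon[j], m$lat[j]),
                                  r = 6371008.8) / 1000
    geo[i, j] <- geo[j, i] <- d
  }
  lat <- abs(outer(m$lat, m$lat, "-"))
  dimnames(lat) <- list(pops, pops)

  env_vars <- setdiff(num_cols, c("pc1", "PC1"))
  Z <- scale(as.matrix(m[, env_vars, drop = FALSE]))
  Z[, apply(Z, 2, function(z) anyNA(z))] <- 0  # constant variables
  envd <- as.matrix(dist(Z))
  dimnames(envd) <- list(pops, pops)

  pc1 <- if ("pc1" %in% names(m)) m$pc1
         else if ("PC1" %in% names(m)) m$PC1
         else prcomp(Z, center = FALSE, scale. = FALSE)$x[, 1]
  pc1d <- abs(outer(pc1, pc1, "-"))
  dimnames(pc1d) <- list(pops, pops)

  out <- list(Geo = geo, Lat = lat, Env = envd, PC1 = pc1d)
  if ("bio4" %in% names(m)) {
    b4 <- abs(outer(m$bio4, m$bio4, "-"))
    dimnames(b4) <- list(pops, pops)
    out$bio4 <- b4
  }
  for (nm in names(phi_matrices)) {
    P <- phi_matrices[[nm]]
    if (inherits(P, "phi_matrix")) P <- P$phi
    out[[nm]] <- P[pops, pops]
  }
  out
}

#' Simple Mantel test
#'
#' Pearson correlation of the lower triangles of two symmetric matrices,
#' with significance from simultaneous row/column permutations of the
#' second matrix. The p-value is one-sided (correlation at least as large
#' as observed) and uses the `(b + 1) / (m + 1)` estimator; with
#' `exhaustive = TRUE` all `n!` relabelings are enumerated instead and the
#' p-value is the exact fraction (identity included).
#'
#' @param A,B symmetric matrices of equal dimension
#' @param n_perm number of random permutations (default 999)
#' @param exhaustive enumerate all permutations (only sensible for small
#'   matrices)
#' @return list with `r`, `p`, `n_perm`
#' @export
mantel_test <- function(A, B, n_perm = 999, exhaustive = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(identical(dim(A), dim(B)), nrow(A) == ncol(A))
  n <- nrow(A)
  lt <- lower.tri(A)
  if (sd(A[lt]) == 0 || sd(B[lt]) == 0)
    return(list(r = NaN, p = NaN, n_perm = 0))
  r_obs <- cor(A[lt], B[lt])
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- vapply(seq_len(nrow(perms)), function(k) {
      pp <- perms[k, ]
      cor(A[lt], B[pp, pp][lt])
    }, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = nrow(perms)))
  }
  hits <- 0L
  for (k in seq_len(n_perm)) {
    pp <- sample(n)
    if (cor(A[lt], B[pp, pp][lt]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

# all permutations of 1..n as a matrix (n! rows)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

#' Default distance-model set
#'
#' All 31 non-empty main-effect subsets of the five predictors plus six
#' models built around the latitude-by-geography interaction, for 37
#' candidate models in total.
#'
#' @param predictors predictor names (default
#'   `c("Geo", "Env", "Lat", "PC1", "bio4")`)
#' @return character vector of model right-hand sides
#' @export
default_model_set <- function(predictors = c("Geo", "Env", "Lat",
                                             "PC1", "bio4")) {
  subsets <- unlist(lapply(seq_along(predictors), function(k)
    combn(predictors, k, paste, collapse = " + ", simplify = FALSE)))
  extra <- c("Lat * Geo",
             "Lat * Geo + Env", "Lat * Geo + PC1", "Lat * Geo + bio4",
             "Lat * Geo + Env + bio4", "Lat * Geo + Env + PC1")
  c(subsets, extra)
}

aicc_lm <- function(fit) {
  ll <- logLik(fit)
  k <- attr(ll, "df")            # coefficients + residual variance
  n <- length(fit$residuals)
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank distance-matrix regression models by AICc
#'
#' Vectorizes the response and predictor matrices over the off-diagonal
#' lower triangle (one observation per population pair), fits each
#' candidate model by ordinary least squares, and ranks them by the
#' small-sample-corrected Akaike information criterion
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)` (k counts the
#' coefficients plus the residual variance). Pairwise observations are not
#' independent; the AICc ranking is descriptive, as is standard for
#' distance-matrix model comparison.
#'
#' @param dms named list of matrices from [build_distances()]
#' @param response name of the response matrix in `dms`
#' @param model_set character vector of model right-hand sides (default
#'   [default_model_set()] restricted to available predictors)
#' @return data frame, one row per fitted model, ordered by AICc:
#'   `formula`, `k`, `logLik`, `AICc`, `delta_AICc`, `rank`, plus the
#'   intercept estimate, SE, t and p. Full fits in `attr(, "fits")`.
#' @export
rank_models <- function(dms, response, model_set = NULL) {
  stopifnot(response %in% names(dms))
  lt <- lower.tri(dms[[response]])
  dat <- as.data.frame(lapply(dms, function(M) as.matrix(M)[lt]))
  if (is.null(model_set)) {
    avail <- intersect(c("Geo", "Env", "Lat", "PC1", "bio4"), names(dms))
    model_set <- default_model_set(avail)
    if (!all(c("Lat", "Geo") %in% avail))
      model_set <- model_set[!grepl("\\*", model_set)]
  }
  n <- nrow(dat)
  fits <- list()
  rows <- lapply(model_set, function(rhs) {
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- lm(fml, data = dat)
    a <- aicc_lm(fit)
    if (is.na(a)) {
      warning("model '", rhs, "' skipped: too few pairs for AICc")
      return(NULL)
    }
    fits[[rhs]] <<- fit
    cf <- summary(fit)$coefficients
    data.frame(formula = rhs,
               k = attr(logLik(fit), "df"),
               logLik = as.numeric(logLik(fit)),
               AICc = a,
               intercept = cf["(Intercept)", 1],
               intercept_se = cf["(Intercept)", 2],
               intercept_t = cf["(Intercept)", 3],
               intercept_p = cf["(Intercept)", 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AICc), , drop = FALSE]
  out$delta_AICc <- out$AICc - out$AICc[1]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "n_pairs") <- n
  out
}

#' Correlations between diversity metrics and population covariates
#'
#' Pearson correlation (with two-sided p) between each z-scored genetic
#' diversity metric and each covariate, across populations.
#'
#' @param diversity data frame: `population` column plus numeric diversity
#'   metrics (e.g. `Ae`, `Ho`, `Theta`)
#' @param covariates data frame: `population` column plus numeric
#'   covariates (e.g. `latitude`, `PC1`, `PC2`)
#' @return data frame with columns `metric`, `covariate`, `r`, `p`, `n`
#' @export
diversity_correlations <- function(diversity, covariates) {
  m <- merge(diversity, covariates, by = "population")
  if (nrow(m) < 3) stop("need at least 3 populations")
  mets <- setdiff(names(diversity)[vapply(diversity, is.numeric,
                                          logical(1))], "population")
  covs <- setdiff(names(covariates)[vapply(covariates, is.numeric,
                                           logical(1))], "population")
  rows <- list()
  for (me in mets) for (cv in covs) {
    x <- as.numeric(scale(m[[me]]))
    y <- m[[cv]]
    if (all(is.na(x)) || sd(y, na.rm = TRUE) == 0) {
      r <- NaN; p <- NaN
    } else {
      ct <- cor.test(x, y)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(
      metric = me, covariate = cv, r = r, p = p, n = nrow(m),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
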