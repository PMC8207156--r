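# robust per-column scale for summary-statistic standardization:
# MAD, falling back to sd, falling back to 1 for constant columns
robust_scale <- function(X) {
  s <- apply(X, 2, stats::mad)
  s0 <- s == 0 | is.na(s)
  if (any(s0)) s[s0] <- apply(X[, s0, drop = FALSE], 2, sd)
  s[s == 0 | is.na(s)] <- 1
  s
}

abc_distances <- function(observed, stat_mat) {
  sc <- robust_scale(stat_mat)
  Z <- sweep(stat_mat, 2, sc, "/")
  z_obs <- observed / sc
  d <- sqrt(rowSums(sweep(Z, 2, z_obs, "-")^2))
  list(d = d, Z = Z, z_obs = z_obs, scale = sc)
}

epanechnikov_weights <- function(d, d_max) {
  if (d_max <= 0) return(rep(1, length(d)))
  dm <- d_max * (1 + 1e-12)
  pmax(0, 1 - (d / dm)^2)
}

#' ABC scenario choice by rejection and multinomial logistic regression
#'
#' Summary statistics are standardized by a per-column robust scale
#' (median absolute deviation); the simulations nearest the observed
#' vector in Euclidean distance are retained. The direct (rejection)
#' posterior is the scenario frequency among retained rows; the logistic
#' posterior comes from a multinomial logistic regression of scenario id
#' on the standardized statistics of the retained rows (Epanechnikov
#' distance weights), evaluated at the observed vector.
#'
#' @param observed named numeric vector of summary statistics (see
#'   [abc_stat_names()])
#' @param table a reference table from [build_reference_table()]
#' @param tolerance fraction of simulations retained (default 0.01)
#' @return list of class `abc_model_choice`: `direct` and `logistic`
#'   posterior probability vectors over scenarios, `best` (scenario id by
#'   logistic posterior), `retained` (row indices), `n_retained`
#' @export
abc_model_choice <- function(observed, table, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  sn <- abc_stat_names()
  stat_mat <- as.matrix(table[, sn])
  obs <- unlist(observed)[sn]
  dd <- abc_distances(obs, stat_mat)
  n_keep <- max(1L, ceiling(tolerance * nrow(table)))
  keep <- order(dd$d)[seq_len(n_keep)]

  scen_all <- sort(unique(table$scenario))
  scen_keep <- factor(table$scenario[keep], levels = scen_all)
  direct <- as.numeric(table(scen_keep)) / n_keep
  names(direct) <- scen_all

  logistic <- direct
  if (length(unique(table$scenario[keep])) >= 2) {
    df <- as.data.frame(dd$Z[keep, , drop = FALSE])
    df$scenario <- droplevels(scen_keep)
    w <- epanechnikov_weights(dd$d[keep], max(dd$d[keep]))
    if (any(w > 0)) w[w <= 0] <- min(w[w > 0]) / 2 else w[] <- 1
    fit <- nnet::multinom(scenario ~ ., data = df, weights = w,
                          trace = FALSE, maxit = 500)
    newd <- as.data.frame(t(dd$z_obs))
    pr <- predict(fit, newdata = newd, type = "probs")
    pr_full <- setNames(numeric(length(scen_all)), scen_all)
    if (length(pr) == 1) { # two-class fit returns P(second level)
      lv <- levels(df$scenario)
      pr_full[lv[1]] <- 1 - pr
      pr_full[lv[2]] <- pr
    } else {
      pr_full[names(pr)] <- pr
    }
    logistic <- pr_full / sum(pr_full)
  }
  structure(list(direct = direct, logistic = logistic,
                 best = as.integer(names(which.max(logistic))),
                 retained = keep, n_retained = n_keep),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (", x$n_retained, " retained)\n", sep = "")
  m <- rbind(direct = round(x$direct, 4), logistic = round(x$logistic, 4))
  print(m)
  cat("best scenario:", x$best, "\n")
  invisible(x)
}

# weighted quantiles of a sample (type-4-style interpolation on the
# cumulative weight)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}

#' ABC parameter estimation with local-linear regression adjustment
#'
#' Retains the simulations of the chosen scenario closest to the observed
#' statistics, maps each parameter to (0, 1) by its prior bounds and
#' logit-transforms it, adjusts the retained draws by a weighted
#' local-linear regression on the standardized statistics (Epanechnikov
#' weights in distance), and back-transforms. Point estimates are weighted
#' posterior medians with 2.5/97.5 percentile intervals; the logit
#' back-transform keeps every adjusted draw inside its prior bounds.
#'
#' @param observed named numeric summary-statistic vector
#' @param table reference table from [build_reference_table()]
#' @param scenario_id the scenario whose rows are used
#' @param retain_fraction fraction of the full table's rows retained
#'   (default 0.01), taken as the nearest rows within the scenario
#' @param priors prior set giving the parameter bounds
#' @return list of class `abc_param_estimate`: `summary` data frame
#'   (parameter, median, q2.5, q97.5), `adjusted` draw matrix, `weights`,
#'   `adjusted_ok` (FALSE if the regression was singular and the
#'   unadjusted rejection sample was used)
#' @export
abc_estimate_params <- function(observed, table, scenario_id,
                                retain_fraction = 0.01,
                                priors = default_priors()) {
  sub <- table[table$scenario == scenario_id, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for scenario ", scenario_id)
  sn <- abc_stat_names()
  obs <- unlist(observed)[sn]
  dd <- abc_distances(obs, as.matrix(sub[, sn]))
  n_keep <- max(1L, min(nrow(sub), ceiling(retain_fraction * nrow(table))))
  keep <- order(dd$d)[seq_len(n_keep)]
  w <- epanechnikov_weights(dd$d[keep], max(dd$d[keep]))
  if (any(w > 0)) w[w <= 0] <- min(w[w > 0]) / 2 else w[] <- 1

  par_names <- c("N1", "N2", "N3", "Na", "Nc", "t1", "t2")
  if (scenario_id %in% 3:4) par_names <- c(par_names, "ra")

  X <- sweep(dd$Z[keep, , drop = FALSE], 2, dd$z_obs, "-")
  eps <- 1e-8
  adjusted <- matrix(NA_real_, n_keep, length(par_names),
                     dimnames = list(NULL, par_names))
  adjusted_ok <- TRUE
  for (pn in par_names) {
    a <- priors[[pn]]$min; b <- priors[[pn]]$max
    u <- pmin(1 - eps, pmax(eps, (sub[[pn]][keep] - a) / (b - a)))
    y <- log(u / (1 - u))
    fit <- if (n_keep > ncol(X) + 1)
      tryCatch(lm.wfit(cbind(1, X), y, w), error = function(e) NULL)
    else NULL
    if (is.null(fit) || anyNA(fit$coefficients)) {
      if (n_keep > 1) adjusted_ok <- FALSE
      y_adj <- y
    } else {
      y_adj <- y - X %*% fit$coefficients[-1]
    }
    u_adj <- 1 / (1 + exp(-y_adj))
    adjusted[, pn] <- a + u_adj * (b - a)
  }
  summ <- data.frame(
    parameter = par_names,
    median = vapply(par_names, function(pn)
      weighted_quantile(adjusted[, pn], w, 0.5), numeric(1)),
    q2.5 = vapply(par_names, function(pn)
      weighted_quantile(adjusted[, pn], w, 0.025), numeric(1)),
    q97.5 = vapply(par_names, function(pn)
      weighted_quantile(adjusted[, pn], w, 0.975), numeric(1)),
    row.names = NULL)
  structure(list(summary = summ, adjusted = adjusted, weights = w,
                 retained = keep, adjusted_ok = adjusted_ok),
            class = "abc_param_estimate")
}

#' @export
print.abc_param_estimate <- function(x, ...) {
  cat("ABC parameter estimates (", nrow(x$adjusted), " retained draws",
      if (!x$adjusted_ok) "; regression fallback: unadjusted" else "",
      ")\n", sep = "")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(z) signif(z, 4))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Posterior predictive (misclassification) error of scenario choice
#'
#' Holds out reference-table rows one at a time as pseudo-observed
#' datasets, classifies each against the remaining rows with
#' [abc_model_choice()], and reports the fraction assigned to a scenario
#' other than the one that generated them.
#'
#' @param table reference table
#' @param n_pseudo number of held-out pseudo-observed rows (default 100)
#' @param tolerance retention fraction for each classification
#' @param use `"logistic"` (default) or `"direct"` posterior for the call
#' @return list: `error` (misclassification rate in \[0, 1\]), `n_pseudo`,
#'   `calls` data frame (true scenario, chosen scenario)
#' @export
posterior_predictive_error <- function(table, n_pseudo = 100,
                                       tolerance = 0.01,
                                       use = c("logistic", "direct")) {
  use <- match.arg(use)
  n_pseudo <- min(n_pseudo, nrow(table))
  idx <- sample(nrow(table), n_pseudo)
  truth <- integer(n_pseudo); call <- integer(n_pseudo)
  sn <- abc_stat_names()
  for (i in seq_len(n_pseudo)) {
    r <- idx[i]
    mc <- abc_model_choice(unlist(table[r, sn]), table[-r, , drop = FALSE],
                           tolerance = tolerance)
    post <- if (use == "logistic") mc$logistic else mc$direct
    truth[i] <- table$scenario[r]
    call[i] <- as.integer(names(which.max(post)))
  }
  list(error = mean(call != truth), n_pseudo = n_pseudo,
       calls = data.frame(true = truth, chosen = call))
}
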