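#' Prior set for the four divergence scenarios
#'
#' Parameters of the three-lineage divergence model (sizes in diploid
#' individuals, times in generations): `N1` (Dson), `N2` (Dvov-S), `N3`
#' (Dvov-N) current sizes, `Na`/`Nc` ancestral sizes of the Dson and Dvov
#' branches, split times `t1 <= t2`, and (scenarios 3-4 only) the admixture
#' proportion `ra`. Defaults: `N1` and `N3` have normal priors (means
#' 36,997 and 49,416, sd 10,000) truncated to `[10, 100000]`; `Na`, `Nc`
#' uniform on `[10, 100000]`; `N2`, `t1`, `t2` uniform on `[10, 50000]`;
#' `ra` uniform on `[0.001, 0.999]`. Draws must satisfy `N1 > N2`,
#' `N2 < N3`, `t2 >= t1`, `Na <= N1`, `Nc <= N3`.
#'
#' @return list of per-parameter prior specifications (each with `dist`,
#'   bounds and, for normals, `mean` and `sd`)
#' @export
default_priors <- function() {
  list(
    N1 = list(dist = "norm", mean = 36997, sd = 10000, min = 10, max = 1e5),
    N2 = list(dist = "unif", min = 10, max = 5e4),
    N3 = list(dist = "norm", mean = 49416, sd = 10000, min = 10, max = 1e5),
    Na = list(dist = "unif", min = 10, max = 1e5),
    Nc = list(dist = "unif", min = 10, max = 1e5),
    t1 = list(dist = "unif", min = 10, max = 5e4),
    t2 = list(dist = "unif", min = 10, max = 5e4),
    ra = list(dist = "unif", min = 0.001, max = 0.999))
}

#' Published-scale point values for the supported divergence scenario
#'
#' A reference parameter set for scenario 2 (ancestral Dvov lineage of size
#' `Nc` giving rise to the Dson branch `t2` generations ago, and to the
#' Dvov-S / Dvov-N split `t1` generations ago), used as the generative
#' truth in the package's recovery experiments. `N1` is set to the prior
#' mean, the remaining values to the posterior point estimates of the study
#' system this package models.
#'
#' @return named numeric vector with `N1, N2, N3, Na, Nc, t1, t2`
#' @export
default_scenario2_params <- function() {
  c(N1 = 36997, N2 = 1340, N3 = 61100, Na = 37100, Nc = 8820,
    t1 = 6930, t2 = 8290)
}

prior_draw_one <- function(sp, n) {
  if (sp$dist == "unif") {
    runif(n, sp$min, sp$max)
  } else {
    x <- rnorm(n, sp$mean, sp$sd)
    while (any(bad <- x < sp$min | x > sp$max))
      x[bad] <- rnorm(sum(bad), sp$mean, sp$sd)
    x
  }
}

constraints_ok <- function(d) {
  d$N1 > d$N2 & d$N2 < d$N3 & d$t2 >= d$t1 & d$Na <= d$N1 & d$Nc <= d$N3
}

#' Draw parameter vectors from the prior, honouring the constraints
#'
#' Rejection sampling: draws are redrawn until `N1 > N2 < N3`,
#' `t2 >= t1`, `Na <= N1` and `Nc <= N3` all hold. For scenarios 1-2 the
#' admixture proportion `ra` is reported as `NA`.
#'
#' @param priors a prior set as from [default_priors()]
#' @param scenario_id scenario (1-4)
#' @param n number of draws
#' @param max_attempts bound on the rejection loop
#' @return data frame of accepted draws with columns
#'   `N1, N2, N3, Na, Nc, t1, t2, ra`
#' @export
draw_priors <- function(priors = default_priors(), scenario_id = 1, n = 1,
                        max_attempts = 1e6) {
  stopifnot(scenario_id %in% 1:4, n >= 1)
  out <- NULL
  attempts <- 0
  while (is.null(out) || nrow(out) < n) {
    m <- max(n, 2 * (n - if (is.null(out)) 0 else nrow(out)))
    attempts <- attempts + m
    if (attempts > max_attempts)
      stop("prior constraints appear unsatisfiable (", max_attempts,
           " attempts)")
    d <- data.frame(lapply(priors[c("N1", "N2", "N3", "Na", "Nc",
                                    "t1", "t2", "ra")],
                           prior_draw_one, n = m))
    d <- d[constraints_ok(d), , drop = FALSE]
    out <- rbind(out, d)
  }
  out <- out[seq_len(n), , drop = FALSE]
  if (scenario_id %in% 1:2) out$ra <- NA_real_
  rownames(out) <- NULL
  out
}

# backward-in-time deme/event specification for the Rcpp simulator.
# demes (0-based): 0 = Dson (N1), 1 = Dvov-S (N2), 2 = Dvov-N (N3).
scenario_events <- function(scenario_id, params) {
  p <- as.list(params)
  ev <- list()
  add <- function(time, type, from, to = 0L, to2 = 0L, prob = 1,
                  newsize = 0) {
    ev[[length(ev) + 1]] <<- list(time = time, type = type, from = from,
                                  to = to, to2 = to2, prob = prob,
                                  newsize = newsize)
  }
  # at t1: Dvov-S lineages join the Dvov ancestor (scenarios 1-2) or are
  # routed to the Dson branch with probability ra (scenarios 3-4); the two
  # persisting branches switch to their ancestral sizes Na, Nc
  if (scenario_id %in% 1:2) {
    add(p$t1, 0L, 1L, to = 2L)
  } else {
    add(p$t1, 0L, 1L, to = 0L, to2 = 2L, prob = p$ra)
  }
  add(p$t1, 1L, 0L, newsize = p$Na)
  add(p$t1, 1L, 2L, newsize = p$Nc)
  # at t2: the remaining branches merge; root size Na (1, 3) or Nc (2, 4)
  if (scenario_id %in% c(1, 3)) {
    add(p$t2, 0L, 2L, to = 0L)
  } else {
    add(p$t2, 0L, 0L, to = 2L)
  }
  do.call(rbind.data.frame, ev)
}

#' Convert a mutation-scaled population size to an effective size
#'
#' `Ne = Theta / (4 * mu * gen_time)`, with `mu` in substitutions per site
#' per year and `gen_time` in years per generation (so `mu * gen_time` is
#' the per-generation rate).
#'
#' @param theta mutation-scaled population size
#' @param mu substitution rate per site per year (default 6.70325e-10, a
#'   cycad estimate)
#' @param gen_time generation time in years (default 100)
#' @return effective population size (diploid individuals)
#' @export
theta_to_ne <- function(theta, mu = 6.70325e-10, gen_time = 100) {
  stopifnot(all(theta > 0), mu > 0, gen_time > 0)
  theta / (4 * mu * gen_time)
}

#' Convert generations to thousands of years
#'
#' @param t_generations time in generations (>= 0)
#' @param gen_time generation time in years (default 100)
#' @return time in thousands of years (ky)
#' @export
generations_to_ky <- function(t_generations, gen_time = 100) {
  stopifnot(all(t_generations >= 0), gen_time > 0)
  t_generations * gen_time / 1000
}
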