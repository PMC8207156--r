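#' Phi(outlier) / Phi(neutral) selection-regime ratio scan
#'
#' For nested groups of populations along a gradient, computes the ratio of
#' outlier-locus to neutral-locus Phi for every unordered population pair
#' within each group, and tests the mean ratio against 1 with a one-sample
#' t test (two-sided by default). A mean ratio significantly above 1
#' indicates diversifying selection, below 1 balancing selection, and a
#' ratio compatible with 1 is consistent with drift. Pairs with zero
#' neutral Phi are excluded (and counted); groups yielding fewer than two
#' usable pairs report verdict `"untested"` and no t test.
#'
#' @param phi_out `phi_matrix` computed on outlier loci (see
#'   [pairwise_phi()])
#' @param phi_neu `phi_matrix` computed on neutral loci, same population
#'   ordering
#' @param groups named list of character vectors of population names
#' @param alternative passed to [stats::t.test()] (default `"two.sided"`)
#' @return data frame with one row per group: `group`, `n_pops`, `n_pairs`,
#'   `n_excluded`, `mean_ratio`, `sd_ratio`, `t`, `p`, `verdict`
#' @export
phi_ratio_scan <- function(phi_out, phi_neu, groups,
                           alternative = "two.sided") {
  PO <- if (inherits(phi_out, "phi_matrix")) phi_out$phi else as.matrix(phi_out)
  PN <- if (inherits(phi_neu, "phi_matrix")) phi_neu$phi else as.matrix(phi_neu)
  if (!identical(dim(PO), dim(PN)) ||
      !identical(rownames(PO), rownames(PN)))
    stop("the two Phi matrices must share dimensions and population order")

  rows <- lapply(names(groups), function(gname) {
    pops <- sort(unique(groups[[gname]]))
    missing <- setdiff(pops, rownames(PO))
    if (length(missing))
      stop("group '", gname, "' names unknown populations: ",
           paste(missing, collapse = ", "))
    prs <- if (length(pops) >= 2) combn(pops, 2) else
      matrix(character(0), nrow = 2)
    ratios <- numeric(0)
    n_excl <- 0L
    if (ncol(prs)) {
      num <- PO[cbind(prs[1, ], prs[2, ])]
      den <- PN[cbind(prs[1, ], prs[2, ])]
      usable <- den > 0
      n_excl <- sum(!usable)
      ratios <- num[usable] / den[usable]
    }
    n_pairs <- length(ratios)
    tt <- pp <- NA_real_
    if (n_pairs >= 2 && sd(ratios) > 0) {
      ht <- t.test(ratios, mu = 1, alternative = alternative)
      tt <- unname(ht$statistic)
      pp <- ht$p.value
    }
    m <- if (n_pairs) mean(ratios) else NA_real_
    verdict <- if (n_pairs < 2) {
      "untested"
    } else if (n_pairs >= 2 && sd(ratios) == 0) {
      "untested-variance"
    } else if (!is.na(pp) && pp < 0.05) {
      if (m > 1) "diversifying" else "balancing"
    } else "drift"
    data.frame(group = gname, n_pops = length(pops),
               n_pairs = n_pairs, n_excluded = n_excl,
               mean_ratio = m,
               sd_ratio = if (n_pairs >= 2) sd(ratios) else NA_real_,
               t = tt, p = pp, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
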