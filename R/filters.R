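#' Hardy-Weinberg chi-square test from dosage counts
#'
#' One-degree-of-freedom chi-square (no continuity correction) comparing
#' observed genotype counts at a biallelic locus with the Hardy-Weinberg
#' expectation computed from that sample's allele frequency.
#'
#' @param n0,n1,n2 counts of individuals with dosage 0, 1 and 2
#' @return list with `chisq`, `p` and the allele frequency `p_alt`;
#'   monomorphic samples give `chisq = 0`, `p = 1`
#' @export
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) return(list(chisq = NA_real_, p = NA_real_, p_alt = NA_real_))
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  if (p <= 0 || p >= 1) return(list(chisq = 0, p = 1, p_alt = p))
  exp_cnt <- n * c(q^2, 2 * p * q, p^2)
  obs <- c(n0, n1, n2)
  chisq <- sum((obs - exp_cnt)^2 / exp_cnt)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       p_alt = p)
}

#' Filter a genotype matrix by call rate, MAF and within-population HWE
#'
#' Loci are removed in three sequential screens: (1) call rate below
#' `locus_presence_min`; (2) pooled minor allele frequency below `maf_min`;
#' (3) a significant Hardy-Weinberg departure (chi-square, 1 df) within any
#' single population at level `hwe_alpha`. A population with fewer than two
#' typed individuals at a locus is skipped for that locus's HWE screen
#' rather than failed.
#'
#' @param g a [genotype_matrix()]
#' @param maf_min minimum pooled minor-allele frequency (default 0.05)
#' @param locus_presence_min minimum fraction of individuals typed
#'   (default 0.9)
#' @param hwe_alpha significance level of the HWE screen (default 0.05)
#' @return list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report`, a data frame counting input loci,
#'   removals per rule (in screen order) and retained loci
#' @export
apply_filters <- function(g, maf_min = 0.05, locus_presence_min = 0.9,
                          hwe_alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$geno) == 0) stop("empty genotype matrix")
  stopifnot(maf_min > 0, maf_min < 1,
            locus_presence_min > 0, locus_presence_min < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  geno <- g$geno
  n_in <- ncol(geno)

  call_rate <- colMeans(!is.na(geno))
  keep1 <- call_rate >= locus_presence_min
  n_presence <- sum(!keep1)
  geno <- geno[, keep1, drop = FALSE]

  p_pool <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p_pool, 1 - p_pool)
  keep2 <- !is.na(maf) & maf >= maf_min
  n_maf <- sum(!keep2)
  geno <- geno[, keep2, drop = FALSE]

  pops <- levels(g$population)
  fails_hwe <- logical(ncol(geno))
  for (pp in pops) {
    sub <- geno[g$population == pp, , drop = FALSE]
    for (l in which(!fails_hwe)) {
      x <- sub[, l]
      x <- x[!is.na(x)]
      if (length(x) < 2) next
      h <- hwe_chisq(sum(x == 0), sum(x == 1), sum(x == 2))
      if (!is.na(h$p) && h$p < hwe_alpha) fails_hwe[l] <- TRUE
    }
  }
  n_hwe <- sum(fails_hwe)
  geno <- geno[, !fails_hwe, drop = FALSE]

  out <- g
  out$geno <- geno
  report <- data.frame(
    n_input = n_in,
    removed_presence = n_presence,
    removed_maf = n_maf,
    removed_hwe = n_hwe,
    n_retained = ncol(geno))
  list(genotypes = out, report = report)
}
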