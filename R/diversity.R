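#' Alternate-allele frequencies per group
#'
#' @param g a [genotype_matrix()]
#' @param grouping `"population"`, `"lineage"` or `"species"`
#' @return numeric matrix, groups x loci, of alternate-allele frequencies
#'   (`NaN` where a group has no typed individual at a locus)
#' @export
allele_freq_by_group <- function(g, grouping = "population") {
  fac <- group_factor(g, grouping)
  f <- vapply(levels(fac), function(lv) {
    colMeans(g$geno[fac == lv, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(g$geno)))
  out <- matrix(f, nrow = ncol(g$geno),
                dimnames = list(colnames(g$geno), levels(fac)))
  t(out)
}

#' Per-group diversity statistics
#'
#' For each group and biallelic locus with allele frequencies `p`, `q`:
#' expected heterozygosity `He = 2pq`, effective allele number
#' `Ae = 1/(p^2 + q^2)`, Shannon information `I = -(p ln p + q ln q)` (in
#' nats), and observed heterozygosity `Ho` as the fraction of heterozygotes
#' among typed individuals. Per-locus values are averaged over the loci
#' typed in the group; the inbreeding coefficient is
#' `F = (He - Ho) / He` on the averaged values (`NaN` when `He = 0`).
#'
#' @param g a [genotype_matrix()]
#' @param grouping `"population"`, `"lineage"` or `"species"`
#' @return data frame with one row per group: `group`, `n_typed` (mean
#'   individuals typed per locus), `Ae`, `Ho`, `He`, `F`, `I_shannon`
#' @export
diversity <- function(g, grouping = "population") {
  fac <- group_factor(g, grouping)
  rows <- lapply(levels(fac), function(lv) {
    sub <- g$geno[fac == lv, , drop = FALSE]
    typed <- colSums(!is.na(sub))
    use <- typed > 0
    sub <- sub[, use, drop = FALSE]
    typed <- typed[use]
    p <- colMeans(sub, na.rm = TRUE) / 2
    q <- 1 - p
    he <- 2 * p * q
    ae <- 1 / (p^2 + q^2)
    sh <- ifelse(p > 0 & p < 1, -(p * log(p) + q * log(q)), 0)
    ho <- colSums(sub == 1, na.rm = TRUE) / typed
    He <- mean(he); Ho <- mean(ho)
    data.frame(group = lv,
               n_typed = mean(typed),
               Ae = mean(ae),
               Ho = Ho,
               He = He,
               F = if (He > 0) (He - Ho) / He else NaN,
               I_shannon = mean(sh),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-locus differentiation statistics
#'
#' Wright's Fst per locus from group allele frequencies: `Hs` is the
#' unweighted mean within-group expected heterozygosity, `Ht` the expected
#' heterozygosity of the unweighted mean allele frequency, and
#' `Fst = (Ht - Hs) / Ht`, clamped to `[0, 1]`. Loci monomorphic over all
#' groups get `Fst = 0` by convention.
#'
#' @param g a [genotype_matrix()]
#' @param grouping `"population"`, `"lineage"` or `"species"`
#' @return list with `locus` names, the `p_by_group` frequency matrix, and
#'   per-locus vectors `Hs`, `Ht`, `Fst`
#' @export
per_locus_stats <- function(g, grouping = "population") {
  p <- allele_freq_by_group(g, grouping)
  if (nrow(p) < 2) stop("need at least 2 groups")
  hs <- colMeans(2 * p * (1 - p), na.rm = TRUE)
  pbar <- colMeans(p, na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  fst <- ifelse(ht > 0, pmin(1, pmax(0, (ht - hs) / ht)), 0)
  list(locus = colnames(g$geno), p_by_group = p,
       Hs = unname(hs), Ht = unname(ht), Fst = unname(fst))
}

#' Nei's (1972) standard genetic distance between groups
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))` with the gene-identity terms `J` averaged
#' over loci. For biallelic loci `Jx = p_x^2 + q_x^2` and
#' `Jxy = p_x p_y + q_x q_y`. A zero between-group identity gives an
#' infinite distance, which is replaced by the sentinel
#' [NEI_D_SENTINEL] so downstream summary vectors stay finite.
#'
#' @param freqs numeric matrix, groups x loci, of alternate-allele
#'   frequencies on a shared locus set
#' @param sentinel value substituted for an infinite distance
#' @return symmetric groups x groups distance matrix with zero diagonal
#' @export
nei_distance <- function(freqs, sentinel = NEI_D_SENTINEL) {
  freqs <- as.matrix(freqs)
  ng <- nrow(freqs)
  if (is.null(rownames(freqs))) rownames(freqs) <- paste0("g", seq_len(ng))
  D <- matrix(0, ng, ng, dimnames = list(rownames(freqs), rownames(freqs)))
  J <- function(px, py) mean(px * py + (1 - px) * (1 - py), na.rm = TRUE)
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    jx <- J(freqs[i, ], freqs[i, ])
    jy <- J(freqs[j, ], freqs[j, ])
    jxy <- J(freqs[i, ], freqs[j, ])
    d <- if (jxy <= 0) Inf else -log(jxy / sqrt(jx * jy))
    if (!is.finite(d)) d <- sentinel
    D[i, j] <- D[j, i] <- max(0, d)
  }
  D
}
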