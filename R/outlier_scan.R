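#' Fst-heterozygosity confidence-envelope outlier scan
#'
#' Partitions loci into neutral and outlier sets by comparing each locus's
#' Fst with smoothed empirical quantile bounds conditional on its total
#' heterozygosity (Ht). Loci are binned by Ht into `n_bins` equal-count
#' bins (merged forward until each holds at least `min_per_bin` loci);
#' within each bin the `(1 - ci)/2` and `1 - (1 - ci)/2` empirical Fst
#' quantiles are computed and connected by linear interpolation against the
#' bin-median Ht, forming lower and upper envelope bounds. Loci above the
#' upper bound are flagged `outlier_high`, below the lower bound
#' `outlier_low`, otherwise `neutral`.
#'
#' @param stats per-locus statistics from [per_locus_stats()]
#' @param ci envelope confidence level (default 0.95)
#' @param n_bins number of Ht bins; default `ceiling(n_loci / 50)` capped
#'   at 20
#' @param min_per_bin minimum loci per bin after forward merging
#'   (default 20)
#' @return list of class `locus_partition`: data frame `loci` (locus, Ht,
#'   Fst, lower, upper, flag), data frame `envelope` (bin-median Ht and
#'   quantile nodes), and `ci`
#' @export
fst_het_envelope <- function(stats, ci = 0.95, n_bins = NULL,
                             min_per_bin = 20) {
  stopifnot(ci > 0, ci < 1)
  ht <- stats$Ht
  fst <- stats$Fst
  n <- length(ht)
  if (is.null(n_bins)) n_bins <- min(20L, max(1L, ceiling(n / 50)))
  if (n < min_per_bin) {
    warning("fewer loci than min_per_bin; using a single bin")
    n_bins <- 1L
  }

  ord <- order(ht)
  # equal-count bins on the Ht order, merged forward to >= min_per_bin
  raw_bin <- ceiling(seq_along(ord) / (n / n_bins))
  raw_bin[raw_bin > n_bins] <- n_bins
  merged <- integer(length(ord))
  cur <- 1L; count <- 0L; i_raw <- raw_bin[1]
  for (k in seq_along(ord)) {
    if (raw_bin[k] != i_raw && count >= min_per_bin) {
      cur <- cur + 1L; count <- 0L
    }
    i_raw <- raw_bin[k]
    merged[k] <- cur
    count <- count + 1L
  }
  # if last bin is undersized, fold it into the previous one
  if (max(merged) > 1 && sum(merged == max(merged)) < min_per_bin)
    merged[merged == max(merged)] <- max(merged) - 1L

  bin_of <- integer(n)
  bin_of[ord] <- merged
  alpha <- (1 - ci) / 2
  env <- do.call(rbind, lapply(sort(unique(merged)), function(b) {
    sel <- bin_of == b
    data.frame(bin = b,
               ht_median = median(ht[sel]),
               # Weibull plotting positions (type 6): calibrated so the
               # in-bin exceedance fraction tracks the nominal 1 - ci
               lower = quantile(fst[sel], alpha, names = FALSE, type = 6),
               upper = quantile(fst[sel], 1 - alpha, names = FALSE, type = 6))
  }))

  if (nrow(env) >= 2) {
    lo <- approx(env$ht_median, env$lower, xout = ht, rule = 2)$y
    hi <- approx(env$ht_median, env$upper, xout = ht, rule = 2)$y
  } else {
    lo <- rep(env$lower, n)
    hi <- rep(env$upper, n)
  }
  flag <- ifelse(fst > hi, "outlier_high",
                 ifelse(fst < lo, "outlier_low", "neutral"))
  loci <- data.frame(locus = stats$locus, Ht = ht, Fst = fst,
                     lower = lo, upper = hi, flag = flag,
                     stringsAsFactors = FALSE)
  structure(list(loci = loci, envelope = env, ci = ci),
            class = "locus_partition")
}

#' @export
print.locus_partition <- function(x, ...) {
  tab <- table(factor(x$loci$flag,
                      levels = c("neutral", "outlier_low", "outlier_high")))
  cat("locus partition (ci = ", x$ci, "): ", sep = "")
  cat(paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Split a genotype matrix into total / neutral / outlier datasets
#'
#' @param g a [genotype_matrix()]
#' @param partition a `locus_partition` from [fst_het_envelope()] covering
#'   exactly the loci of `g`, or a character vector of outlier locus names
#' @return list with `all`, `neutral` and `outlier` genotype matrices
#'   (column subsets sharing labels)
#' @export
partition_datasets <- function(g, partition) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (inherits(partition, "locus_partition")) {
    if (!identical(partition$loci$locus, colnames(g$geno)))
      stop("partition does not cover the loci of g")
    is_out <- partition$loci$flag != "neutral"
  } else {
    is_out <- colnames(g$geno) %in% partition
  }
  list(all = g,
       neutral = subset_loci(g, !is_out),
       outlier = subset_loci(g, is_out))
}

#' Combine envelope flags with an external outlier list
#'
#' Mirrors two-method outlier designs where the envelope scan is combined
#' with a second detection method: keeps a locus flagged only if both
#' methods agree (`"intersection"`) or if either flags it (`"union"`).
#'
#' @param partition a `locus_partition` from [fst_het_envelope()]
#' @param external character vector of locus names flagged by the second
#'   method
#' @param rule `"intersection"` or `"union"`
#' @return the partition with updated flags (loci demoted to `"neutral"`
#'   or promoted to `"outlier_high"` as the rule dictates)
#' @export
combine_flags <- function(partition, external,
                          rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  stopifnot(inherits(partition, "locus_partition"))
  df <- partition$loci
  env_out <- df$flag != "neutral"
  ext_out <- df$locus %in% external
  keep <- if (rule == "intersection") env_out & ext_out else env_out | ext_out
  df$flag[env_out & !keep] <- "neutral"
  df$flag[!env_out & keep] <- "outlier_high"
  partition$loci <- df
  partition
}
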