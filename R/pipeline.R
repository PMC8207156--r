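#' Run the full gradient-divergence pipeline on synthetic data
#'
#' End-to-end driver binding the stages together: generate a synthetic
#' dataset, filter loci, compute per-locus statistics, partition loci by
#' the Fst-heterozygosity envelope, compute neutral and outlier Phi
#' matrices, run the selection-regime ratio scan over nested latitudinal
#' groups, run a (small) ABC scenario choice, rank distance-matrix models
#' and perform the niche background test. Sizes default to a fast
#' smoke-test scale; every stage is reproducible from `seed`.
#'
#' @param seed integer random seed
#' @param cfg synthetic configuration (default [synthetic_config()])
#' @param n_perm permutations for Phi matrices (default 0, no tests)
#' @param abc_n_sims reference-table size (default 400)
#' @param abc_n_loci loci per ABC simulation (default 60)
#' @param niche_reps background-test replicates (default 20)
#' @param out_dir optional directory; when given, writes the STRUCTURE
#'   file, CSV tables and JSON manifest there
#' @return list with the results of every stage
#' @export
run_pipeline <- function(seed = 1, cfg = synthetic_config(), n_perm = 0,
                         abc_n_sims = 400, abc_n_loci = 60,
                         niche_reps = 20, out_dir = NULL) {
  set.seed(seed)
  data <- generate_dataset(cfg)
  g <- data$genotypes

  filt <- apply_filters(g)
  gf <- filt$genotypes

  stats <- per_locus_stats(gf)
  part <- fst_het_envelope(stats)
  sets <- partition_datasets(gf, part)

  phi_neu <- pairwise_phi(sets$neutral, n_perm = n_perm,
                          loci_used = "neutral")
  phi_out <- pairwise_phi(sets$outlier, n_perm = n_perm,
                          loci_used = "outlier")

  pops <- levels(g$population)
  lin <- setNames(g$pop_meta$lineage, g$pop_meta$population)[pops]
  groups <- list(
    Dson = pops[lin == "Dson"],
    "Dson+Dvov-S" = pops[lin %in% c("Dson", "Dvov-S")],
    "Dvov-S+Dvov-N" = pops[lin %in% c("Dvov-S", "Dvov-N")],
    "Dvov-N" = pops[lin == "Dvov-N"])
  scan <- phi_ratio_scan(phi_out, phi_neu, groups)

  obs_stats <- lineage_summary_stats(sets$neutral)
  table <- build_reference_table(abc_n_sims, n_loci = abc_n_loci)
  mc <- abc_model_choice(obs_stats, table, tolerance = 0.05)

  dms <- build_distances(data$coords, data$env,
                         list(phi_neutral = phi_neu, phi_outlier = phi_out))
  ranking <- rank_models(dms, "phi_neutral")

  env <- generate_env_layers(cfg)
  niche <- background_test(env$occ_x, env$occ_y, env$layers,
                           n_reps = niche_reps)

  res <- list(data = data, filter = filt$report, partition = part,
              phi = list(neutral = phi_neu, outlier = phi_out),
              ratio_scan = scan, abc = mc, model_ranking = ranking,
              niche = niche, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_structure(g, file.path(out_dir, "genotypes.stru"))
    write.csv(data$coords, file.path(out_dir, "coords.csv"),
              row.names = FALSE)
    write.csv(data$env, file.path(out_dir, "env.csv"), row.names = FALSE)
    write.csv(part$loci, file.path(out_dir, "locus_partition.csv"),
              row.names = FALSE)
    write.csv(scan, file.path(out_dir, "ratio_scan.csv"), row.names = FALSE)
    write.csv(ranking, file.path(out_dir, "model_ranking.csv"),
              row.names = FALSE)
    manifest <- list(seed = seed,
                     n_loci_input = filt$report$n_input,
                     n_loci_retained = filt$report$n_retained,
                     n_outliers = sum(part$loci$flag != "neutral"),
                     abc_best_scenario = mc$best,
                     niche_verdict = as.list(niche$verdict))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Write a diversity table or AMOVA result to CSV and JSON
#'
#' @param x a data frame, `amova_result` or other list-like result
#' @param path_csv,path_json output paths (either may be `NULL`)
#' @return invisibly, `x`
#' @export
write_result <- function(x, path_csv = NULL, path_json = NULL) {
  flat <- if (inherits(x, "amova_result")) x$components else as.data.frame(x)
  if (!is.null(path_csv)) write.csv(flat, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    obj <- if (inherits(x, "amova_result"))
      list(components = x$components, phi = as.list(x$phi),
           p = as.list(x$p), n_perm = x$n_perm)
    else x
    jsonlite::write_json(obj, path_json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(x)
}
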