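# One-command reproduction harness: simulate -> align -> extract ->
# screen -> classify, with provenance manifest and deterministic outputs.

#' Pipeline configuration
#'
#' Bundles the module configurations and one root seed from which all
#' stage seeds are derived (simulation, label shuffles, CV folds), so
#' rerunning with the same configuration reproduces identical outputs.
#'
#' @param seed root seed.
#' @param sim a [sim_config()] (its own seed is overridden by `seed`).
#' @param screen a [screen_config()].
#' @param lasso a [lasso_config()] (seed overridden likewise).
#' @param stages stages to classify (subset of 4, 8, 15, 28).
#' @param screen_groups the two groups compared by the feature screen.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            screen = screen_config(),
                            lasso = lasso_config(),
                            stages = c(4, 8, 15, 28),
                            screen_groups = c("equalized_dead",
                                              "equalized_alive")) {
  sim$seed <- derive_seed(seed, "simulate")
  lasso$seed <- derive_seed(seed, "lasso")
  structure(list(seed = as.integer(seed), sim = sim, screen = screen,
                 lasso = lasso, stages = stages,
                 screen_groups = screen_groups),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates the cohort, builds the control reference model, extracts
#' per-stage feature tables, screens dead-vs-alive equalized embryos
#' with the permutation-calibrated FDR procedure, fits the repeated-CV
#' Lasso per stage, and (optionally) writes versioned outputs plus a
#' provenance manifest into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` to skip writing files.
#' @return (invisibly, when writing) `out_dir`; always returns the full
#'   in-memory result list with components `cohort`, `reference`,
#'   `features` (per stage), `screen`, `classify` (per stage) and
#'   `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  cohort <- simulate_cohort(config$sim)
  timings["simulate"] <- lap(t0)

  t0 <- tic()
  controls <- cohort$embryos[cohort$metadata$group == "control"]
  reference <- build_reference(controls)
  timings["reference"] <- lap(t0)

  t0 <- tic()
  alignments <- lapply(cohort$embryos, function(e)
    tryCatch(suppressWarnings(temporal_align(e, reference$curve)),
             error = function(err) NULL))
  ft_all <- feature_table(cohort$embryos, reference, stage = "all",
                          alignments = alignments)
  meta_cols <- c("embryo_id", "group", "outcome")
  features <- lapply(stats::setNames(config$stages,
                                     paste0("stage", config$stages)),
                     function(s) {
                       cols <- as.vector(t(outer(.stage_cells(s),
                                                 .feature_names,
                                                 paste, sep = ".")))
                       ft_all[, c(meta_cols,
                                  intersect(cols, colnames(ft_all)))]
                     })
  timings["features"] <- lap(t0)

  t0 <- tic()
  ft15 <- features[[which.min(abs(config$stages - 15))]]
  screen_res <- permutation_fdr_alpha(
    ft15, config$screen_groups[1], config$screen_groups[2],
    config = config$screen, seed = derive_seed(config$seed, "shuffles"))
  timings["screen"] <- lap(t0)

  t0 <- tic()
  equalized <- lapply(features, function(ft)
    ft[ft$group %in% c("equalized_alive", "equalized_dead"), ,
       drop = FALSE])
  classify_res <- stage_report(equalized, config$lasso)
  timings["classify"] <- lap(t0)

  # headline summary quantities
  asyn <- vapply(cohort$embryos, function(e) {
    fl <- tryCatch(
      suppressWarnings(phenotype_flags(e)),
      error = function(err) NULL)
    if (is.null(fl)) NA_real_ else fl$ab_p1_asynchrony_min
  }, numeric(1))
  corr <- ab_size_analyses(cohort$metadata, quantity = asyn)
  extra_p4 <- vapply(cohort$embryos, function(e) {
    tr <- cell_tracks(e)
    sum(tr$n_daughters == 2L & founder_of(tr$cell)$founder == "P4") > 1L
  }, logical(1))
  grp <- cohort$metadata$group
  summary <- list(
    n_embryos = nrow(cohort$metadata),
    gpa_residual = reference$gpa_residual,
    alpha_star = screen_res$alpha_star,
    n_passing_features = sum(screen_res$screen$pass),
    asynchrony_ab_size_r = corr$correlation$r,
    asynchrony_ab_size_p = corr$correlation$p,
    extra_p4_fraction_equalized_dead =
      mean(extra_p4[grp == "equalized_dead"]),
    accuracy_by_stage = vapply(classify_res, function(cr)
      cr$accuracy_mean, numeric(1)))

  result <- list(cohort = cohort, reference = reference,
                 features = features, screen = screen_res,
                 classify = classify_res, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_native(cohort$embryos, file.path(out_dir, "lineages.tsv"))
    write_metadata(cohort$metadata, file.path(out_dir, "metadata.csv"))
    jsonlite::write_json(
      list(units = "micrometres, minutes",
           cells = reference$cells,
           mean_position = reference$mean_position,
           mean_division_vector = reference$mean_division_vector,
           extents = as.list(reference$extents),
           n_controls = reference$n_controls,
           gpa_residual = reference$gpa_residual),
      file.path(out_dir, "reference.json"), digits = NA, auto_unbox = TRUE)
    for (nm in names(features))
      utils::write.csv(features[[nm]],
                       file.path(out_dir, paste0("features_", nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(screen_res$screen, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
    utils::write.csv(screen_res$fdr_table,
                     file.path(out_dir, "volcano_calibration.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary,
           classify = lapply(classify_res, function(cr) list(
             accuracy_mean = cr$accuracy_mean,
             accuracy_sd = cr$accuracy_sd,
             model_sizes = as.list(cr$model_sizes),
             inclusion_top = as.list(sort(cr$inclusion,
                                          decreasing = TRUE)[1:10]),
             best_auc = cr$best$auc))),
      file.path(out_dir, "result.json"), digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(
      list(seed = config$seed,
           config_hash = config_hash(config),
           stage_timings_sec = as.list(round(timings, 3)),
           created = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(result)
}

#' Stable hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization; identifies a run in the
#' provenance manifest.
#'
#' @param config any serializable configuration object.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate the pipeline against deposited lineage recordings
#'
#' Opt-in, offline comparison harness: given a local directory of
#' StarryNite-format lineage exports plus a metadata CSV, runs the
#' alignment / feature / screening stages on the real recordings and
#' reports the recomputed headline statistics. Nothing is ever
#' downloaded; when no path is given a skipped status is returned.
#'
#' @param deposit_dir directory with one subdirectory of t###-nuclei
#'   files per embryo and a `metadata.csv` (see [read_metadata()]), or
#'   `NULL`.
#' @param xy_res,z_res imaging calibration (micrometres per pixel /
#'   plane).
#' @param screen a [screen_config()].
#' @return list with `status` and, when run, `reference`, `screen`, and
#'   per-group cell-cycle CV summaries.
#' @export
validate_against_deposit <- function(deposit_dir = NULL, xy_res = 0.14,
                                     z_res = 0.75,
                                     screen = screen_config()) {
  if (is.null(deposit_dir) || !nzchar(deposit_dir %||% ""))
    return(list(status = "skipped: external data not provided"))
  if (!dir.exists(deposit_dir))
    stop("mapping error: '", deposit_dir, "' is not a directory; expected ",
         "one subdirectory of t###-nuclei files per embryo plus ",
         "metadata.csv", call. = FALSE)
  meta_path <- file.path(deposit_dir, "metadata.csv")
  if (!file.exists(meta_path))
    stop("mapping error: metadata.csv not found under '", deposit_dir,
         "'; see read_metadata() for the expected columns", call. = FALSE)
  metadata <- read_metadata(meta_path)
  dirs <- list.dirs(deposit_dir, recursive = FALSE)
  embryos <- list()
  for (dd in dirs) {
    id <- basename(dd)
    row <- metadata[metadata$embryo_id == id, , drop = FALSE]
    md <- if (nrow(row) == 1L)
      embryo_metadata(group = row$group,
                      relative_AB_size = row$relative_AB_size,
                      compression_um = row$compression_um,
                      frame_interval_min = row$frame_interval_min,
                      outcome = row$outcome)
    else embryo_metadata()
    embryos[[id]] <- tryCatch(
      read_starrynite(dd, xy_res = xy_res, z_res = z_res,
                      frame_interval_min = md$frame_interval_min,
                      embryo_id = id, metadata = md),
      error = function(e) {
        warning("skipping '", id, "': ", conditionMessage(e))
        NULL
      })
  }
  embryos <- Filter(Negate(is.null), embryos)
  if (!length(embryos))
    stop("mapping error: no readable embryos under '", deposit_dir, "'",
         call. = FALSE)
  groups <- vapply(embryos, function(e) e$metadata$group, character(1))
  controls <- embryos[groups == "control"]
  if (length(controls) < 2L)
    return(list(status = "partial: reference requires >= 2 control embryos",
                n_embryos = length(embryos)))
  reference <- build_reference(controls)
  ft <- feature_table(embryos, reference, stage = 15)
  vs <- variability_stats(ft)
  life_cv <- vs[grepl("\\.LifeTime$", vs$feature), ]
  cv_by_group <- tapply(life_cv$cv, life_cv$group,
                        function(v) mean(v, na.rm = TRUE))
  res <- list(status = "ok", n_embryos = length(embryos),
              reference = reference,
              cellcycle_cv_by_group = cv_by_group)
  if (all(c("equalized_dead", "equalized_alive") %in% groups))
    res$screen <- permutation_fdr_alpha(ft, "equalized_dead",
                                        "equalized_alive", config = screen)
  else
    res$screen_status <- "skipped: both equalized groups not present"
  res
}
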