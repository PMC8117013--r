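#' Pipeline configuration
#'
#' A single structured configuration driving [run_all()]. Either supply
#' input paths (ring widths, metadata, climate) or enable the simulate
#' stage; all randomness flows from named per-stage seeds derived from
#' `seed`.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate generate synthetic inputs (default TRUE).
#' @param ringwidth_path,metadata_path,climate_path input files used when
#'   `simulate = FALSE` (long CSV / metadata CSV / climate CSV).
#' @param span analysis years.
#' @param min_cambial_age juvenile-growth filter (default 15).
#' @param n_boot,boot_level bootstrap settings for correlation functions.
#' @param n_iter,burn_in MCMC settings.
#' @param seed base seed; per-stage seeds are derived deterministically.
#' @param truth a [synthetic_truth()] (simulate mode).
#' @param climate_params a [climate_gen_params()] (simulate mode).
#' @param calendar an [epidemic_calendar()].
#' @param write_draws also write full posterior draws CSVs (default FALSE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            ringwidth_path = NULL,
                            metadata_path = NULL,
                            climate_path = NULL,
                            span = 1950:2005,
                            min_cambial_age = 15,
                            n_boot = 1000L,
                            boot_level = 0.95,
                            n_iter = 60000L,
                            burn_in = 10000L,
                            seed = 1L,
                            truth = synthetic_truth(seed = seed),
                            climate_params = climate_gen_params(),
                            calendar = epidemic_calendar(),
                            write_draws = FALSE) {
  structure(list(out_dir = out_dir, simulate = simulate,
                 ringwidth_path = ringwidth_path,
                 metadata_path = metadata_path,
                 climate_path = climate_path, span = span,
                 min_cambial_age = min_cambial_age, n_boot = n_boot,
                 boot_level = boot_level, n_iter = n_iter,
                 burn_in = burn_in, seed = seed, truth = truth,
                 climate_params = climate_params, calendar = calendar,
                 write_draws = write_draws),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] may be set in the file; structured
#' fields (truth, climate parameters, calendar) use package defaults with
#' the file's `seed`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$span) && length(y$span) == 2L)
    y$span <- y$span[1]:y$span[2]
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

log_stage <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> chronologies -> covariates -> correlation
#' functions -> epidemic-year rankings -> Bayesian fits -> posterior
#' overlap and the qualitative mixture-effects table, writing every result
#' as CSV/JSON under `config$out_dir` together with a manifest (config
#' hash, seeds, file checksums). Rerunning with the same config reproduces
#' every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with all in-memory results and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  span <- config$span
  seed <- config$seed

  # --- inputs -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (config$simulate) {
    study <- generate_study(truth = config$truth,
                            climate_params = config$climate_params,
                            calendar = config$calendar, span = span)
    climate <- study$climate
    series_by_group <- study$series
    utils::write.csv(climate, file.path(out, "climate.csv"),
                     row.names = FALSE)
    all_series <- unlist(series_by_group, recursive = FALSE)
    write_long_csv(all_series, file.path(out, "ring_widths.csv"))
    write_rwl(all_series, file.path(out, "ring_widths.rwl"))
    write_metadata_csv(series_metadata(all_series),
                       file.path(out, "tree_metadata.csv"))
    write_truth_json(config$truth, study$tree_truth,
                     file.path(out, "truth.json"))
  } else {
    if (is.null(config$climate_path) || !file.exists(config$climate_path))
      stop_stage("climate", "climate path missing and simulate disabled")
    if (is.null(config$ringwidth_path) ||
        !file.exists(config$ringwidth_path))
      stop_stage("ringwidths", "ring-width path missing and simulate disabled")
    climate <- utils::read.csv(config$climate_path)
    meta <- if (!is.null(config$metadata_path))
      read_metadata_csv(config$metadata_path) else NULL
    series <- if (grepl("\\.rwl$", config$ringwidth_path))
      read_rwl(config$ringwidth_path, metadata = meta)
    else read_long_csv(config$ringwidth_path, metadata = meta)
    key <- paste(group_species_label(series), vapply(series, `[[`, "",
                                                     "stand_type"),
                 sep = "_")
    series_by_group <- split(series, key)
    study <- NULL
  }
  log_stage("inputs", t0)

  # --- chronologies -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  chronologies <- list()
  for (g in names(series_by_group)) {
    bai_list <- group_bai_series(series_by_group[[g]],
                                 min_age = config$min_cambial_age)
    chronologies[[g]] <- build_mean_chronology(bai_list, group = g,
                                               span = span)
  }
  chron_df <- do.call(rbind, lapply(names(chronologies), function(g)
    cbind(group = g, as.data.frame(chronologies[[g]]))))
  utils::write.csv(chron_df, file.path(out, "chronologies.csv"),
                   row.names = FALSE)
  stats_df <- chronology_stats_table(series_by_group, chronologies)
  utils::write.csv(stats_df, file.path(out, "chronology_stats.csv"),
                   row.names = FALSE)
  log_stage("chronology", t0)

  # --- covariates ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  covariates <- build_covariate_table(climate, years = span,
                                      calendar = config$calendar,
                                      ref_span = span)
  utils::write.csv(covariates, file.path(out, "covariates.csv"),
                   row.names = FALSE)
  log_stage("covariates", t0)

  # --- correlation functions ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  corr_df <- do.call(rbind, lapply(names(chronologies), function(g)
    correlation_function(chronologies[[g]], climate,
                         n_boot = config$n_boot,
                         level = config$boot_level,
                         seed = child_seed(seed, paste0("corr_", g)))))
  utils::write.csv(corr_df, file.path(out, "correlations.csv"),
                   row.names = FALSE)
  log_stage("correlate", t0)

  # --- epidemic-year rankings ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  rank_df <- do.call(rbind, lapply(names(chronologies), function(g)
    cbind(group = g,
          rank_first_differences(chronologies[[g]], config$calendar))))
  utils::write.csv(rank_df, file.path(out, "rankings.csv"),
                   row.names = FALSE)
  log_stage("rank", t0)

  # --- Bayesian fits ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fits <- list()
  for (g in names(chronologies)) {
    fits[[g]] <- fit_mh(chronologies[[g]], covariates,
                        n_iter = config$n_iter, burn_in = config$burn_in,
                        seed = child_seed(seed, paste0("fit_", g)),
                        group = g)
    if (config$write_draws)
      utils::write.csv(as.data.frame(fits[[g]]$draws),
                       file.path(out, paste0("draws_", g, ".csv")),
                       row.names = FALSE)
  }
  summaries <- lapply(fits, function(f) {
    s <- summary(f)
    list(summary = s, r_squared = r_squared(f),
         acceptance = as.list(stats::setNames(f$acceptance,
                                              model_par_names())),
         diagnostics = convergence_report(f))
  })
  jsonlite::write_json(summaries, file.path(out, "fit_summaries.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  log_stage("fit", t0)

  # --- overlap + qualitative table ----------------------------------------
  t0 <- as.numeric(Sys.time())
  overlaps <- overlap_matrix(fits)
  utils::write.csv(overlaps, file.path(out, "overlap.csv"),
                   row.names = FALSE)
  table3 <- summarize_mixture_effects(fits, overlaps)
  utils::write.csv(table3, file.path(out, "mixture_effects.csv"),
                   row.names = FALSE)
  log_stage("overlap", t0)

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    config_hash = config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("dendromix")),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out, f))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(chronologies = chronologies, stats = stats_df,
                 covariates = covariates, correlations = corr_df,
                 rankings = rank_df, fits = fits, overlaps = overlaps,
                 mixture_effects = table3, manifest = manifest,
                 study = study))
}

group_species_label <- function(series) {
  vapply(series, function(s)
    if (s$species == "black_spruce") "spruce" else "aspen", "")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # hash the analysis-defining settings, not the output location
  cfg <- config[setdiff(names(config), "out_dir")]
  dump <- utils::capture.output(utils::str(cfg, digits.d = 15,
                                           list.len = 1e4))
  writeLines(dump, tmp)
  unname(tools::md5sum(tmp))
}

#' Qualitative species-mixture effects table
#'
#' For each model parameter and each within-species pair of stand types,
#' reports the direction of the difference (from posterior-mean signs) and
#' whether it is significant under the <10% posterior-overlap rule;
#' non-significant contrasts are reported as "Null".
#'
#' @param fits named list of [fit_mh()] results (group labels as names).
#' @param overlaps optional precomputed [overlap_matrix()].
#' @return data.frame(parameter, species, contrast, direction, overlap,
#'   significant).
#' @export
summarize_mixture_effects <- function(fits, overlaps = NULL) {
  if (is.null(overlaps)) overlaps <- overlap_matrix(fits)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(overlaps))) {
    a <- overlaps$group_a[i]; b <- overlaps$group_b[i]
    if (group_species(a) != group_species(b)) next
    p <- overlaps$parameter[i]
    ma <- mean(fits[[a]]$draws[, p]); mb <- mean(fits[[b]]$draws[, p])
    dir <- if (!overlaps$significant[i] || ma == mb) "Null"
    else if (ma > mb) "Higher" else "Lower"
    k <- k + 1L
    rows[[k]] <- data.frame(parameter = p,
                            species = group_species(a),
                            contrast = paste(group_stand(a), "vs",
                                             group_stand(b)),
                            direction = dir,
                            overlap = overlaps$overlap[i],
                            significant = overlaps$significant[i])
  }
  do.call(rbind, rows)
}
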