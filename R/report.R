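#' Analysis configuration
#'
#' Builds and validates the configuration for an end-to-end run. Exactly one
#' of `simulate` (a [synthetic_params()] or an argument list for it) and
#' `input_dir` (a directory in the layout written by [write_cohort()]:
#' `cohort.csv`, `sc_<id>_tp<k>.csv`, optional `ts_<id>_tp<k>.csv`) must be
#' given.
#'
#' @param simulate [synthetic_params()] or a named list of its arguments.
#' @param input_dir Directory of input files.
#' @param density Network density for thresholding (default 0.25).
#' @param mask_convention `"row"`, `"union"` or `"intersection"`.
#' @param fc_metric `"pearson"` or `"partial"`.
#' @param clusters Named list of 0-based node index vectors, a JSON path, or
#'   `NULL` to use [study_clusters()] when the atlas has 90 nodes.
#' @param lme_form `"days_plus_pma"` or `"days_only"`.
#' @param bonferroni_m Family size for the regional correction (default 7).
#' @param fd_threshold Low-motion threshold in mm (default 0.3).
#' @param sweep_densities Densities for the threshold sweep, or `NULL` to
#'   skip the sweep.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Seed for any simulation (overrides the simulate block's).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(simulate = NULL, input_dir = NULL,
                            density = 0.25,
                            mask_convention = "row",
                            fc_metric = c("pearson", "partial"),
                            clusters = NULL,
                            lme_form = "days_plus_pma",
                            bonferroni_m = 7L,
                            fd_threshold = 0.3,
                            sweep_densities = seq(0.05, 1, by = 0.05),
                            out_dir = NULL,
                            seed = NULL) {
  fc_metric <- match.arg(fc_metric)
  if (is.null(simulate) == is.null(input_dir)) {
    stop("exactly one of `simulate` and `input_dir` must be given",
         call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "synthetic_params")) {
    if (!is.null(seed)) simulate$seed <- seed
    simulate <- do.call(synthetic_params, simulate)
  } else if (!is.null(simulate) && !is.null(seed)) {
    simulate$seed <- as.integer(seed)
  }
  if (is.character(clusters)) clusters <- read_clusters(clusters)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]",
                                        call. = FALSE)
  structure(list(simulate = simulate, input_dir = input_dir,
                 density = density, mask_convention = mask_convention,
                 fc_metric = fc_metric, clusters = clusters,
                 lme_form = lme_form, bonferroni_m = as.integer(bonferroni_m),
                 fd_threshold = fd_threshold,
                 sweep_densities = sweep_densities,
                 out_dir = out_dir, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [analysis_config()]; the
#' `simulate` block holds [synthetic_params()] arguments.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(analysis_config, cfg)
}

read_input_dir <- function(dir) {
  panel <- read_cohort_table(file.path(dir, "cohort.csv"))
  ids <- panel$subject_id
  load_tp <- function(prefix, tp, reader, ...) {
    files <- file.path(dir, sprintf("%s_%s_tp%d.csv", prefix, ids, tp))
    if (!all(file.exists(files))) {
      if (!any(file.exists(files))) return(NULL)
      stop("missing ", prefix, " files for some subjects at tp", tp,
           call. = FALSE)
    }
    lapply(seq_along(ids), function(i) reader(files[i], i, tp))
  }
  sc1 <- load_tp("sc", 1L, function(f, i, tp)
    read_connectome(f, ids[i], tp, "structural"))
  sc2 <- load_tp("sc", 2L, function(f, i, tp)
    read_connectome(f, ids[i], tp, "structural"))
  ts1 <- load_tp("ts", 1L, function(f, i, tp) read_timeseries(f))
  ts2 <- load_tp("ts", 2L, function(f, i, tp) read_timeseries(f))
  list(panel = panel,
       sc = if (!is.null(sc1)) list(tp1 = sc1, tp2 = sc2),
       ts = if (!is.null(ts1)) list(tp1 = ts1, tp2 = ts2))
}

analyse_modality <- function(tp1, tp2, panel, config, label) {
  s <- similarity_matrix(tp1, tp2, density = config$density,
                         mask_convention = config$mask_convention)
  s_unmasked <- similarity_matrix(tp1, tp2, density = NULL)
  idf <- identifiability(s)
  glm_fit <- glm_self_similarity(idf$self_similarities,
                                 panel$pma_scan1, panel$days_between_scans)
  lme_fit <- lme_self_to_other(s, panel, form = config$lme_form)
  pc_pma <- partial_corr(panel$pma_scan1, idf$self_similarities,
                         covariates = panel$days_between_scans)
  pc_days <- partial_corr(panel$days_between_scans, idf$self_similarities,
                          covariates = panel$pma_scan1)
  sweep <- NULL
  if (!is.null(config$sweep_densities)) {
    sweep <- threshold_sweep(tp1, tp2, config$sweep_densities,
                             mask_convention = config$mask_convention)
  }
  regional <- NULL
  if (!is.null(config$clusters)) {
    regional <- regional_pipeline(tp1, tp2, config$clusters,
                                  density = config$density,
                                  mask_convention = config$mask_convention)
    reg_glm <- purrr::imap(regional$identifiability, function(ridf, name) {
      fit <- glm_self_similarity(ridf$self_similarities,
                                 panel$pma_scan1, panel$days_between_scans)
      dplyr::mutate(tidy.fingerprint_glm(fit), cluster = name)
    }) |> dplyr::bind_rows()
    for (term in c("pma1", "days")) {
      rows <- reg_glm$term == term
      reg_glm[rows, c("p_adjusted", "significant")] <-
        bonferroni(reg_glm$p_value[rows], m = config$bonferroni_m)[
          c("p_adjusted", "significant")]
    }
    regional$glm <- reg_glm
  }
  list(modality = label, similarity = s,
       similarity_unmasked = idf_pair(s_unmasked),
       normalized = row_max_normalize(s), zscores = zscore_rows(s),
       identifiability = idf, glm = glm_fit, lme = lme_fit,
       partial_corr_pma = pc_pma, partial_corr_days = pc_days,
       sweep = sweep, regional = regional)
}

idf_pair <- function(s) list(similarity = s, identifiability = identifiability(s))

#' Run the end-to-end fingerprinting analysis
#'
#' Executes the full pipeline from an [analysis_config()]: obtain the cohort
#' (simulated or read from disk), build functional connectomes from the
#' timeseries with the configured metric, compute thresholded and unmasked
#' similarity matrices, identifiability, row-max-normalised and z-scored
#' matrices, the threshold sweep, regional cluster results with
#' Bonferroni-corrected age models, and the age / interval statistics —
#' per available modality. Deterministic given the config and seed. When
#' `out_dir` is set, writes delimited matrices, summary tables and a JSON
#' run manifest.
#'
#' @param config An `analysis_config`, or a YAML path.
#' @return A `fingerprint_report`: per-modality result lists (`structural`,
#'   `functional`), the `panel`, `summary` tibble and `config`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))

  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    panel <- cohort$panel
    sc <- cohort$sc
    ts <- cohort$ts
  } else {
    inputs <- read_input_dir(config$input_dir)
    panel <- inputs$panel
    sc <- inputs$sc
    ts <- inputs$ts
  }
  nn <- if (!is.null(sc)) nrow(sc$tp1[[1]]) else nrow(ts$tp1[[1]])
  if (is.null(config$clusters) && nn == 90) {
    config$clusters <- study_clusters()
  }

  results <- list()
  if (!is.null(sc)) {
    results$structural <- withCallingHandlers(
      analyse_modality(sc$tp1, sc$tp2, panel, config, "structural"),
      error = function(e) stop("structural stage: ", conditionMessage(e),
                               call. = FALSE))
  }
  if (!is.null(ts)) {
    fc_fun <- if (config$fc_metric == "pearson") pearson_fc else partial_fc
    results$functional <- withCallingHandlers({
      fc1 <- lapply(seq_len(nrow(panel)), function(i)
        fc_fun(ts$tp1[[i]], panel$subject_id[i], 1L))
      fc2 <- lapply(seq_len(nrow(panel)), function(i)
        fc_fun(ts$tp2[[i]], panel$subject_id[i], 2L))
      analyse_modality(fc1, fc2, panel, config,
                       paste0("functional_", config$fc_metric))
    }, error = function(e) stop("functional stage: ", conditionMessage(e),
                                call. = FALSE))
  }

  summary <- purrr::map(results, function(r) {
    tibble::tibble(
      modality = r$modality,
      n_subjects = r$identifiability$n_total,
      n_matched = r$identifiability$n_matched,
      rate = r$identifiability$rate,
      rate_unmasked = r$similarity_unmasked$identifiability$rate,
      mean_self = mean(r$identifiability$self_similarities),
      mean_other = mean(r$identifiability$other_similarities))
  }) |> dplyr::bind_rows()

  report <- structure(list(results = results, panel = panel,
                           summary = summary, config = config),
                      class = "fingerprint_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat("<fingerprint_report>\n")
  print(x$summary)
  invisible(x)
}

write_matrix_csv <- function(v, path) {
  utils::write.csv(as.data.frame(v), path, row.names = TRUE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$panel),
                   file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  for (name in names(report$results)) {
    r <- report$results[[name]]
    pre <- file.path(out_dir, name)
    write_matrix_csv(r$similarity$values, paste0(pre, "_similarity.csv"))
    write_matrix_csv(r$normalized$values, paste0(pre, "_similarity_rowmax.csv"))
    write_matrix_csv(r$zscores$values, paste0(pre, "_similarity_zscores.csv"))
    coefs <- dplyr::bind_rows(
      dplyr::mutate(generics::tidy(r$glm), model = "glm_self_similarity"),
      dplyr::mutate(generics::tidy(r$lme), model = "lme_self_to_other"))
    utils::write.csv(coefs, paste0(pre, "_coefficients.csv"),
                     row.names = FALSE)
    if (!is.null(r$sweep)) {
      utils::write.csv(r$sweep, paste0(pre, "_threshold_sweep.csv"),
                       row.names = FALSE)
    }
    if (!is.null(r$regional)) {
      utils::write.csv(r$regional$summary, paste0(pre, "_regional.csv"),
                       row.names = FALSE)
      utils::write.csv(r$regional$glm, paste0(pre, "_regional_glm.csv"),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("neofinger")),
    seed = report$config$seed %||%
      (if (!is.null(report$config$simulate)) report$config$simulate$seed),
    density = report$config$density,
    mask_convention = report$config$mask_convention,
    fc_metric = report$config$fc_metric,
    lme_form = report$config$lme_form,
    bonferroni_m = report$config$bonferroni_m,
    n_subjects = nrow(report$panel),
    modalities = names(report$results),
    timestamp = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
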