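#' Run configuration for the end-to-end synthetic study
#'
#' Bundles everything a seeded run needs: the study design, condition
#' effects, fit options, QC thresholds and the myosin head concentration.
#'
#' @param design A [study_design()].
#' @param effects A [condition_effects()].
#' @param fit A [fit_options()] list.
#' @param qc A [qc_thresholds()] list.
#' @param head_concentration_uM Myosin head concentration for the
#'   energetics, uM.
#' @param baseline_condition Condition used as the baseline of percent
#'   differences; defaults to the first condition of the design.
#' @return A `run_config` list.
#' @export
run_config <- function(design = study_design(),
                       effects = condition_effects(),
                       fit = fit_options(),
                       qc = qc_thresholds(),
                       head_concentration_uM = 220,
                       baseline_condition = design$conditions[1]) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design().")
  if (!inherits(effects, "condition_effects")) abort("`effects` must be a condition_effects().")
  if (!baseline_condition %in% design$conditions) {
    abort("`baseline_condition` must be one of the design's conditions.")
  }
  structure(list(design = design, effects = effects, fit = fit, qc = qc,
                 head_concentration_uM = head_concentration_uM,
                 baseline_condition = baseline_condition),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The schema mirrors the arguments of [study_design()],
#' [condition_effects()], [fit_options()] and [qc_thresholds()] under the
#' top-level keys `design`, `effects`, `fit`, `qc`, `head_concentration_uM`,
#' `baseline_condition`. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("design", "effects", "fit", "qc", "head_concentration_uM",
             "baseline_condition")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  design <- do.call(study_design, raw$design %||% list())
  eff_args <- raw$effects %||% list()
  if (!is.null(eff_args$baseline)) {
    eff_args$baseline <- lapply(eff_args$baseline, function(b) {
      do.call(decay_truth, b)
    })
  }
  if (!is.null(eff_args$condition_mult)) {
    eff_args$condition_mult <- bind_rows(lapply(eff_args$condition_mult, as_tibble))
  }
  if (!is.null(eff_args$temperature_mult)) {
    eff_args$temperature_mult <- bind_rows(lapply(eff_args$temperature_mult, as_tibble))
  }
  effects <- do.call(condition_effects, eff_args)
  args <- list(design = design, effects = effects,
               fit = do.call(fit_options, raw$fit %||% list()),
               qc = do.call(qc_thresholds, raw$qc %||% list()))
  if (!is.null(raw$head_concentration_uM)) {
    args$head_concentration_uM <- raw$head_concentration_uM
  }
  if (!is.null(raw$baseline_condition)) {
    args$baseline_condition <- raw$baseline_condition
  }
  do.call(run_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config, file = tmp, control = c("keepNA", "keepInteger", "showAttributes"))
  unname(tools::md5sum(tmp))
}

manifest_add <- function(manifest, stage, files) {
  manifest$stages[[stage]] <- list(
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  manifest
}

write_manifest <- function(manifest, out_dir) {
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate stage: write the synthetic study to disk
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written (`traces.csv`, `truth.csv`).
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(config$design, config$effects)
  paths <- file.path(out_dir, c("traces.csv", "truth.csv"))
  readr::write_csv(sim$traces, paths[1])
  readr::write_csv(sim$truth, paths[2])
  invisible(paths)
}

#' Fit stage: fit every fiber trace and write fits + QC report
#'
#' @param config A [run_config()].
#' @param out_dir Directory holding `traces.csv`; outputs are written there.
#' @return Invisibly, the paths written (`fits.csv`, `qc_report.json`).
#' @export
run_fit <- function(config, out_dir) {
  traces <- readr::read_csv(file.path(out_dir, "traces.csv"),
                            show_col_types = FALSE)
  assert_columns(traces, c("fiber_id", "time_s", "raw_fluor",
                           "background_fluor"), "traces.csv")
  fits <- fit_decay_all(traces, config$fit)
  part <- qc_filter(fits, config$qc)
  paths <- file.path(out_dir, c("fits.csv", "qc_report.json"))
  readr::write_csv(fits, paths[1])
  jsonlite::write_json(
    list(n_fit = nrow(fits), n_accepted = nrow(part$accepted),
         n_rejected = nrow(part$rejected),
         rejections = part$rejected[, c("fiber_id", "reason")]),
    paths[2], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Energetics stage: fiber records, animal summaries, ratios and tests
#'
#' @param config A [run_config()].
#' @param out_dir Directory holding `fits.csv`; outputs are written there.
#' @return Invisibly, the paths written.
#' @export
run_energetics <- function(config, out_dir) {
  fits <- readr::read_csv(file.path(out_dir, "fits.csv"),
                          show_col_types = FALSE)
  accepted <- qc_filter(fits, config$qc)$accepted
  records <- fiber_records(accepted, config$head_concentration_uM)
  summaries <- aggregate_by_animal(records)
  paths <- file.path(out_dir, c("fiber_records.csv", "animal_summary.csv"))
  readr::write_csv(records, paths[1])
  readr::write_csv(summaries, paths[2])
  if (length(config$design$temperatures_C) == 2L) {
    temps <- sort(config$design$temperatures_C, decreasing = TRUE)
    ratios <- temperature_ratios(records, temp_warm = temps[1],
                                 temp_cold = temps[2])
    rp <- file.path(out_dir, "temperature_ratios.csv")
    readr::write_csv(ratios, rp)
    paths <- c(paths, rp)
  }
  invisible(paths)
}

#' Report stage: group means, percent differences and ANOVA per stratum
#'
#' Per fiber type x temperature x metric: condition means of the animal
#' means, signed percent difference of each condition versus the baseline
#' condition, and a classical one-way ANOVA across conditions on animal
#' means (run when every condition has >= 2 animals).
#'
#' @param config A [run_config()].
#' @param out_dir Directory holding `animal_summary.csv`.
#' @return Invisibly, the path of `report.json`.
#' @export
run_report <- function(config, out_dir) {
  summaries <- readr::read_csv(file.path(out_dir, "animal_summary.csv"),
                               show_col_types = FALSE)
  base <- config$baseline_condition
  metrics <- intersect(c("mean_p1_pct", "mean_p2_pct", "mean_t1_s",
                         "mean_t2_s", "mean_atp_consumption"),
                       names(summaries))
  strata <- distinct(summaries, .data$fiber_type, .data$temperature_C)
  blocks <- list()
  for (i in seq_len(nrow(strata))) {
    st <- summaries |>
      filter(.data$fiber_type == strata$fiber_type[i],
             .data$temperature_C == strata$temperature_C[i])
    for (metric in metrics) {
      cond_means <- st |>
        group_by(.data$condition) |>
        summarise(mean = mean(.data[[metric]]), n_animals = dplyr::n(),
                  .groups = "drop")
      pct <- cond_means |>
        filter(.data$condition != base) |>
        mutate(percent_vs_baseline = percent_difference(
          cond_means$mean[cond_means$condition == base], .data$mean)) |>
        select("condition", "percent_vs_baseline")
      test <- if (length(unique(st$condition)) >= 2 &&
                  all(table(st$condition) >= 2)) {
        one_way_anova(st, metric, "condition")
      } else {
        NULL
      }
      blocks[[length(blocks) + 1L]] <- list(
        fiber_type = strata$fiber_type[i],
        temperature_C = strata$temperature_C[i],
        metric = sub("^mean_", "", metric),
        baseline = base,
        condition_means = cond_means,
        percent_differences = pct,
        anova = test)
    }
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(baseline_condition = base, comparisons = blocks),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the full seeded simulate -> fit -> energetics -> report pipeline
#'
#' Executes every stage into `out_dir` and writes `manifest.json` with the
#' package version, seed, config hash and per-file md5 hashes. Re-running
#' with the same config and seed reproduces identical file hashes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
run_study_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config().")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("myostates")),
    seed = config$design$seed,
    config_hash = config_hash(config),
    stages = list())
  manifest <- manifest_add(manifest, "simulate", run_simulate(config, out_dir))
  manifest <- manifest_add(manifest, "fit", run_fit(config, out_dir))
  manifest <- manifest_add(manifest, "energetics", run_energetics(config, out_dir))
  manifest <- manifest_add(manifest, "report", run_report(config, out_dir))
  invisible(write_manifest(manifest, out_dir))
}

#' X-ray stage: measure reflections on a set of profiles
#'
#' @param profiles Named list of profile tibbles (`radius_mm`, `intensity`).
#' @param windows Named list of radius windows ([reflection_windows()]).
#' @param geometry A [beam_geometry()].
#' @param out_path Optional CSV path for the measurements.
#' @return Tibble of measurements, one row per profile x reflection.
#' @export
run_xray <- function(profiles, windows = reflection_windows(),
                     geometry = beam_geometry(), out_path = NULL) {
  out <- imap(profiles, function(pr, nm) {
    m <- measure_reflections(pr, windows, geometry)
    mutate(m, profile_id = nm, .before = 1)
  }) |> list_rbind()
  if (!is.null(out_path)) readr::write_csv(out, out_path)
  out
}

#' Omics stage: preprocessing, differential expression, z-scores and PCA
#'
#' @param am An `abundance_matrix`.
#' @param group_a,group_b Groups for the differential comparison (b vs a).
#' @param out_dir Optional directory for `de_results.csv`,
#'   `ptm_zscores.csv` and `pca_scores.csv`.
#' @param seed Seed for the imputation.
#' @param ... Passed to [differential_expression()].
#' @return List with `de`, `zscores`, `pca`.
#' @export
run_omics <- function(am, group_a, group_b, out_dir = NULL, seed = 1L, ...) {
  pre <- preprocess_abundance(am, seed = seed)
  de <- differential_expression(pre, group_a, group_b, ...)
  zs <- ptm_zscores(pre)
  pca <- pca_samples(pre, k = 2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(de, file.path(out_dir, "de_results.csv"))
    readr::write_csv(zs$condition_means, file.path(out_dir, "ptm_zscores.csv"))
    readr::write_csv(pca, file.path(out_dir, "pca_scores.csv"))
  }
  list(de = de, zscores = zs, pca = pca)
}
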