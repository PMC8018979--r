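#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end analysis uses. Unknown
#' arguments are rejected; a resolved copy is written next to every
#' output by [run_pipeline()].
#'
#' @param n_cna,n_mci Synthetic cohort group sizes.
#' @param seed Master seed for all randomness.
#' @param filter A [filter_spec()].
#' @param dtc_mode Dual-task-cost denominator convention.
#' @param alpha Feature-screening significance level.
#' @param ridge Logistic separation-guard penalty.
#' @param evaluation Model evaluation mode, `"in_sample"` or `"cv"`.
#' @param dropout_prob Protocol-dropout probability for the simulator.
#' @param gait_distance_m Walkway length, m.
#' @param out_dir Optional output directory; when given, every stage's
#'   tables plus a run manifest are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_cna = 27, n_mci = 17, seed = 1,
                            filter = filter_spec(),
                            dtc_mode = c("st_denominator", "dt_denominator"),
                            alpha = 0.05, ridge = 1e-4,
                            evaluation = c("in_sample", "cv"),
                            dropout_prob = 0, gait_distance_m = 10,
                            out_dir = NULL) {
  dtc_mode <- match.arg(dtc_mode)
  evaluation <- match.arg(evaluation)
  stopifnot(inherits(filter, "filter_spec"), alpha >= 0, alpha <= 1,
            ridge >= 0)
  structure(list(n_cna = n_cna, n_mci = n_mci, seed = as.integer(seed),
                 filter = filter, dtc_mode = dtc_mode, alpha = alpha,
                 ridge = ridge, evaluation = evaluation,
                 dropout_prob = dropout_prob,
                 gait_distance_m = gait_distance_m, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes simulate -> eligibility -> filter/segment/features -> DTC ->
#' group screening + MMSE correlation -> per-(task, load) logistic
#' models, end to end. Deterministic given the configuration: rerunning
#' with the same config reproduces every table.
#'
#' @param config A [pipeline_config()].
#' @return List bundle: `subjects`, `base_features`, `dtc_table`,
#'   `screen`, `mmse_correlations`, `models`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- generator_config(n_cna = config$n_cna, n_mci = config$n_mci,
                          seed = config$seed,
                          dropout_prob = config$dropout_prob,
                          gait_distance_m = config$gait_distance_m)
  cohort <- simulate_cohort(gen)
  eligible <- apply_eligibility(cohort$subjects)
  cohort$subjects <- eligible
  if (nrow(eligible) == 0) stop("pipeline aborted: no eligible subjects")

  base <- build_base_features(cohort, fspec = config$filter,
                              distance_m = config$gait_distance_m)
  meta <- eligible[match(base$subject_id, eligible$subject_id), ]
  dtc <- assemble_dtc_table(base, mode = config$dtc_mode)
  screen <- screen_features(dtc, meta$group, alpha = config$alpha)
  mmse_cor <- correlate_with_mmse(dtc, meta$mmse)
  models <- run_model_suite(dtc, meta$group, meta$age, screen,
                            ridge = config$ridge,
                            evaluation = config$evaluation,
                            seed = config$seed)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mcdtscreen")),
    seed = config$seed,
    n_cna = config$n_cna, n_mci = config$n_mci,
    n_analysed = nrow(base),
    exclusions = attr(eligible, "exclusions"),
    dtc_denominator_mode = attr(dtc, "denominator_mode"),
    alpha = config$alpha, evaluation = config$evaluation,
    n_feature_columns = n_feature_columns(dtc),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  bundle <- list(subjects = eligible, base_features = base, dtc_table = dtc,
                 screen = screen, mmse_correlations = mmse_cor,
                 models = models, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle, config)
  bundle
}

write_pipeline_outputs <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(bundle$subjects, p("subjects.csv"), row.names = FALSE)
  utils::write.csv(bundle$dtc_table, p("features_dtc.csv"), row.names = FALSE)
  utils::write.csv(bundle$screen, p("group_screen.csv"), row.names = FALSE)
  utils::write.csv(bundle$mmse_correlations, p("mmse_correlations.csv"),
                   row.names = FALSE)
  flat_models <- bundle$models[, setdiff(names(bundle$models),
                                         c("model", "roc"))]
  utils::write.csv(flat_models, p("models.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- config[setdiff(names(config), "filter")]
  cfg$filter <- unclass(config$filter)
  jsonlite::write_json(cfg, p("config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
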