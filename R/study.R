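# End-to-end study replica: simulate a development cohort, fit the joint and
# landmark models on it, simulate case-mix-shifted validation cohorts, and
# externally validate all three prediction settings (error curves,
# calibration, subgroup analyses). Every random draw flows from one root
# seed, so a rerun with the same configuration is byte-identical.

#' Configuration of a full development-and-validation study
#'
#' @param dev_scenario name of the development simulation scenario (see
#'   [simulation_scenario()]).
#' @param dev_n development cohort size.
#' @param validation_scenarios character vector of validation scenario names.
#' @param val_n validation cohort size(s) (recycled).
#' @param landmark_time the landmark / prediction time `s` used for the
#'   calibration analyses and subgroup split (years).
#' @param w_grid prediction windows for the fixed-`s` error curve.
#' @param s_grid prediction times for the fixed-`w` error curve.
#' @param w_fixed window used along `s_grid`.
#' @param calibration_w window for the calibration tables
#'   (prediction at `landmark_time + calibration_w` years).
#' @param subgroups also validate on the relapse-before-s / no-relapse
#'   subgroups (prediction only; no refitting).
#' @param joint_control a [joint_control()].
#' @param landmark_control a [landmark_control()].
#' @return list of class `"study_config"`.
#' @export
study_config <- function(dev_scenario = "french_like", dev_n = 1000,
                         validation_scenarios = c("west_midlands_like",
                                                  "netherlands_like"),
                         val_n = 1500, landmark_time = 5,
                         w_grid = c(1, 2, 5, 8), s_grid = c(1, 3, 5, 7),
                         w_fixed = 5, calibration_w = 5, subgroups = TRUE,
                         joint_control = jointpredict::joint_control(),
                         landmark_control = jointpredict::landmark_control()) {
  stopifnot(landmark_time >= 0, all(w_grid > 0), all(s_grid >= 0),
            w_fixed > 0, calibration_w > 0,
            !anyDuplicated(validation_scenarios))
  structure(list(dev_scenario = dev_scenario, dev_n = dev_n,
                 validation_scenarios = validation_scenarios,
                 val_n = rep_len(val_n, length(validation_scenarios)),
                 landmark_time = landmark_time, w_grid = w_grid,
                 s_grid = s_grid, w_fixed = w_fixed,
                 calibration_w = calibration_w, subgroups = subgroups,
                 joint_control = joint_control,
                 landmark_control = landmark_control),
            class = "study_config")
}

subgroup_cohort <- function(x, ids) {
  cohort(x$subjects[x$subjects$id %in% ids, , drop = FALSE],
         x$recurrences[x$recurrences$id %in% ids, , drop = FALSE],
         origin = x$origin)
}

validate_on <- function(val, joint_fit, lm_fitter, config) {
  s0 <- config$landmark_time
  curves_w <- prediction_error_curve(val, joint = joint_fit,
                                     landmark_fitter = lm_fitter,
                                     settings = c("rec", "ign", "lm"),
                                     s = s0, w = config$w_grid)
  s_ok <- config$s_grid[config$s_grid + config$w_fixed <=
                          max(val$subjects$followup_time)]
  curves_s <- prediction_error_curve(val, joint = joint_fit,
                                     landmark_fitter = lm_fitter,
                                     settings = c("rec", "ign", "lm"),
                                     s = s_ok, w = config$w_fixed)
  G <- censoring_km(val)
  at_risk <- val$subjects$followup_time > s0
  calib <- list()
  for (set in c("rec", "ign", "lm")) {
    model <- if (set == "lm") lm_fitter(s0) else joint_fit
    pr <- predict_death(model, val, s0, config$calibration_w, setting = set)
    calib[[set]] <- calibration_table(
      pr$probability, val$subjects$followup_time[at_risk],
      val$subjects$death[at_risk], s0, config$calibration_w)
  }
  out <- list(curves_w = curves_w, curves_s = curves_s, calibration = calib)
  if (config$subgroups) {
    nprev <- n_relapses(val, before = s0)
    ids_rel <- val$subjects$id[nprev >= 1 & at_risk]
    ids_norel <- val$subjects$id[nprev == 0 & at_risk]
    out$subgroups <- list()
    for (nm in c("relapsed", "no_relapse")) {
      ids <- if (nm == "relapsed") ids_rel else ids_norel
      if (length(ids) < 30) next
      sub <- subgroup_cohort(val, ids)
      out$subgroups[[nm]] <- prediction_error_curve(
        sub, joint = joint_fit, landmark_fitter = lm_fitter,
        settings = c("rec", "ign", "lm"), s = s0, w = config$w_grid)
    }
  }
  out
}

#' Run the full development-and-validation study
#'
#' Simulates the development cohort, fits the joint frailty model and the
#' landmark Cox model, simulates each validation scenario with its shifted
#' covariate mix, and computes prediction-error curves (both with `s` fixed
#' and with `w` fixed), calibration tables for the three settings, and the
#' subgroup analyses (prediction on relapsed / relapse-free subjects without
#' refitting). Deterministic given `seed`. If `out_dir` is given, all tables
#' are written as CSV and the fitted models as JSON.
#'
#' @param config a [study_config()].
#' @param seed integer root seed; every stage derives its stream from it.
#' @param out_dir optional output directory.
#' @return (invisibly) a report list with the fitted models, per-scenario
#'   validation results, and the development-cohort summary.
#' @export
run_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  dev_scn <- simulation_scenario(config$dev_scenario,
                                 n_subjects = config$dev_n)
  dev <- simulate_cohort(dev_scn$true, dev_scn$config, seed = seed)
  joint_fit <- fit_joint_model(dev, config$joint_control)
  lm_cache <- new.env()
  lm_fitter <- function(s) {
    key <- as.character(s)
    if (is.null(lm_cache[[key]]))
      lm_cache[[key]] <- fit_landmark_cox(build_landmark_dataset(dev, s),
                                          config$landmark_control)
    lm_cache[[key]]
  }
  report <- list(seed = seed, config = config, joint_fit = joint_fit,
                 landmark_fit = lm_fitter(config$landmark_time),
                 dev_summary = list(
                   n = config$dev_n, deaths = sum(dev$subjects$death),
                   relapses = nrow(dev$recurrences),
                   no_relapse_fraction = mean(n_relapses(dev) == 0)),
                 validation = list())
  for (k in seq_along(config$validation_scenarios)) {
    nm <- config$validation_scenarios[k]
    scn <- simulation_scenario(nm, n_subjects = config$val_n[k])
    val <- simulate_cohort(scn$true, scn$config, seed = seed + 1000 * k)
    report$validation[[nm]] <- validate_on(val, joint_fit, lm_fitter, config)
  }
  if (!is.null(out_dir)) write_study(report, out_dir)
  invisible(report)
}

write_study <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_joint_model(report$joint_fit, file.path(out_dir, "joint_model.json"))
  write_landmark_model(report$landmark_fit,
                       file.path(out_dir, "landmark_model.json"))
  for (nm in names(report$validation)) {
    v <- report$validation[[nm]]
    utils::write.csv(v$curves_w,
                     file.path(out_dir, paste0("brier_curve_w_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(v$curves_s,
                     file.path(out_dir, paste0("brier_curve_s_", nm, ".csv")),
                     row.names = FALSE)
    for (set in names(v$calibration))
      utils::write.csv(as.data.frame(v$calibration[[set]]),
                       file.path(out_dir,
                                 paste0("calibration_", nm, "_", set, ".csv")),
                       row.names = FALSE)
    for (sg in names(v$subgroups))
      utils::write.csv(v$subgroups[[sg]],
                       file.path(out_dir,
                                 paste0("brier_subgroup_", nm, "_", sg,
                                        ".csv")),
                       row.names = FALSE)
  }
  summary <- list(seed = report$seed,
                  dev = report$dev_summary,
                  theta = report$joint_fit$theta,
                  alpha = report$joint_fit$alpha,
                  joint_converged = report$joint_fit$converged)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
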