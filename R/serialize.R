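# JSON persistence for fitted models and YAML persistence for simulation
# scenarios, so a fitted model can be reused for prediction without refitting.

hazard_to_list <- function(h) {
  if (inherits(h, "spline_hazard"))
    list(type = "spline", order = h$basis$order, t_max = h$basis$t_max,
         interior = h$basis$interior, eta = h$eta)
  else if (inherits(h, "weibull_hazard"))
    list(type = "weibull", shape = h$shape, scale = h$scale)
  else if (inherits(h, "piecewise_hazard"))
    list(type = "piecewise", cuts = h$cuts, values = h$values)
  else stop("unknown hazard type")
}

hazard_from_list <- function(l) {
  switch(l$type,
         spline = {
           b <- spline_basis(l$t_max,
                             n_basis = length(l$interior) + l$order,
                             order = l$order)
           b$interior <- as.numeric(l$interior)
           b$knots <- c(rep(0, l$order), b$interior, rep(l$t_max, l$order))
           spline_hazard(b, as.numeric(l$eta))
         },
         weibull = weibull_hazard(l$shape, l$scale),
         piecewise = piecewise_hazard(as.numeric(l$cuts),
                                      as.numeric(l$values)),
         stop("unknown hazard type ", l$type))
}

#' Write a fitted joint frailty model to JSON
#' @param fit a `"joint_frailty_fit"`.
#' @param path output file.
#' @export
write_joint_model <- function(fit, path) {
  obj <- list(model = "joint_frailty",
              hazard_rec = hazard_to_list(fit$hazard_rec),
              hazard_death = hazard_to_list(fit$hazard_death),
              beta_rec = as.list(fit$beta_rec),
              beta_death = as.list(fit$beta_death),
              alpha = fit$alpha, theta = fit$theta,
              se = fit$se, converged = fit$converged,
              loglik = fit$loglik, loglik_pen = fit$loglik_pen,
              n = fit$n, n_relapses = fit$n_relapses, n_deaths = fit$n_deaths,
              control = unclass(fit$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a joint frailty model from JSON
#' @param path file written by [write_joint_model()].
#' @return a `"joint_frailty_fit"` usable for prediction (no working-scale
#'   internals).
#' @export
read_joint_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hazard_rec = hazard_from_list(l$hazard_rec),
                 hazard_death = hazard_from_list(l$hazard_death),
                 beta_rec = unlist(l$beta_rec),
                 beta_death = unlist(l$beta_death),
                 alpha = l$alpha, theta = l$theta, se = l$se,
                 converged = l$converged, loglik = l$loglik,
                 loglik_pen = l$loglik_pen, n = l$n,
                 n_relapses = l$n_relapses, n_deaths = l$n_deaths,
                 control = l$control),
            class = "joint_frailty_fit")
}

#' Write a landmark Cox fit to JSON
#' @param fit a `"landmark_fit"`.
#' @param path output file.
#' @export
write_landmark_model <- function(fit, path) {
  obj <- list(model = "landmark_cox", landmark_time = fit$landmark_time,
              hazard = hazard_to_list(fit$hazard), beta = as.list(fit$beta),
              se = as.list(fit$se), n_at_risk = fit$n_at_risk,
              n_deaths = fit$n_deaths, converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a landmark Cox fit from JSON
#' @param path file written by [write_landmark_model()].
#' @return a `"landmark_fit"`.
#' @export
read_landmark_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(landmark_time = l$landmark_time,
                 hazard = hazard_from_list(l$hazard),
                 beta = unlist(l$beta), se = unlist(l$se),
                 n_at_risk = l$n_at_risk, n_deaths = l$n_deaths,
                 converged = l$converged),
            class = "landmark_fit")
}

#' Write a simulation scenario (true parameters + config) to YAML
#' @param scenario list with `true` and `config` as returned by
#'   [simulation_scenario()].
#' @param path output file.
#' @export
write_scenario <- function(scenario, path) {
  obj <- list(
    true = list(theta = scenario$true$theta, alpha = scenario$true$alpha,
                beta_rec = as.list(stats::setNames(scenario$true$beta_rec,
                                                   DESIGN_COLUMNS)),
                beta_death = as.list(stats::setNames(scenario$true$beta_death,
                                                     DESIGN_COLUMNS)),
                base_rec = hazard_to_list(scenario$true$base_rec),
                base_death = hazard_to_list(scenario$true$base_death)),
    config = unclass(scenario$config))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a simulation scenario from YAML
#' @param path file written by [write_scenario()].
#' @return list with `true` (`"true_params"`) and `config` (`"sim_config"`).
#' @export
read_scenario <- function(path) {
  l <- yaml::read_yaml(path)
  tp <- true_params(theta = l$true$theta, alpha = l$true$alpha,
                    beta_rec = unlist(l$true$beta_rec),
                    beta_death = unlist(l$true$beta_death),
                    base_rec = hazard_from_list(l$true$base_rec),
                    base_death = hazard_from_list(l$true$base_death))
  cf <- l$config
  cf$covariate_frequencies$age <-
    stats::setNames(unlist(cf$covariate_frequencies$age), AGE_LEVELS)
  cf$covariate_frequencies$grade <-
    stats::setNames(unlist(cf$covariate_frequencies$grade), GRADE_LEVELS)
  cfg <- sim_config(n_subjects = cf$n_subjects,
                    covariate_frequencies = cf$covariate_frequencies,
                    admin_censoring = cf$admin_censoring,
                    early_censoring_fraction = cf$early_censoring_fraction,
                    early_censoring_window = unlist(cf$early_censoring_window),
                    recording_truncation_time = cf$recording_truncation_time,
                    seed = cf$seed)
  list(true = tp, config = cfg)
}
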