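# Dynamic conditional predictions of death over (s, s+w].
#
# Three settings:
#   * rec — joint model, conditioning on the relapse history up to s
#            (J relapses, last at X_J, and no (J+1)-th relapse by s);
#   * ign — joint model, relapse history ignored (only survival to s);
#   * lm  — landmark Cox model fitted at s, relapse count as covariate.
# The first two are ratios of frailty integrals evaluated by quadrature in
# the log domain (the u^J term underflows otherwise).

#' Conditional survival of the death process given the frailty
#'
#' `S^D(t | z, u) = exp(-u^alpha Lambda_0^D(t) exp(beta_death' z))`.
#'
#' @param params joint-model parameters (see [subject_conditional_loglik()]).
#' @param covariates 1-row data.frame (or design vector via `z`).
#' @param t time (years from origin).
#' @param u frailty value(s).
#' @return survival probabilities, one per element of `u`.
#' @export
conditional_survival_death <- function(params, covariates, t, u) {
  p <- normalize_params(params)
  z <- if (is.numeric(covariates)) covariates
       else drop(covariate_matrix(covariates))
  exp(-u^p$alpha * eval_cumulative(p$hdeath, t) * exp(sum(p$beta_death * z)))
}

#' Conditional survival of the next-recurrence process given the frailty
#'
#' Probability that the (J+1)-th relapse has not occurred by `s` given the
#' J-th happened at `last_relapse` (0 if none), on the calendar timescale:
#' `exp(-u [Lambda_0^R(s) - Lambda_0^R(X_J)] exp(beta_rec' z))`.
#'
#' @inheritParams conditional_survival_death
#' @param s prediction time.
#' @param last_relapse calendar time of the last relapse before `s` (0 when
#'   the subject has no relapse).
#' @export
conditional_survival_next_recurrence <- function(params, covariates, s,
                                                 last_relapse, u) {
  if (last_relapse > s) stop("last relapse time exceeds the prediction time")
  p <- normalize_params(params)
  z <- if (is.numeric(covariates)) covariates
       else drop(covariate_matrix(covariates))
  dLam <- eval_cumulative(p$hrec, s) - eval_cumulative(p$hrec, last_relapse)
  exp(-u * dLam * exp(sum(p$beta_rec * z)))
}

# Shared log-domain engine for the two joint-model predictions. Returns the
# probability of death in (s, s+w] conditional on survival to s, the number
# of past relapses J and (for setting rec) no further relapse by s.
joint_prediction <- function(p, z, s, w, J, last_relapse, use_history, rule) {
  lpD <- sum(p$beta_death * z)
  LamD_s <- eval_cumulative(p$hdeath, s) * exp(lpD)
  LamD_sw <- eval_cumulative(p$hdeath, s + w) * exp(lpD)
  u <- rule$u
  logu <- log(u)
  ua <- u^p$alpha
  history <- if (use_history) {
    lpR <- sum(p$beta_rec * z)
    dLamR <- (eval_cumulative(p$hrec, s) -
                eval_cumulative(p$hrec, last_relapse)) * exp(lpR)
    J * logu - u * dLamR
  } else 0
  A <- -ua * LamD_s                       # log S^D(s | u)
  B <- -ua * LamD_sw                      # log S^D(s+w | u)
  C <- history + rule$logw
  log_den <- logsumexp(A + C)
  if (log_den < log(1e-300))
    stop("degenerate history: frailty integral underflows")
  # log(e^A - e^B) = A + log(1 - e^(B-A)), B <= A
  diffBA <- pmin(B - A, 0)
  log_diff <- ifelse(diffBA == 0, -Inf, A + log(-expm1(diffBA)))
  log_num <- logsumexp(log_diff + C)
  min(max(exp(log_num - log_den), 0), 1)
}

#' Dynamic prediction of death using the relapse history
#'
#' The conditional probability of death in `(s, s+w]` given survival to `s`,
#' the baseline covariates, and the relapse history up to `s` (`J` relapses
#' at times `<= s`, none between the last one and `s`). Evaluated as a ratio
#' of gamma-frailty integrals by quadrature.
#'
#' @param params joint-model parameters.
#' @param covariates 1-row data.frame or design vector.
#' @param relapse_times relapse calendar times `<= s` (empty vector for no
#'   relapse).
#' @param s prediction time (`>= 0`); the subject is known alive at `s`.
#' @param w prediction window (`> 0`).
#' @param rule optional `"gamma_quadrature"`.
#' @return list with `probability`, `setting = "rec"`, `s`, `w`, `J`.
#' @export
predict_rec <- function(params, covariates, relapse_times, s, w, rule = NULL) {
  stopifnot(s >= 0, w > 0)
  if (length(relapse_times) && any(relapse_times > s))
    stop("relapse history contains times after the prediction time s")
  p <- normalize_params(params)
  if (is.null(rule)) rule <- prediction_quadrature(p$theta, p$alpha)
  z <- if (is.numeric(covariates)) covariates
       else drop(covariate_matrix(covariates))
  J <- length(relapse_times)
  lastX <- if (J) max(relapse_times) else 0
  prob <- joint_prediction(p, z, s, w, J, lastX, use_history = TRUE, rule)
  list(probability = prob, setting = "rec", s = s, w = w, J = J)
}

#' Dynamic prediction of death ignoring the relapse history
#'
#' Same conditional probability as [predict_rec()] but with the relapse
#' information dropped from the conditioning (only survival to `s` and the
#' baseline covariates are used); the relapse process still shaped the fitted
#' parameters.
#'
#' @inheritParams predict_rec
#' @return list with `probability`, `setting = "ign"`, `s`, `w`.
#' @export
predict_ign <- function(params, covariates, s, w, rule = NULL) {
  stopifnot(s >= 0, w > 0)
  p <- normalize_params(params)
  if (is.null(rule)) rule <- prediction_quadrature(p$theta, p$alpha)
  z <- if (is.numeric(covariates)) covariates
       else drop(covariate_matrix(covariates))
  prob <- joint_prediction(p, z, s, w, J = 0, last_relapse = 0,
                           use_history = FALSE, rule)
  list(probability = prob, setting = "ign", s = s, w = w)
}

#' Dynamic prediction of death from a landmark Cox fit
#'
#' `[S(s) - S(s+w)] / S(s)` under the landmark model's spline baseline and
#' coefficients; the relapse history enters only through the previous-
#' relapse-count indicators.
#'
#' @param fit a `"landmark_fit"` (see [fit_landmark_cox()]).
#' @param covariates 1-row data.frame with the baseline covariates.
#' @param n_prev_rec number of relapses at or before the landmark time.
#' @param s prediction time; must equal `fit$landmark_time`.
#' @param w prediction window.
#' @return list with `probability`, `setting = "lm"`, `s`, `w`.
#' @export
predict_lm <- function(fit, covariates, n_prev_rec, s, w) {
  stopifnot(w > 0)
  if (abs(s - fit$landmark_time) > 1e-9)
    stop("prediction time ", s, " does not match the landmark time ",
         fit$landmark_time, "; fit a landmark model at s")
  z <- c(drop(covariate_matrix(covariates)),
         rec1 = as.numeric(n_prev_rec == 1),
         rec2plus = as.numeric(n_prev_rec >= 2))
  lp <- sum(fit$beta * z)
  # baseline cumulative hazard measured from s
  Lam <- eval_cumulative(fit$hazard, w)
  prob <- -expm1(-exp(lp) * Lam)
  list(probability = min(max(prob, 0), 1), setting = "lm", s = s, w = w)
}

#' Predictions for every at-risk subject of a cohort
#'
#' Vectorized driver used by the validation layer: for each subject with
#' follow-up beyond `s`, computes the chosen prediction setting from their
#' covariates and relapse history truncated at `s`.
#'
#' @param object a `"joint_frailty_fit"` / `"true_params"` (settings
#'   `"rec"`, `"ign"`) or a `"landmark_fit"` (setting `"lm"`).
#' @param x a `"cohort"`.
#' @param s prediction time.
#' @param w prediction window.
#' @param setting `"rec"`, `"ign"` or `"lm"`.
#' @param rule optional quadrature rule (joint settings).
#' @return data.frame `id, s, w, setting, probability` for subjects with
#'   `followup_time > s`.
#' @export
predict_death <- function(object, x, s, w, setting = c("rec", "ign", "lm"),
                          rule = NULL) {
  setting <- match.arg(setting)
  at_risk <- which(x$subjects$followup_time > s)
  if (!length(at_risk)) stop("no subjects at risk at s = ", s)
  subj <- x$subjects[at_risk, , drop = FALSE]
  Z <- covariate_matrix(subj)
  probs <- numeric(nrow(subj))
  if (setting == "lm") {
    nprev <- n_relapses(x, before = s)[at_risk]
    for (i in seq_len(nrow(subj)))
      probs[i] <- predict_lm(object, subj[i, , drop = FALSE], nprev[i],
                             s, w)$probability
  } else {
    p <- normalize_params(object)
    if (is.null(rule)) rule <- prediction_quadrature(p$theta, p$alpha)
    for (i in seq_len(nrow(subj))) {
      if (setting == "rec") {
        rt <- relapse_times(x, subj$id[i])
        rt <- rt[rt <= s]
        probs[i] <- predict_rec(p, Z[i, ], rt, s, w, rule)$probability
      } else {
        probs[i] <- predict_ign(p, Z[i, ], s, w, rule)$probability
      }
    }
  }
  data.frame(id = subj$id, s = s, w = w, setting = setting,
             probability = probs)
}
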