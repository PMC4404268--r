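# External validation machinery: IPCW Brier prediction-error curves,
# explained-variation R^2 against the Kaplan-Meier reference, and decile
# calibration tables.

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Reverse Kaplan-Meier: the "event" is censoring (death indicator flipped),
#' deaths act as censorings of the censoring process. At tied times deaths
#' precede censorings (standard convention). Used to build the IPCW weights.
#'
#' @param x a `"cohort"`.
#' @return object of class `"censoring_km"` with step times and values;
#'   evaluate with [eval_censoring()].
#' @export
censoring_km <- function(x) {
  s <- x$subjects
  fit <- survival::survfit(survival::Surv(s$followup_time, 1 - s$death) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "censoring_km")
}

#' Evaluate a censoring survival curve
#'
#' @param G a `"censoring_km"` (or any list with `time`, `surv` steps).
#' @param t evaluation times.
#' @param left evaluate the left limit `G(t-)` instead of `G(t)`.
#' @return right-continuous step-function values; 1 before the first step.
#' @export
eval_censoring <- function(G, t, left = FALSE) {
  idx <- if (left) findInterval(t, G$time, left.open = TRUE)
         else findInterval(t, G$time)
  c(1, G$surv)[idx + 1]
}

#' Inverse-probability-of-censoring weight for one evaluation subject
#'
#' For a subject in the evaluation set (alive and uncensored at `s`):
#' deaths observed by `s+w` are weighted by the inverse conditional censoring
#' survival at their death time (left limit), survivors beyond `s+w` by the
#' inverse conditional censoring survival at `s+w`; subjects censored alive
#' before `s+w` get weight zero.
#'
#' @param time follow-up time(s) `T`, all `> s`.
#' @param death death indicator(s).
#' @param s,w prediction time and window.
#' @param G a `"censoring_km"`.
#' @return weights `h_i`.
#' @export
ipcw_weight <- function(time, death, s, w, G) {
  if (any(time <= s)) stop("evaluation subjects must have follow-up > s")
  Gs <- eval_censoring(G, s)
  Gsw <- eval_censoring(G, s + w)
  Gt <- eval_censoring(G, time, left = TRUE)
  w1 <- as.numeric(time <= s + w) * death
  w2 <- as.numeric(time > s + w)
  if (any(w1 > 0 & Gt <= 0))
    stop("censoring survival is zero at an observed death time; ",
         "IPCW positivity violated")
  if (any(w2 > 0) && Gsw <= 0)
    stop("censoring survival is zero at s + w = ", s + w,
         "; IPCW positivity violated")
  out <- numeric(length(time))
  out[w1 > 0] <- Gs / Gt[w1 > 0]
  out[w2 > 0] <- out[w2 > 0] + Gs / Gsw
  out
}

#' IPCW Brier prediction error at (s, w)
#'
#' `Err = (1/N_s) sum_i [ I(T_i > s+w) - (1 - P_i) ]^2 h_i` over the `N_s`
#' subjects alive and uncensored at `s`, with IPCW weights `h_i` from
#' [ipcw_weight()]. With no censoring every weight is 1 and this is the
#' plain mean squared error of the predicted death status.
#'
#' @param predictions predicted death probabilities over `(s, s+w]`, one per
#'   evaluation subject, in `[0, 1]`.
#' @param time,death follow-up and death indicator of the same subjects.
#' @param s,w prediction time and window.
#' @param G a `"censoring_km"` estimated on the evaluation sample.
#' @return list with `err`, `n` (= `N_s`).
#' @export
brier_error <- function(predictions, time, death, s, w, G) {
  if (any(predictions < 0 | predictions > 1))
    stop("predictions must lie in [0, 1]")
  if (length(predictions) != length(time))
    stop("one prediction per subject required")
  h <- ipcw_weight(time, death, s, w, G)
  err <- mean((as.numeric(time > s + w) - (1 - predictions))^2 * h)
  list(err = err, n = length(time))
}

#' Reference prediction error of the Kaplan-Meier predictor
#'
#' The same IPCW Brier error with every subject given the cohort-level
#' Kaplan-Meier conditional death probability between `s` and `s+w`
#' (estimated on the entire cohort, no covariates).
#'
#' @param x the evaluation `"cohort"`.
#' @param s,w prediction time and window.
#' @param G a `"censoring_km"`; default: estimated on `x`.
#' @return list with `err`, `n`, and the KM death probability `p_km`.
#' @export
km_reference_error <- function(x, s, w, G = censoring_km(x)) {
  subj <- x$subjects
  fit <- survival::survfit(survival::Surv(subj$followup_time, subj$death) ~ 1)
  Ss <- eval_censoring(fit, s)        # step evaluation works for any KM
  Ssw <- eval_censoring(fit, s + w)
  if (Ss <= 0) stop("Kaplan-Meier survival is zero at s = ", s)
  p_km <- 1 - Ssw / Ss
  at_risk <- subj$followup_time > s
  res <- brier_error(rep(p_km, sum(at_risk)), subj$followup_time[at_risk],
                     subj$death[at_risk], s, w, G)
  c(res, list(p_km = p_km))
}

#' Explained residual variation
#'
#' `R^2 = 1 - Err / Err_KM`: the fraction by which the model's prediction
#' error undercuts the covariate-free Kaplan-Meier prediction. Can be
#' negative when the model predicts worse than the average.
#'
#' @param err model prediction error.
#' @param err_km Kaplan-Meier reference error (`> 0`).
#' @return scalar, at most 1; `NA` with a warning when `err_km = 0`.
#' @export
r_squared <- function(err, err_km) {
  if (err_km <= 0) {
    warning("Kaplan-Meier reference error is zero; R^2 undefined")
    return(NA_real_)
  }
  1 - err / err_km
}

#' Prediction-error curves over a grid of (s, w)
#'
#' Evaluates the IPCW Brier error, its Kaplan-Meier reference, and R^2 for
#' the requested settings at every combination of the supplied prediction
#' times and windows (fix `s` and vary `w`, or the reverse, by passing a
#' scalar and a vector). For the landmark setting a model is (re)fitted at
#' each distinct `s` through `landmark_fitter`.
#'
#' @param x the evaluation `"cohort"`.
#' @param joint a `"joint_frailty_fit"` (or `"true_params"`) for settings
#'   `"rec"` and `"ign"`; may be `NULL` if only `"lm"` is requested.
#' @param landmark_fitter function `s -> "landmark_fit"` (typically fitting
#'   on the development cohort); required for setting `"lm"`.
#' @param settings subset of `c("rec", "ign", "lm")`.
#' @param s,w numeric vectors of prediction times and windows.
#' @param G optional `"censoring_km"` (default: estimated on `x`).
#' @return data.frame with columns `setting, s, w, n, err, err_km, r2`.
#' @export
prediction_error_curve <- function(x, joint = NULL, landmark_fitter = NULL,
                                   settings = c("rec", "ign"),
                                   s, w, G = censoring_km(x)) {
  stopifnot(all(settings %in% c("rec", "ign", "lm")))
  if (any(c("rec", "ign") %in% settings) && is.null(joint))
    stop("settings 'rec'/'ign' need a joint model")
  if ("lm" %in% settings && is.null(landmark_fitter))
    stop("setting 'lm' needs a landmark_fitter function")
  lm_fits <- list()
  out <- list()
  for (si in s) {
    at_risk <- sum(x$subjects$followup_time > si)
    if (at_risk == 0) {
      warning("empty risk set at s = ", si, "; point skipped")
      next
    }
    if ("lm" %in% settings)
      lm_fits[[as.character(si)]] <- landmark_fitter(si)
    for (wi in w) {
      ref <- km_reference_error(x, si, wi, G)
      for (set in settings) {
        model <- if (set == "lm") lm_fits[[as.character(si)]] else joint
        pr <- predict_death(model, x, si, wi, setting = set)
        sel <- x$subjects$followup_time > si
        be <- brier_error(pr$probability, x$subjects$followup_time[sel],
                          x$subjects$death[sel], si, wi, G)
        out[[length(out) + 1]] <- data.frame(
          setting = set, s = si, w = wi, n = be$n, err = be$err,
          err_km = ref$err, r2 = r_squared(be$err, ref$err))
      }
    }
  }
  do.call(rbind, out)
}

#' Decile calibration table at (s, s+w)
#'
#' Groups the evaluation subjects by deciles of their predicted death risk;
#' for each decile reports the mean predicted risk and the observed death
#' proportion between `s` and `s+w`, estimated by a conditional Kaplan-Meier
#' within the decile (which reduces to the raw proportion when nobody is
#' censored before `s+w`), with a 95% confidence interval (Greenwood on the
#' KM scale; Wilson score when censoring-free). A histogram of the predicted
#' values in 5%-wide bins is attached as an attribute.
#'
#' @param predictions predicted death probabilities for subjects alive and
#'   uncensored at `s`.
#' @param time,death their follow-up times and death indicators.
#' @param s,w prediction time and window.
#' @return data.frame of class `"calibration_table"` with columns
#'   `decile, n, mean_pred, obs_prop, lower, upper`; attribute `"histogram"`
#'   (counts in `seq(0, 1, 0.05)` bins), attribute `"s"`, `"w"`.
#' @export
calibration_table <- function(predictions, time, death, s, w) {
  if (any(predictions < 0 | predictions > 1))
    stop("predictions must lie in [0, 1]")
  if (any(time <= s)) stop("evaluation subjects must have follow-up > s")
  breaks <- unique(stats::quantile(predictions, probs = 0:10 / 10, type = 7))
  if (length(breaks) < 3) {
    warning("predicted values nearly identical; calibration groups collapsed")
    breaks <- unique(c(min(predictions) - 1e-12, breaks, max(predictions)))
  }
  grp <- cut(predictions, breaks = breaks, include.lowest = TRUE)
  rows <- lapply(levels(grp), function(g) {
    sel <- grp == g
    n <- sum(sel)
    ti <- time[sel]
    de <- death[sel]
    censored_in_window <- any(ti <= s + w & de == 0)
    if (censored_in_window) {
      fit <- survival::survfit(survival::Surv(ti, de) ~ 1, conf.type = "log")
      idx <- findInterval(s + w, fit$time)
      if (idx == 0) {
        obs <- 0; lo <- 0; hi <- 0
      } else {
        obs <- 1 - fit$surv[idx]
        lo <- 1 - min(fit$upper[idx], 1)
        hi <- 1 - max(fit$lower[idx], 0)
        if (is.na(lo)) lo <- 0
        if (is.na(hi)) hi <- 1
      }
    } else {
      k <- sum(ti <= s + w & de == 1)
      ci <- wilson_ci(k, n)
      obs <- k / n
      lo <- ci[1]; hi <- ci[2]
    }
    data.frame(decile = g, n = n, mean_pred = mean(predictions[sel]),
               obs_prop = obs, lower = lo, upper = hi)
  })
  out <- do.call(rbind, rows)
  hist_counts <- table(cut(predictions, breaks = seq(0, 1, 0.05),
                           include.lowest = TRUE))
  structure(out, histogram = hist_counts, s = s, w = w,
            class = c("calibration_table", "data.frame"))
}

# 95% Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, z = stats::qnorm(0.975)) {
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}
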