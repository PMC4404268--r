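# Landmark Cox model: at a chosen prediction time s, keep the subjects still
# alive and uncensored, summarize their relapse history as the number of
# previous relapses (0 / 1 / 2+), and fit a proportional-hazards model for
# death on t >= s with an M-spline baseline by penalized full likelihood.
# Relapses after s are ignored by construction.

#' Build the landmark dataset at time s
#'
#' Keeps subjects with follow-up strictly beyond `s` (alive and uncensored at
#' `s`) and attaches the relapse-count covariate `n_prev_rec = #\{X_ij <= s\}`
#' together with its indicator coding (`rec1`, `rec2plus`; reference: no
#' previous relapse). Outcome time and death indicator are unchanged;
#' relapses after `s` are not looked at.
#'
#' @param x a `"cohort"`.
#' @param s landmark time (`>= 0`).
#' @return data.frame with the subject columns, `n_prev_rec`, `rec1`,
#'   `rec2plus`; attribute `"landmark_time"`.
#' @export
build_landmark_dataset <- function(x, s) {
  stopifnot(s >= 0)
  keep <- x$subjects$followup_time > s
  if (!any(keep)) stop("empty risk set at landmark time s = ", s)
  d <- x$subjects[keep, , drop = FALSE]
  nprev <- n_relapses(x, before = s)[keep]
  d$n_prev_rec <- nprev
  d$rec1 <- as.numeric(nprev == 1)
  d$rec2plus <- as.numeric(nprev >= 2)
  rownames(d) <- NULL
  attr(d, "landmark_time") <- s
  d
}

#' Control parameters for [fit_landmark_cox()]
#'
#' @param n_basis number of M-spline basis functions for the baseline.
#' @param kappa curvature-penalty smoothing parameter.
#' @param maxit,reltol,grad_tol optimizer settings (see [joint_control()]).
#' @return list of class `"landmark_control"`.
#' @export
landmark_control <- function(n_basis = 7, kappa = 1e3, maxit = 500,
                             reltol = 1e-10, grad_tol = 1e-4) {
  structure(list(n_basis = n_basis, kappa = kappa, maxit = maxit,
                 reltol = reltol, grad_tol = grad_tol),
            class = "landmark_control")
}

#' Fit the landmark Cox model at time s by penalized full likelihood
#'
#' Proportional-hazards model for death on `t >= s` with spline baseline
#' hazard, fitted to the landmark dataset: the likelihood conditions on
#' survival to `s` (left truncation), which the baseline handles by living on
#' `[s, t_max]` with cumulative hazard zero at `s`. Covariates are the five
#' baseline prognostic factors plus the previous-relapse-count indicators.
#'
#' @param data a landmark dataset from [build_landmark_dataset()].
#' @param control a [landmark_control()].
#' @return object of class `"landmark_fit"`: `landmark_time`, `hazard` (a
#'   `"spline_hazard"` on the time-since-landmark scale), named `beta` with
#'   `se`, `n_at_risk`, `n_deaths`, `converged`, penalized log-likelihood.
#' @export
fit_landmark_cox <- function(data, control = landmark_control()) {
  s <- attr(data, "landmark_time")
  if (is.null(s)) stop("data must come from build_landmark_dataset()")
  if (sum(data$death) < 1) stop("no deaths after the landmark time")
  X <- cbind(covariate_matrix(data), rec1 = data$rec1,
             rec2plus = data$rec2plus)
  # work on the time-since-landmark scale: tau = T - s in (0, t_max - s]
  tau <- data$followup_time - s
  delta <- data$death
  t_max <- max(tau)
  basis <- spline_basis(t_max, control$n_basis, times = tau[delta == 1])
  m <- control$n_basis
  p <- ncol(X)
  drows <- which(delta == 1)
  B_ev <- basis_matrix(basis, tau[drows])
  I_tau <- ibasis_matrix(basis, tau)
  P <- penalty_matrix(basis)
  n <- nrow(data)
  idx <- list(z = 1:m, b = m + 1:p)

  fn <- function(par) {
    eta <- par[idx$z]^2
    beta <- par[idx$b]
    lam <- drop(B_ev %*% eta)
    Lam <- drop(I_tau %*% eta)
    lp <- drop(X %*% beta)
    ll <- sum(log(pmax(lam, 1e-300)) + lp[drows]) - sum(exp(lp) * Lam)
    pen <- control$kappa * drop(t(eta) %*% P %*% eta)
    out <- -(ll - pen) / n
    if (!is.finite(out)) 1e10 else out
  }
  gr <- function(par) {
    eta <- par[idx$z]^2
    beta <- par[idx$b]
    lam <- drop(B_ev %*% eta)
    Lam <- drop(I_tau %*% eta)
    elp <- exp(drop(X %*% beta))
    g <- numeric(length(par))
    d_eta <- colSums(B_ev / pmax(lam, 1e-300)) - drop(t(I_tau) %*% elp) -
      2 * control$kappa * drop(P %*% eta)
    g[idx$z] <- 2 * par[idx$z] * d_eta
    g[idx$b] <- drop(t(X) %*% (delta - elp * Lam))
    -g / n
  }

  rate <- sum(delta) / sum(tau)
  par0 <- c(sqrt(constant_hazard_coefs(basis, rate)), rep(0, p))
  cx <- try(suppressWarnings(
    survival::coxph(survival::Surv(tau, delta) ~ X)), silent = TRUE)
  if (!inherits(cx, "try-error") && all(is.finite(stats::coef(cx))))
    par0[idx$b] <- unname(stats::coef(cx))
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  par <- opt$par
  grad <- gr(par)
  converged <- opt$convergence == 0 && max(abs(grad)) < control$grad_tol
  se <- rep(NA_real_, p)
  H <- try(stats::optimHess(par, fn, gr), silent = TRUE)
  if (!inherits(H, "try-error")) {
    cv <- try(solve(H * n), silent = TRUE)
    if (!inherits(cv, "try-error") && all(diag(cv)[idx$b] > 0))
      se <- sqrt(diag(cv)[idx$b])
    else warning("singular Hessian in landmark fit; SEs unavailable")
  }
  nm <- c(DESIGN_COLUMNS, "rec1", "rec2plus")
  structure(list(landmark_time = s,
                 hazard = spline_hazard(basis, par[idx$z]^2),
                 beta = stats::setNames(par[idx$b], nm),
                 se = stats::setNames(se, nm),
                 n_at_risk = n, n_deaths = sum(delta),
                 converged = converged, loglik_pen = -fn(par) * n,
                 control = control),
            class = "landmark_fit")
}

#' @export
print.landmark_fit <- function(x, ...) {
  cat("Landmark Cox model at s =", x$landmark_time, "years\n")
  cat("  at risk:", x$n_at_risk, " deaths:", x$n_deaths,
      " converged:", x$converged, "\n")
  print(round(data.frame(HR = exp(x$beta), se = x$se), 3))
  invisible(x)
}
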