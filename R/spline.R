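# M-spline / I-spline machinery for baseline hazards.
#
# Hazards are modelled as lambda_0(t) = sum_i eta_i M_i(t) with M-splines of
# order 4 (cubic) on [0, t_max]: each M_i is non-negative and integrates to 1
# over its support, so eta_i >= 0 guarantees a valid hazard. The cumulative
# hazard uses the integrated basis and the smoothness penalty is the exact
# Gram matrix of second derivatives.

#' Cubic M-spline basis on [0, t_max]
#'
#' @param t_max upper boundary knot (years); lower boundary is 0.
#' @param n_basis number of basis functions `m`; the number of interior knots
#'   is `m - order`.
#' @param order spline order (4 = cubic, the default).
#' @param times optional event times; interior knots are placed at equally
#'   spaced quantiles of `times` (default: equally spaced on `[0, t_max]`).
#' @return object of class `"spline_basis"` with the augmented knot vector.
#' @export
spline_basis <- function(t_max, n_basis = 7, order = 4, times = NULL) {
  stopifnot(t_max > 0, n_basis >= order)
  n_int <- n_basis - order
  if (n_int > 0) {
    if (!is.null(times)) {
      times <- times[times > 0 & times < t_max]
      probs <- seq_len(n_int) / (n_int + 1)
      interior <- unname(stats::quantile(times, probs, type = 7))
      # guard against ties / boundary collisions
      interior <- pmin(pmax(interior, t_max * 1e-6), t_max * (1 - 1e-6))
      if (any(diff(interior) <= 0))
        interior <- seq(0, t_max, length.out = n_int + 2)[-c(1, n_int + 2)]
    } else {
      interior <- seq(0, t_max, length.out = n_int + 2)[-c(1, n_int + 2)]
    }
  } else interior <- numeric(0)
  knots <- c(rep(0, order), interior, rep(t_max, order))
  structure(list(order = order, n_basis = n_basis, t_max = t_max,
                 interior = interior, knots = knots),
            class = "spline_basis")
}

check_domain <- function(basis, t) {
  eps <- basis$t_max * 1e-12
  if (any(t < -eps) || any(t > basis$t_max + eps))
    stop("time outside the spline domain [0, ", basis$t_max,
         "]; refusing to extrapolate")
  pmin(pmax(t, 0), basis$t_max)
}

#' Evaluate the M-spline basis
#'
#' @param basis a `"spline_basis"`.
#' @param t evaluation times in `[0, t_max]`.
#' @return matrix `length(t) x n_basis`; row sums of the underlying B-splines
#'   are rescaled so each column integrates to one over its support.
#' @export
basis_matrix <- function(basis, t) {
  t <- check_domain(basis, t)
  k <- basis$order
  kn <- basis$knots
  # splineDesign drops the point t = t_max from the last B-spline's support;
  # nudge inside
  tt <- pmin(t, basis$t_max * (1 - 1e-12))
  B <- splines::splineDesign(kn, tt, ord = k)
  scale <- k / (kn[seq_len(basis$n_basis) + k] - kn[seq_len(basis$n_basis)])
  sweep(B, 2, scale, `*`)
}

# Gauss-Legendre nodes on [a, b]
gl_nodes <- function(q, a, b) {
  g <- pracma::gaussLegendre(q, a, b)
  list(x = g$x, w = g$w)
}

# Exact full-interval integrals of each basis function: rows = inter-knot
# intervals, cols = basis functions (3-point Gauss-Legendre, exact for cubics)
interval_integrals <- function(basis) {
  br <- unique(c(0, basis$interior, basis$t_max))
  F <- matrix(0, length(br) - 1, basis$n_basis)
  for (j in seq_len(length(br) - 1)) {
    g <- gl_nodes(3, br[j], br[j + 1])
    F[j, ] <- colSums(basis_matrix(basis, g$x) * g$w)
  }
  list(breaks = br, F = F)
}

#' Evaluate the integrated (I-spline) basis
#'
#' Column `i` holds `I_i(t) = \int_0^t M_i(u) du`, so the cumulative hazard is
#' the matrix product with the coefficient vector. Exact piecewise-polynomial
#' integration (Gauss-Legendre per knot interval).
#'
#' @inheritParams basis_matrix
#' @return matrix `length(t) x n_basis`, zero at `t = 0`, entries in `[0, 1]`.
#' @export
ibasis_matrix <- function(basis, t) {
  t <- check_domain(basis, t)
  ii <- interval_integrals(basis)
  br <- ii$breaks
  cumF <- rbind(0, apply(ii$F, 2, cumsum))  # integral up to each break
  out <- matrix(0, length(t), basis$n_basis)
  j_of <- findInterval(t, br, rightmost.closed = TRUE)
  j_of <- pmin(pmax(j_of, 1L), length(br) - 1L)
  for (j in unique(j_of)) {
    sel <- which(j_of == j)
    base <- matrix(cumF[j, ], length(sel), basis$n_basis, byrow = TRUE)
    for (s in seq_along(sel)) {
      tt <- t[sel[s]]
      if (tt > br[j]) {
        g <- gl_nodes(3, br[j], tt)
        base[s, ] <- base[s, ] + colSums(basis_matrix(basis, g$x) * g$w)
      }
    }
    out[sel, ] <- base
  }
  out
}

#' Exact curvature-penalty Gram matrix
#'
#' `P[i, j] = \int_0^{t_max} M_i''(t) M_j''(t) dt`, computed exactly
#' (second derivatives of cubics are piecewise linear; 2-point
#' Gauss-Legendre per interval). `P` is symmetric positive semi-definite and
#' its null space contains every coefficient vector representing a linear
#' hazard.
#'
#' @param basis a `"spline_basis"`.
#' @return `n_basis x n_basis` matrix.
#' @export
penalty_matrix <- function(basis) {
  k <- basis$order
  kn <- basis$knots
  m <- basis$n_basis
  scale <- k / (kn[seq_len(m) + k] - kn[seq_len(m)])
  br <- unique(c(0, basis$interior, basis$t_max))
  P <- matrix(0, m, m)
  for (j in seq_len(length(br) - 1)) {
    g <- gl_nodes(2, br[j], br[j + 1])
    x <- pmin(g$x, basis$t_max * (1 - 1e-12))
    D2 <- splines::splineDesign(kn, x, ord = k, derivs = rep(2L, length(x)))
    D2 <- sweep(D2, 2, scale, `*`)
    P <- P + t(D2) %*% (D2 * g$w)
  }
  (P + t(P)) / 2
}

# ---------------------------------------------------------------------------
# Baseline hazard objects. Spline hazards come out of fitting; parametric
# (Weibull, piecewise-constant) hazards drive the synthetic-data generator and
# serve as analytic references in tests. All respond to eval_hazard(),
# eval_cumulative() and (parametric only) inv_cumulative().

#' Spline baseline hazard
#' @param basis a `"spline_basis"`.
#' @param eta non-negative coefficient vector of length `n_basis`.
#' @return object of class `c("spline_hazard", "baseline_hazard")`.
#' @export
spline_hazard <- function(basis, eta) {
  stopifnot(length(eta) == basis$n_basis)
  if (any(eta < 0)) stop("spline hazard coefficients must be non-negative")
  structure(list(basis = basis, eta = as.numeric(eta)),
            class = c("spline_hazard", "baseline_hazard"))
}

#' Weibull baseline hazard
#' @param shape,scale Weibull shape and scale; the cumulative hazard is
#'   `(t / scale)^shape`.
#' @return object of class `c("weibull_hazard", "baseline_hazard")`.
#' @export
weibull_hazard <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale),
            class = c("weibull_hazard", "baseline_hazard"))
}

#' Piecewise-constant baseline hazard
#' @param cuts left endpoints of the pieces, starting at 0; the last piece
#'   extends to infinity.
#' @param values strictly positive hazard value on each piece.
#' @return object of class `c("piecewise_hazard", "baseline_hazard")`.
#' @export
piecewise_hazard <- function(cuts, values) {
  stopifnot(cuts[1] == 0, length(cuts) == length(values), all(values >= 0),
            !is.unsorted(cuts, strictly = TRUE))
  structure(list(cuts = cuts, values = values),
            class = c("piecewise_hazard", "baseline_hazard"))
}

#' Constant baseline hazard
#' @param rate hazard per year.
#' @export
constant_hazard <- function(rate) piecewise_hazard(0, rate)

#' Evaluate a baseline hazard
#' @param h a `"baseline_hazard"`.
#' @param t times.
#' @return `lambda_0(t)`.
#' @export
eval_hazard <- function(h, t) UseMethod("eval_hazard")

#' @export
eval_hazard.spline_hazard <- function(h, t) {
  drop(basis_matrix(h$basis, t) %*% h$eta)
}

#' @export
eval_hazard.weibull_hazard <- function(h, t) {
  (h$shape / h$scale) * (pmax(t, 0) / h$scale)^(h$shape - 1)
}

#' @export
eval_hazard.piecewise_hazard <- function(h, t) {
  h$values[findInterval(t, h$cuts)]
}

#' Evaluate a cumulative baseline hazard
#' @inheritParams eval_hazard
#' @return `Lambda_0(t) = \int_0^t lambda_0`.
#' @export
eval_cumulative <- function(h, t) UseMethod("eval_cumulative")

#' @export
eval_cumulative.spline_hazard <- function(h, t) {
  drop(ibasis_matrix(h$basis, t) %*% h$eta)
}

#' @export
eval_cumulative.weibull_hazard <- function(h, t) (pmax(t, 0) / h$scale)^h$shape

#' @export
eval_cumulative.piecewise_hazard <- function(h, t) {
  ends <- c(h$cuts[-1], Inf)
  vapply(t, function(tt) {
    sum(h$values * pmax(0, pmin(tt, ends) - h$cuts))
  }, numeric(1))
}

#' Invert a cumulative baseline hazard
#'
#' Solves `Lambda_0(t) = y` for `t`; used by the simulation engine to draw
#' event times by inversion. Defined for parametric hazards only.
#'
#' @param h a parametric `"baseline_hazard"`.
#' @param y non-negative cumulative-hazard values.
#' @return times `t` with `eval_cumulative(h, t) = y` (`Inf` if unreachable).
#' @export
inv_cumulative <- function(h, y) UseMethod("inv_cumulative")

#' @export
inv_cumulative.weibull_hazard <- function(h, y) h$scale * y^(1 / h$shape)

#' @export
inv_cumulative.piecewise_hazard <- function(h, y) {
  ends <- c(h$cuts[-1], Inf)
  cumH <- cumsum(c(0, h$values * (ends - h$cuts)))[seq_along(h$cuts)]
  vapply(y, function(yy) {
    j <- findInterval(yy, cumH)
    if (h$values[j] == 0) {
      if (yy > cumH[j]) Inf else h$cuts[j]
    } else h$cuts[j] + (yy - cumH[j]) / h$values[j]
  }, numeric(1))
}

#' @export
inv_cumulative.spline_hazard <- function(h, y) {
  stop("inversion of spline hazards is not supported; use a parametric hazard")
}

#' Curvature penalty of a spline hazard
#'
#' `\int (lambda_0''(t))^2 dt = eta' P eta` with `P` from [penalty_matrix()].
#'
#' @param h a `"spline_hazard"`.
#' @return non-negative scalar; 0 iff the hazard is linear in `t`.
#' @export
curvature_penalty <- function(h) {
  drop(t(h$eta) %*% penalty_matrix(h$basis) %*% h$eta)
}

#' Coefficients reproducing a constant hazard
#'
#' M-splines scaled by knot spacing reproduce constants exactly:
#' `eta_i = c (t_{i+k} - t_i) / k` gives `sum eta_i M_i(t) = c`.
#'
#' @param basis a `"spline_basis"`.
#' @param value the constant hazard level.
#' @return coefficient vector of length `n_basis`.
#' @export
constant_hazard_coefs <- function(basis, value) {
  k <- basis$order
  kn <- basis$knots
  i <- seq_len(basis$n_basis)
  value * (kn[i + k] - kn[i]) / k
}

#' Coefficients reproducing a linear hazard a + b t
#'
#' Uses the Greville abscissae of the knot vector; the result is exact while
#' `a + b t >= 0` on the domain.
#'
#' @param basis a `"spline_basis"`.
#' @param a,b intercept and slope.
#' @return coefficient vector of length `n_basis`.
#' @export
linear_hazard_coefs <- function(basis, a, b) {
  k <- basis$order
  kn <- basis$knots
  i <- seq_len(basis$n_basis)
  greville <- vapply(i, function(ii) mean(kn[(ii + 1):(ii + k - 1)]), numeric(1))
  (a + b * greville) * (kn[i + k] - kn[i]) / k
}
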