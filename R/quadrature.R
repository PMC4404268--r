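# Numerical integration over the gamma frailty.
#
# Every marginal quantity in the joint model is an integral
# \int_0^infty f(u) g(u) du against the gamma density g with mean 1 and
# variance theta. A fixed quadrature rule {u_k, w_k} turns it into
# sum_k exp(log w_k) f(u_k); weights are kept on the log scale because the
# integrands routinely underflow (u^J terms, survival products).

#' Gamma frailty density
#'
#' Density of the frailty `u ~ Gamma(1/theta, 1/theta)` (shape, rate), which
#' has mean 1 and variance `theta`:
#' `g(u) = u^(1/theta - 1) exp(-u/theta) / (theta^(1/theta) Gamma(1/theta))`.
#'
#' @param u positive frailty values.
#' @param theta frailty variance, `> 0`.
#' @return density values.
#' @export
gamma_frailty_density <- function(u, theta) {
  if (theta <= 0) stop("theta must be > 0")
  if (any(u <= 0)) stop("frailty values must be > 0")
  stats::dgamma(u, shape = 1 / theta, rate = 1 / theta)
}

#' Quadrature rule for integrals against the gamma frailty density
#'
#' Two constructions are available. `"laguerre"`: a generalized Gauss-Laguerre
#' rule with parameter `a = 1/theta - 1` after the change of variables
#' `u = theta x`, exact for integrands of the form (polynomial in `u`) times
#' `exp(-c u)` against `g` — the family the marginal likelihood lives in.
#' `"quantile"`: Gauss-Legendre on the probability scale with nodes at gamma
#' quantiles, which is markedly more accurate for the bounded prediction
#' integrands when the frailty variance is large (the Laguerre weight becomes
#' sharply singular at zero for `theta > 1`). `"auto"` picks `"laguerre"`
#' unless `theta < 1/150`, where the Laguerre weights overflow and the
#' quantile rule takes over. Likelihood evaluation defaults to `"auto"`;
#' prediction defaults to the quantile rule for `theta >= 0.5`. Weights are
#' returned as logs; `sum(exp(logw)) = 1` up to machine precision, i.e. the
#' rule integrates the density to one.
#'
#' @param theta frailty variance.
#' @param n_nodes number of nodes (default 64).
#' @param method `"auto"` (default), `"laguerre"` or `"quantile"`.
#' @return object of class `"gamma_quadrature"` with fields `u` (nodes),
#'   `logw` (log weights), `theta`, `n_nodes`, `method`.
#' @export
gamma_quadrature <- function(theta, n_nodes = 64, method = c("auto", "laguerre",
                                                             "quantile")) {
  if (theta <= 0) stop("theta must be > 0")
  method <- match.arg(method)
  if (method == "auto") method <- if (theta >= 1 / 150) "laguerre" else "quantile"
  if (method == "laguerre") {
    a <- 1 / theta - 1
    gl <- gauss_laguerre_gw(n_nodes, a)
    u <- theta * gl$x
    logw <- gl$logw
  } else {
    gl <- pracma::gaussLegendre(n_nodes, 0, 1)
    u <- stats::qgamma(gl$x, shape = 1 / theta, rate = 1 / theta)
    logw <- log(gl$w)
  }
  keep <- is.finite(logw) & u > 0
  structure(list(u = u[keep], logw = logw[keep], theta = theta,
                 n_nodes = n_nodes, method = method),
            class = "gamma_quadrature")
}

# default rule for prediction integrands. With a unit power link the
# integrands are (powers of u) times exp(-c u), for which the generalized
# Laguerre rule is exact; otherwise they are bounded smooth functions of u
# for which the quantile-scale rule dominates once the gamma density develops
# its integrable singularity at zero (theta around 1 and beyond).
prediction_quadrature <- function(theta, alpha = NA, n_nodes = 64) {
  laguerre_ok <- theta < 0.5 || (is.finite(alpha) && alpha == 1)
  gamma_quadrature(theta, n_nodes,
                   method = if (laguerre_ok) "laguerre" else "quantile")
}

# default rule for likelihood integrands: (powers of u) x exp(-Lam_R u -
# Lam_D u^alpha). Laguerre-exact at alpha = 1 and excellent while the gamma
# density is bounded; for large theta with a non-unit power link the weight
# singularity at zero degrades it and the quantile rule takes over.
likelihood_quadrature <- function(theta, alpha = NA, n_nodes = 64) {
  laguerre_ok <- theta < 2 || (is.finite(alpha) && alpha == 1)
  gamma_quadrature(theta, n_nodes,
                   method = if (laguerre_ok) "laguerre" else "quantile")
}

# Golub-Welsch construction of the generalized Gauss-Laguerre rule for the
# weight x^a e^(-x), valid for any a > -1 (pracma's version requires a >= 0,
# which excludes theta > 1). Weights are returned as logs normalized to the
# total mass Gamma(a+1), i.e. sum(exp(logw)) = 1: the squared first
# eigenvector components of the Jacobi matrix.
gauss_laguerre_gw <- function(n, a) {
  stopifnot(a > -1, n >= 1)
  k <- seq_len(n) - 1
  diag_J <- 2 * k + a + 1
  off_J <- sqrt(k[-1] * (k[-1] + a))
  J <- matrix(0, n, n)
  J[cbind(seq_len(n), seq_len(n))] <- diag_J
  if (n > 1) {
    J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off_J
    J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off_J
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], logw = 2 * log(abs(e$vectors[1, ord])))
}

#' Integrate a function against the gamma frailty density
#'
#' @param rule a `"gamma_quadrature"`.
#' @param log_f function returning the log integrand at a vector of `u`.
#' @return the log of `\int exp(log_f(u)) g(u) du` (log-sum-exp over nodes).
#' @export
integrate_frailty <- function(rule, log_f) {
  logsumexp(log_f(rule$u) + rule$logw)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix
row_logsumexp <- function(L) {
  m <- apply(L, 1, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(L[ok, , drop = FALSE] - m[ok])))
  out
}
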