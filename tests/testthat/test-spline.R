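test_that("M-spline basis reproduces constants and integrates to one", {
  b <- spline_basis(12, n_basis = 7)
  tt <- c(0.3, 2.7, 5, 8.1, 11.5)
  h <- spline_hazard(b, constant_hazard_coefs(b, 0.37))
  expect_equal(eval_hazard(h, tt), rep(0.37, 5), tolerance = 1e-10)
  # each column of the integrated basis reaches 1 at t_max
  expect_equal(drop(ibasis_matrix(b, b$t_max)), rep(1, 7), tolerance = 1e-10)
  # zero coefficients -> zero hazard
  h0 <- spline_hazard(b, rep(0, 7))
  expect_equal(eval_hazard(h0, tt), rep(0, 5))
  expect_error(eval_hazard(h, 12.5), "domain")
  expect_error(eval_hazard(h, -1), "domain")
})

test_that("cumulative hazard matches adaptive quadrature of the hazard", {
  b <- spline_basis(10, n_basis = 8)
  set.seed(4)
  eta <- rexp(8, 2)
  h <- spline_hazard(b, eta)
  expect_equal(eval_cumulative(h, 0), 0)
  for (tt in c(0.9, 3.7, 6.2, 10)) {
    num <- integrate(function(x) eval_hazard(h, x), 0, tt,
                     rel.tol = 1e-10, subdivisions = 500)$value
    expect_equal(eval_cumulative(h, tt), num, tolerance = 1e-8)
  }
  # constant case: c * t
  hc <- spline_hazard(b, constant_hazard_coefs(b, 0.5))
  expect_equal(eval_cumulative(hc, 7.3), 0.5 * 7.3, tolerance = 1e-10)
  # monotone non-decreasing and differentiates back to the hazard
  tt <- seq(0.5, 9.5, by = 0.5)
  Lam <- eval_cumulative(h, tt)
  expect_true(all(diff(Lam) >= 0))
  eps <- 1e-6
  deriv <- (eval_cumulative(h, tt + eps) - Lam) / eps
  expect_equal(deriv, eval_hazard(h, tt), tolerance = 1e-4)
})

test_that("curvature penalty is exact, PSD, and vanishes on linear hazards", {
  b <- spline_basis(8, n_basis = 7)
  P <- penalty_matrix(b)
  expect_equal(P, t(P))
  expect_true(all(eigen(P, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
  # linear hazards lie in the null space
  lin <- linear_hazard_coefs(b, 0.2, 0.05)
  expect_equal(drop(t(lin) %*% P %*% lin), 0, tolerance = 1e-10)
  expect_equal(curvature_penalty(spline_hazard(b, rep(0, 7))), 0)
  # random coefficients against numeric quadrature of (lambda'')^2
  set.seed(11)
  eta <- rexp(7)
  h <- spline_hazard(b, eta)
  e <- 1e-4
  d2 <- function(x) {
    (eval_hazard(h, x + e) - 2 * eval_hazard(h, x) +
       eval_hazard(h, x - e)) / e^2
  }
  # (lambda'')^2 is a quadratic polynomial on each inter-knot interval, so
  # 3-point Gauss-Legendre per interval is exact; evaluate lambda'' by finite
  # differences, keeping the stencil inside the interval (the third
  # derivative jumps at the knots)
  br <- unique(c(0, b$interior, 8))
  # Gauss-Legendre nodes are interior, so the stencil stays inside each piece
  num <- sum(vapply(seq_len(length(br) - 1), function(j) {
    g <- pracma::gaussLegendre(3, br[j], br[j + 1])
    sum(g$w * d2(g$x)^2)
  }, numeric(1)))
  expect_equal(curvature_penalty(h), num, tolerance = 1e-4)
})

test_that("parametric hazards invert their cumulative hazards", {
  hw <- weibull_hazard(1.4, 20)
  y <- c(0.01, 0.3, 2)
  expect_equal(eval_cumulative(hw, inv_cumulative(hw, y)), y,
               tolerance = 1e-12)
  hp <- piecewise_hazard(c(0, 2, 5), c(0.1, 0.3, 0.05))
  expect_equal(eval_cumulative(hp, inv_cumulative(hp, y)), y,
               tolerance = 1e-12)
  expect_equal(eval_cumulative(hp, 3), 0.1 * 2 + 0.3 * 1, tolerance = 1e-12)
  # non-negativity guard
  b <- spline_basis(5, n_basis = 6)
  expect_error(spline_hazard(b, c(-0.1, rep(0.2, 5))), "non-negative")
})

test_that("gamma quadrature integrates the frailty density and its moments", {
  for (theta in c(0.25, 1, 1.07, 4)) {
    r <- gamma_quadrature(theta)
    w <- exp(r$logw)
    expect_lt(abs(sum(w) - 1), 1e-8)
    expect_lt(abs(sum(w * r$u) - 1), 1e-8)
    expect_lt(abs(sum(w * (r$u - 1)^2) - theta), 1e-7)
    expect_true(all(is.finite(r$logw)))
  }
  # near-degenerate frailty switches to the quantile rule and stays sane
  r0 <- gamma_quadrature(1e-6)
  expect_identical(r0$method, "quantile")
  expect_lt(abs(sum(exp(r0$logw) * r0$u) - 1), 1e-6)
})

test_that("gamma frailty density matches its closed form and moments", {
  expect_equal(gamma_frailty_density(1, 1), exp(-1))
  for (theta in c(0.25, 1, 4)) {
    expect_equal(integrate(gamma_frailty_density, 0, Inf, theta = theta,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    expect_equal(integrate(function(u) u * gamma_frailty_density(u, theta),
                           0, Inf, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
    expect_equal(integrate(function(u) (u - 1)^2 *
                             gamma_frailty_density(u, theta),
                           0, Inf, rel.tol = 1e-10)$value, theta,
                 tolerance = 1e-7)
  }
  expect_error(gamma_frailty_density(1, -1), "theta")
  expect_error(gamma_frailty_density(-1, 1), "frailty")
})
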