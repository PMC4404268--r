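test_that("conditional log-likelihood matches hand formulas", {
  # no events, u = 1, constant hazards a, b, follow-up t: -(a + b) t
  p <- flat_true(rate_rec = 0.3, rate_death = 0.12)
  s0 <- make_subject(numeric(0), 7, 0)
  expect_equal(subject_conditional_loglik(s0, p, 1), -(0.3 + 0.12) * 7,
               tolerance = 1e-12)
  # alpha = 1, u = 1: sum of Andersen-Gill and Cox contributions
  s1 <- make_subject(c(2, 5), 8, 1,
                     covs = data.frame(age_group = "le40", pvi = 1,
                                       size_gt20 = 0, nodal = 1,
                                       grade = "II"))
  tp <- recovery_true()
  z <- drop(covariate_matrix(s1$covariates))
  lpR <- sum(tp$beta_rec * z); lpD <- sum(tp$beta_death * z)
  ag <- sum(log(eval_hazard(tp$base_rec, c(2, 5))) + lpR) -
    eval_cumulative(tp$base_rec, 8) * exp(lpR)
  cox <- log(eval_hazard(tp$base_death, 8)) + lpD -
    eval_cumulative(tp$base_death, 8) * exp(lpD)
  expect_equal(subject_conditional_loglik(s1, tp, 1), ag + cox,
               tolerance = 1e-12)
  # doubling u shifts the terms by the predicted pattern
  u <- 1.3
  tp2 <- recovery_true(alpha = 1.7)
  LamR <- eval_cumulative(tp2$base_rec, 8) * exp(lpR)
  LamD <- eval_cumulative(tp2$base_death, 8) * exp(lpD)
  l1 <- subject_conditional_loglik(s1, tp2, u)
  l2 <- subject_conditional_loglik(s1, tp2, 2 * u)
  expect_equal(l2 - l1,
               2 * log(2) + 1.7 * log(2) - u * LamR -
                 (2^1.7 - 1) * u^1.7 * LamD,
               tolerance = 1e-10)
})

test_that("quadrature marginal likelihood equals the alpha=1 closed form", {
  scn <- simulation_scenario("french_like", n_subjects = 25, seed = 7)
  scn$true$alpha <- 1
  co <- simulate_cohort(scn$true, scn$config)
  p <- scn$true
  quad <- marginal_loglik(co, p, per_subject = TRUE)
  th <- p$theta
  Z <- covariate_matrix(co)
  closed <- vapply(seq_len(nrow(co$subjects)), function(i) {
    sj <- co$subjects[i, ]
    rt <- relapse_times(co, sj$id)
    lpR <- sum(p$beta_rec * Z[i, ]); lpD <- sum(p$beta_death * Z[i, ])
    LamR <- eval_cumulative(p$base_rec, sj$followup_time) * exp(lpR)
    LamD <- eval_cumulative(p$base_death, sj$followup_time) * exp(lpD)
    N <- length(rt); d <- sj$death
    sum(log(eval_hazard(p$base_rec, rt))) + N * lpR +
      d * (log(eval_hazard(p$base_death, sj$followup_time)) + lpD) +
      lgamma(1 / th + N + d) - lgamma(1 / th) - log(th) / th -
      (1 / th + N + d) * log(1 / th + LamR + LamD)
  }, numeric(1))
  expect_equal(quad, closed, tolerance = 1e-8)
})

test_that("near-degenerate frailty reduces to the no-frailty likelihood", {
  scn <- simulation_scenario("french_like", n_subjects = 40, seed = 19)
  co <- simulate_cohort(scn$true, scn$config)
  p <- list(hrec = scn$true$base_rec, hdeath = scn$true$base_death,
            beta_rec = scn$true$beta_rec, beta_death = scn$true$beta_death,
            alpha = scn$true$alpha, theta = 1e-6)
  with_frailty <- marginal_loglik(co, p)
  # u == 1 likelihood: conditional loglik summed at u = 1
  no_frailty <- sum(vapply(seq_len(nrow(co$subjects)), function(i) {
    sj <- co$subjects[i, ]
    subject_conditional_loglik(
      make_subject(relapse_times(co, sj$id), sj$followup_time, sj$death,
                   covs = co$subjects[i, , drop = FALSE]), p, 1)
  }, numeric(1)))
  expect_equal(with_frailty, no_frailty, tolerance = 1e-4)
})

test_that("fitting is deterministic and improves the penalized likelihood", {
  scn <- simulation_scenario("french_like", n_subjects = 250, seed = 23)
  co <- simulate_cohort(scn$true, scn$config)
  ctl <- joint_control(n_basis = 6, n_nodes = 32, maxit = 200)
  f1 <- fit_joint_model(co, ctl)
  f2 <- fit_joint_model(co, ctl)
  expect_identical(f1$working$par, f2$working$par)
  # optimizer end point beats the initial point
  ob <- jointpredict:::joint_objective(co, ctl)
  par0 <- jointpredict:::joint_init(co, ob, ctl)
  expect_lt(ob$fn(f1$working$par), ob$fn(par0))
  expect_true(all(is.finite(f1$se$beta_death)))
  expect_gt(f1$theta, 0)
})

test_that("posterior frailty mean increases with the relapse count", {
  tp <- recovery_true(theta = 1, alpha = 1.5)
  means <- vapply(0:4, function(J) {
    rt <- if (J > 0) seq(1, 5, length.out = J) else numeric(0)
    posterior_frailty_mean(make_subject(rt, 8, 0), tp)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("LCV reduces to the AIC-like form without smoothing and is
           permutation invariant", {
  scn <- simulation_scenario("french_like", n_subjects = 150, seed = 29)
  co <- simulate_cohort(scn$true, scn$config)
  ctl <- joint_control(n_basis = 5, n_nodes = 32, kappa_rec = 0,
                       kappa_death = 0, maxit = 300)
  f <- fit_joint_model(co, ctl)
  v <- lcv(f, co)
  p_free <- 2 * 5 + 2 * 7 + 2
  expect_equal(v, (p_free - f$loglik) / f$n, tolerance = 1e-4)
  # permutation invariance
  perm <- rev(seq_len(nrow(co$subjects)))
  co_perm <- cohort(co$subjects[perm, ], co$recurrences)
  f_perm <- fit_joint_model(co_perm, ctl)
  expect_equal(lcv(f_perm, co_perm), v, tolerance = 1e-4)
})
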