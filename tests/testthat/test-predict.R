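test_that("conditional survival pieces match their closed forms", {
  tp <- flat_true(rate_rec = 0.25, rate_death = 0.12, theta = 1, alpha = 1)
  cv <- ref_covs()
  expect_equal(conditional_survival_death(tp, cv, 0, 1.7), 1)
  expect_equal(conditional_survival_death(tp, cv, 6, 1e-12), 1,
               tolerance = 1e-9)
  expect_equal(conditional_survival_death(tp, cv, 6, 1), exp(-0.12 * 6),
               tolerance = 1e-12)
  # next-recurrence survival on the calendar clock
  expect_equal(conditional_survival_next_recurrence(tp, cv, 4, 4, 1.3), 1)
  expect_equal(conditional_survival_next_recurrence(tp, cv, 5, 2, 1),
               exp(-0.25 * 3), tolerance = 1e-12)
  expect_equal(conditional_survival_next_recurrence(tp, cv, 5, 0, 2),
               exp(-2 * 0.25 * 5), tolerance = 1e-12)
  expect_error(conditional_survival_next_recurrence(tp, cv, 3, 4, 1),
               "exceeds")
})

test_that("joint predictions reproduce the gamma Laplace-transform value", {
  # theta = 1, alpha = 1, Lambda_D(s) = 0.5, Lambda_D(s+w) = 1.0, J = 0,
  # no relapse hazard: P = [1/1.5 - 1/2] / [1/1.5] = 0.25
  tp <- true_params(theta = 1, alpha = 1, beta_rec = rep(0, 7),
                    beta_death = rep(0, 7),
                    base_rec = constant_hazard(0),
                    base_death = constant_hazard(0.1))
  cv <- ref_covs()
  expect_equal(predict_rec(tp, cv, numeric(0), 5, 5)$probability, 0.25,
               tolerance = 1e-8)
  expect_equal(predict_ign(tp, cv, 5, 5)$probability, 0.25,
               tolerance = 1e-8)
  # w -> 0+ gives 0
  expect_lt(predict_rec(tp, cv, numeric(0), 5, 1e-12)$probability, 1e-10)
  expect_lt(predict_ign(tp, cv, 5, 1e-12)$probability, 1e-10)
})

test_that("degenerate frailty reduces P_ign to the plain conditional risk", {
  tp <- flat_true(rate_rec = 0.2, rate_death = 0.1, theta = 1e-8, alpha = 1)
  cv <- ref_covs()
  plain <- 1 - exp(-0.1 * 10) / exp(-0.1 * 5)
  expect_equal(predict_ign(tp, cv, 5, 5)$probability, plain,
               tolerance = 1e-5)
})

test_that("P_rec equals P_ign when history carries no information", {
  # alpha = 0: the frailty terms cancel in the ratio for every J
  tp0 <- flat_true(rate_rec = 0.3, rate_death = 0.1, theta = 1, alpha = 0)
  cv <- ref_covs()
  p_ign <- predict_ign(tp0, cv, 5, 5)$probability
  for (J in 0:3) {
    rt <- if (J > 0) seq(1, 4.5, length.out = J) else numeric(0)
    expect_equal(predict_rec(tp0, cv, rt, 5, 5)$probability, p_ign,
                 tolerance = 1e-10)
  }
  # J = 0 and a zero relapse hazard: the S^R term is 1, settings coincide
  tp1 <- true_params(theta = 0.8, alpha = 1.4, beta_rec = rep(0, 7),
                     beta_death = rep(0, 7),
                     base_rec = constant_hazard(0),
                     base_death = constant_hazard(0.15))
  expect_equal(predict_rec(tp1, cv, numeric(0), 4, 3)$probability,
               predict_ign(tp1, cv, 4, 3)$probability, tolerance = 1e-12)
})

test_that("predictions are probabilities, monotone in w and in J", {
  tp <- recovery_true(theta = 1, alpha = 1.5)
  cv <- data.frame(age_group = "40to55", pvi = 1, size_gt20 = 0, nodal = 1,
                   grade = "II")
  ws <- c(0.5, 1, 2, 4, 7)
  for (J in c(0, 2)) {
    rt <- if (J > 0) c(1, 3) else numeric(0)
    pr <- vapply(ws, function(w)
      predict_rec(tp, cv, rt, 5, w)$probability, numeric(1))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_true(all(diff(pr) > 0))
  }
  # more relapses, higher risk (alpha > 0)
  pJ <- vapply(0:3, function(J) {
    rt <- if (J > 0) seq(1, 4.8, length.out = J) else numeric(0)
    predict_rec(tp, cv, rt, 5, 5)$probability
  }, numeric(1))
  expect_true(all(diff(pJ) > 0))
})

test_that("quadrature predictions agree with Monte-Carlo frailty integrals", {
  tp <- recovery_true(theta = 1.2, alpha = 2)
  cv <- ref_covs()
  set.seed(61)
  M <- 2e5
  u <- rgamma(M, 1 / 1.2, 1 / 1.2)
  for (J in c(0, 2)) {
    rt <- if (J > 0) c(1.5, 3) else numeric(0)
    lastX <- if (J > 0) 3 else 0
    Ss <- conditional_survival_death(tp, cv, 5, u)
    Ssw <- conditional_survival_death(tp, cv, 9, u)
    SR <- conditional_survival_next_recurrence(tp, cv, 5, lastX, u)
    num_i <- (Ss - Ssw) * u^J * SR
    den_i <- Ss * u^J * SR
    P_mc <- mean(num_i) / mean(den_i)
    se_mc <- sd(num_i - P_mc * den_i) / (mean(den_i) * sqrt(M))
    P_quad <- predict_rec(tp, cv, rt, 5, 4)$probability
    expect_lt(abs(P_quad - P_mc), 3 * se_mc + 1e-10)
  }
})

test_that("landmark prediction matches the analytic exponential form", {
  fake <- structure(list(landmark_time = 5, hazard = constant_hazard(0.09),
                         beta = stats::setNames(c(rep(0, 7), 0.8, 1.4),
                                                c(jointpredict:::DESIGN_COLUMNS,
                                                  "rec1", "rec2plus")),
                         n_at_risk = 100),
                    class = "landmark_fit")
  cv <- ref_covs()
  expect_equal(predict_lm(fake, cv, 0, 5, 3)$probability,
               1 - exp(-0.09 * 3), tolerance = 1e-12)
  expect_lt(predict_lm(fake, cv, 0, 5, 1e-12)$probability, 1e-10)
  # positive relapse coefficient: relapsed subject has higher risk
  p0 <- predict_lm(fake, cv, 0, 5, 3)$probability
  p1 <- predict_lm(fake, cv, 1, 5, 3)$probability
  p2 <- predict_lm(fake, cv, 2, 5, 3)$probability
  expect_true(p0 < p1 && p1 < p2)
  expect_error(predict_lm(fake, cv, 0, 4, 3), "landmark time")
})

test_that("predictions update with the history without refitting", {
  tp <- recovery_true(theta = 1, alpha = 1.5)
  cv <- ref_covs()
  relapses <- c(2, 4.5)
  probs <- vapply(c(1, 3, 5), function(s) {
    rt <- relapses[relapses <= s]
    predict_rec(tp, cv, rt, s, 3)$probability
  }, numeric(1))
  # growing history changes the prediction (here: each relapse raises it)
  expect_true(all(diff(probs) > 0))
})

test_that("the cohort-level driver matches the per-subject functions", {
  scn <- simulation_scenario("french_like", n_subjects = 80, seed = 67)
  co <- simulate_cohort(scn$true, scn$config)
  pr <- predict_death(scn$true, co, 5, 5, "rec")
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  i <- which(co$subjects$id == pr$id[1])
  rt <- relapse_times(co, pr$id[1])
  direct <- predict_rec(scn$true, co$subjects[i, , drop = FALSE],
                        rt[rt <= 5], 5, 5)$probability
  expect_equal(pr$probability[1], direct)
})
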