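test_that("censoring Kaplan-Meier handles the degenerate and toy cases", {
  subj <- ref_covs(3)
  subj$id <- c("a", "b", "c")
  # no censored subjects: G = 1 everywhere before the last time
  co1 <- cohort(cbind(subj, followup_time = c(2, 4, 6), death = 1))
  G1 <- censoring_km(co1)
  expect_equal(eval_censoring(G1, c(1, 3, 5.9)), rep(1, 3))
  # all censored at t = 3: step from 1 to 0
  co2 <- cohort(cbind(subj, followup_time = 3, death = 0))
  G2 <- censoring_km(co2)
  expect_equal(eval_censoring(G2, 2.9), 1)
  expect_equal(eval_censoring(G2, 3), 0)
  # hand-computed: times 2, 4, 6 with death 1, 0, 1
  co3 <- cohort(cbind(subj, followup_time = c(2, 4, 6), death = c(1, 0, 1)))
  G3 <- censoring_km(co3)
  expect_equal(eval_censoring(G3, 4, left = TRUE), 1)
  expect_equal(eval_censoring(G3, 4), 0.5)
})

test_that("IPCW weights reproduce the printed formula", {
  # no censoring: every evaluated weight is 1
  G1 <- structure(list(time = numeric(0), surv = numeric(0)),
                  class = "censoring_km")
  expect_equal(ipcw_weight(c(6, 12), c(1, 0), 5, 5, G1), c(1, 1))
  # censored alive inside the window: weight 0
  expect_equal(ipcw_weight(7, 0, 5, 5, G1), 0)
  # toy censoring curve: G(s) = 1, G(T-) = 0.8, death inside window -> 1.25
  G2 <- structure(list(time = c(6, 11), surv = c(0.8, 0.5)),
                  class = "censoring_km")
  expect_equal(ipcw_weight(8, 1, 5, 5, G2), 1 / 0.8)
  # survivor past s + w: 1 / [G(s+w)/G(s)]
  expect_equal(ipcw_weight(12, 0, 5, 5, G2), 1 / (0.8 / 1))
})

test_that("Brier error matches algebra and a brute-force double loop", {
  G1 <- structure(list(time = numeric(0), surv = numeric(0)),
                  class = "censoring_km")
  # perfect foresight, no censoring
  time <- c(6, 7, 12, 14)
  death <- c(1, 1, 0, 1)
  pred <- c(1, 1, 0, 0)
  expect_equal(brier_error(pred, time, death, 5, 5, G1)$err, 0)
  # constant p = 0.5, half the subjects die inside the window
  n <- 10
  time2 <- c(rep(7, 5), rep(12, 5))
  death2 <- c(rep(1, 5), rep(0, 5))
  expect_equal(brier_error(rep(0.5, n), time2, death2, 5, 5, G1)$err, 0.25)
  expect_equal(brier_error(rep(0.3, n), time2, death2, 5, 5, G1)$err,
               (5 * (1 - 0.3)^2 + 5 * 0.3^2) / 10)
  # brute-force oracle on random censored data
  set.seed(71)
  scn <- simulation_scenario("french_like", n_subjects = 50, seed = 71)
  co <- simulate_cohort(scn$true, scn$config)
  G <- censoring_km(co)
  sel <- co$subjects$followup_time > 3
  tt <- co$subjects$followup_time[sel]
  dd <- co$subjects$death[sel]
  pp <- runif(sum(sel))
  expect_equal(brier_error(pp, tt, dd, 3, 4, G)$err,
               brier_bruteforce(pp, tt, dd, 3, 4, G), tolerance = 1e-12)
  # invariant under subject reordering
  o <- sample(seq_along(pp))
  expect_equal(brier_error(pp[o], tt[o], dd[o], 3, 4, G)$err,
               brier_error(pp, tt, dd, 3, 4, G)$err, tolerance = 1e-15)
  expect_error(brier_error(c(1.2, pp[-1]), tt, dd, 3, 4, G), "0, 1")
})

test_that("the Kaplan-Meier reference error closes the R^2 loop", {
  subj <- ref_covs(8)
  subj$id <- letters[1:8]
  # no censoring; 2 of 6 at-risk subjects die inside (5, 10]
  co <- cohort(cbind(subj, followup_time = c(2, 3, 7, 8, 12, 13, 14, 15),
                     death = c(1, 1, 1, 1, 0, 0, 0, 0)))
  G <- censoring_km(co)
  ref <- km_reference_error(co, 5, 5, G)
  q <- 4 / 6                          # survivor fraction past s + w
  expect_equal(ref$p_km, 1 - q, tolerance = 1e-12)
  expect_equal(ref$err, q * (1 - q), tolerance = 1e-12)
  expect_equal(r_squared(ref$err, ref$err), 0)
  # everyone survives past s + w: zero KM death probability and zero error
  co2 <- cohort(cbind(subj, followup_time = 20, death = 0))
  co2$subjects$death <- 0
  ref2 <- km_reference_error(co2, 5, 5, censoring_km(co2))
  expect_equal(ref2$p_km, 0)
  expect_equal(ref2$err, 0)
  expect_warning(r_squared(0.1, 0), "undefined")
  expect_equal(r_squared(0.15, 0.2), 0.25)
  expect_equal(r_squared(0, 0.2), 1)
})

test_that("calibration table is self-consistent on exactly calibrated data", {
  set.seed(73)
  n <- 2000
  pred <- rbeta(n, 1.2, 6)
  died <- rbinom(n, 1, pred)
  time <- ifelse(died == 1, 7.5, 11)
  tab <- calibration_table(pred, time, died, 5, 5)
  expect_equal(sum(tab$n), n)
  inside <- tab$mean_pred >= tab$lower & tab$mean_pred <= tab$upper
  expect_gte(sum(inside), 9)
  # calibration in the large
  expect_lt(abs(sum(tab$n * tab$obs_prop) / n - mean(pred)),
            2 * sqrt(mean(pred) * (1 - mean(pred)) / n))
  expect_equal(sum(attr(tab, "histogram")), n)
})

test_that("calibration table collapses gracefully on constant predictions", {
  n <- 50
  expect_warning(
    tab <- calibration_table(rep(0, n), rep(12, n), rep(0, n), 5, 5),
    "collapsed")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$mean_pred, 0)
  expect_equal(tab$obs_prop, 0)
})

test_that("calibration under censoring uses the conditional Kaplan-Meier", {
  set.seed(79)
  n <- 4000
  pred <- rbeta(n, 1.5, 5)
  # death times with probability pred inside (5, 10], censoring at random
  died <- rbinom(n, 1, pred)
  dtime <- ifelse(died == 1, runif(n, 5, 10), 15)
  ctime <- ifelse(runif(n) < 0.25, runif(n, 5.5, 12), 20)
  time <- pmin(dtime, ctime)
  death <- as.integer(dtime <= ctime)
  tab <- calibration_table(pred, time, death, 5, 5)
  inside <- tab$mean_pred >= tab$lower & tab$mean_pred <= tab$upper
  expect_gte(sum(inside), 8)
})

test_that("error curves agree point-wise with direct Brier calls", {
  scn <- simulation_scenario("french_like", n_subjects = 400, seed = 83)
  co <- simulate_cohort(scn$true, scn$config)
  G <- censoring_km(co)
  cur <- prediction_error_curve(co, joint = scn$true, settings = "ign",
                                s = 4, w = 3, G = G)
  pr <- predict_death(scn$true, co, 4, 3, "ign")
  sel <- co$subjects$followup_time > 4
  be <- brier_error(pr$probability, co$subjects$followup_time[sel],
                    co$subjects$death[sel], 4, 3, G)
  expect_identical(cur$err, be$err)
  expect_identical(cur$n, be$n)
})
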