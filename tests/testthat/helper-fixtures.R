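# Shared fixtures: all built in code, no stored data.

# n subjects at the reference covariate levels (age > 55, grade I, no risk
# factors), so every linear predictor is zero
ref_covs <- function(n = 1) {
  data.frame(age_group = rep("gt55", n), pvi = 0, size_gt20 = 0, nodal = 0,
             grade = "I")
}

# joint-model parameters with constant baseline hazards and zero covariate
# effects: every marginal quantity has a closed form
flat_true <- function(rate_rec = 0.2, rate_death = 0.1, theta = 1,
                      alpha = 1) {
  true_params(theta = theta, alpha = alpha,
              beta_rec = rep(0, 7), beta_death = rep(0, 7),
              base_rec = constant_hazard(rate_rec),
              base_death = constant_hazard(rate_death))
}

# small hand-built cohort used across IO / landmark tests
toy_cohort <- function() {
  cohort(
    data.frame(id = c("A", "B", "C"),
               age_group = c("le40", "gt55", "40to55"),
               pvi = c(1, 0, 0), size_gt20 = c(0, 1, 0),
               nodal = c(1, 0, 1), grade = c("II", "I", "III"),
               followup_time = c(8, 10, 6.5), death = c(1, 0, 1)),
    data.frame(id = c("A", "A"), rec_time = c(2, 5)))
}

# moderate-effect generative truth used for recovery-style checks
recovery_true <- function(theta = 1, alpha = 1) {
  true_params(theta = theta, alpha = alpha,
              beta_rec = c(0, 0, 0.5, 0.7, 0.6, 0.8, 1.1),
              beta_death = c(0, 0, 0.5, 0.7, 0.6, 0.8, 1.1),
              base_rec = weibull_hazard(0.95, 30),
              base_death = weibull_hazard(1.25, 40))
}

# independent, deliberately naive double-loop IPCW Brier implementation
brier_bruteforce <- function(pred, time, death, s, w, G) {
  n <- length(pred)
  total <- 0
  for (i in seq_len(n)) {
    Gs <- eval_censoring(G, s)
    if (time[i] <= s + w && death[i] == 1) {
      h <- Gs / eval_censoring(G, time[i], left = TRUE)
    } else if (time[i] > s + w) {
      h <- Gs / eval_censoring(G, s + w)
    } else {
      h <- 0
    }
    y <- as.numeric(time[i] > s + w)
    total <- total + (y - (1 - pred[i]))^2 * h
  }
  total / n
}

# subject snapshot in the form subject_conditional_loglik expects
make_subject <- function(relapse_times, followup, death, covs = ref_covs()) {
  list(relapse_times = relapse_times, followup_time = followup,
       death = death, covariates = covs)
}
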