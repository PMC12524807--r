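# shared fixtures: small simulated cohorts and fast training configs

tiny_sim <- function(n = 60, p = 8, signal = 3, beta = 1, censor = 0.4,
                     seed = 1, risk_form = "linear") {
  simulate_cohort(sim_config(
    n_samples = n, n_genes = p, signal_genes = signal,
    beta_magnitude = beta, risk_form = risk_form,
    censor_target = censor, seed = seed))
}

fast_tcfg <- function(..., max_epochs = 30, patience = 0, seed = 1) {
  train_config(max_epochs = max_epochs, patience = patience, seed = seed, ...)
}

# naive Cox negative log partial likelihood: direct translation of the
# definition, no log-sum-exp; independent oracle for the stable version
naive_cox_nll <- function(risks, time, event) {
  total <- 0
  for (i in seq_along(risks)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      total <- total - (risks[i] - log(sum(exp(risks[rs]))))
    }
  }
  total
}

random_survival_instance <- function(n, seed, tie_times = FALSE) {
  withr::with_seed(seed, {
    time <- if (tie_times) sample(1:ceiling(n / 2), n, replace = TRUE) * 1.0
            else stats::runif(n)
    event <- stats::rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1L
    list(time = time, event = event, risks = stats::rnorm(n))
  })
}
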