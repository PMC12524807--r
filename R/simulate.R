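#' Configuration for the synthetic survival-cohort simulator
#'
#' Defaults emulate a bulk hepatocellular-carcinoma expression cohort aligned
#' to a macrophage marker-gene signature: 370 samples, 407 retained genes, a
#' sparse set of prognostic genes, Weibull proportional-hazards event times,
#' and ~64.9% random censoring.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes (features).
#' @param signal_genes number of genes with non-zero log-hazard effect; the
#'   first `signal_genes` columns carry coefficients of alternating sign.
#' @param beta_magnitude absolute effect size on the log-hazard per signal
#'   gene (and the coefficient of the interaction term under
#'   `risk_form = "interaction"`).
#' @param risk_form `"linear"` for risk = beta' x; `"interaction"` adds
#'   `beta_magnitude * x1 * x2` (product of the first two signal genes), a
#'   nonlinearity a linear Cox model cannot represent.
#' @param baseline_shape,baseline_scale Weibull baseline-hazard parameters
#'   (shape k, scale lambda in days). Defaults give a median baseline event
#'   time around 900 days, in line with overall survival in advanced liver
#'   cancer cohorts.
#' @param censor_target desired censoring fraction in (0, 1); an independent
#'   exponential censoring rate is tuned by bisection to realize it.
#' @param expression_marginal `"normal"` (standard normal per gene, matching
#'   post-standardization inputs) or `"lognormal"` for a skewed,
#'   expression-like marginal.
#' @param seed integer RNG seed; cohorts are bit-reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 370, n_genes = 407, signal_genes = 20,
                       beta_magnitude = 1, risk_form = c("linear", "interaction"),
                       baseline_shape = 1.2, baseline_scale = 1200,
                       censor_target = 0.649,
                       expression_marginal = c("normal", "lognormal"),
                       seed = 1) {
  risk_form <- match.arg(risk_form)
  expression_marginal <- match.arg(expression_marginal)
  check_scalar_num(n_samples, "n_samples", lower = 2, integer = TRUE)
  check_scalar_num(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar_num(signal_genes, "signal_genes", lower = 0, upper = n_genes,
                   integer = TRUE)
  check_scalar_num(beta_magnitude, "beta_magnitude", lower = 0)
  check_scalar_num(baseline_shape, "baseline_shape", lower = 0, strict_lower = TRUE)
  check_scalar_num(baseline_scale, "baseline_scale", lower = 0, strict_lower = TRUE)
  check_scalar_num(censor_target, "censor_target", lower = 0, upper = 1)
  if (censor_target <= 0 || censor_target >= 1) {
    stop_cf("censor_target must be strictly inside (0, 1)",
            class = "coxformer_config_error")
  }
  if (risk_form == "interaction" && signal_genes < 2) {
    stop_cf("interaction risk needs at least 2 signal genes",
            class = "coxformer_config_error")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 signal_genes = as.integer(signal_genes),
                 beta_magnitude = beta_magnitude, risk_form = risk_form,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censor_target = censor_target,
                 expression_marginal = expression_marginal,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# realized censoring fraction is monotone non-decreasing in the exponential
# censoring rate: censor time c = -log(u)/rate shrinks as rate grows.
realized_censoring_at_rate <- function(rate, t_event, u_cens) {
  mean(-log(u_cens) / rate < t_event)
}

tune_censor_rate <- function(t_event, u_cens, target, tol = 1e-4,
                             max_iter = 200L) {
  lo <- 1e-12; hi <- 1e12
  f_lo <- realized_censoring_at_rate(lo, t_event, u_cens)
  f_hi <- realized_censoring_at_rate(hi, t_event, u_cens)
  if (target < f_lo || target > f_hi) {
    stop_cf(sprintf(
      "censoring target %.3f outside achievable range [%.3f, %.3f]",
      target, f_lo, f_hi), class = "coxformer_simulation_error")
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisection on log-rate
    f_mid <- realized_censoring_at_rate(mid, t_event, u_cens)
    if (abs(f_mid - target) <= tol) return(mid)
    if (f_mid < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Simulate a survival cohort with known ground truth
#'
#' Expression is drawn i.i.d. per gene; event times follow a Weibull
#' proportional-hazards model, `t = lambda * (-log U / exp(risk))^(1/k)`
#' (inverse-transform sampling under baseline hazard shape `k`, scale
#' `lambda`). Censoring times are independent exponentials whose rate is
#' tuned by bisection so the realized censoring fraction matches
#' `cfg$censor_target`. Exact observed-time ties (possible only through
#' floating-point rounding) are broken by a 1e-9-day perturbation so Cox risk
#' sets are unambiguous.
#'
#' @param cfg a [sim_config()].
#' @return A list with `cohort` (a [survival_cohort()]) and `truth`, a
#'   `ground_truth` list carrying `true_beta` (0 for non-signal genes),
#'   `true_risk` (the generative linear or interaction-augmented predictor),
#'   `realized_censoring` and the tuned `censor_rate`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples; p <- cfg$n_genes
    X <- matrix(stats::rnorm(n * p), n, p)
    if (cfg$expression_marginal == "lognormal") {
      X <- exp(0.5 * X)  # skewed, positive, expression-like
    }
    beta <- numeric(p)
    if (cfg$signal_genes > 0) {
      s <- seq_len(cfg$signal_genes)
      beta[s] <- cfg$beta_magnitude * (-1)^(s - 1)  # alternating signs
    }
    risk <- drop(X %*% beta)
    if (cfg$risk_form == "interaction") {
      risk <- risk + cfg$beta_magnitude * X[, 1L] * X[, 2L]
    }
    u <- stats::runif(n)
    t_event <- cfg$baseline_scale *
      (-log(u) / exp(risk))^(1 / cfg$baseline_shape)
    u_cens <- stats::runif(n)
    rate <- tune_censor_rate(t_event, u_cens, cfg$censor_target)
    t_cens <- -log(u_cens) / rate
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    # break exact observed-time ties so every risk set is unambiguous
    while (anyDuplicated(time)) {
      dup <- duplicated(time)
      time[dup] <- time[dup] + 1e-9
    }
    genes <- sprintf("G%04d", seq_len(p))
    ids <- sprintf("S%04d", seq_len(n))
    cohort <- survival_cohort(X, ids, genes, time, event)
    truth <- structure(list(true_beta = stats::setNames(beta, genes),
                            true_risk = stats::setNames(risk, ids),
                            realized_censoring = mean(event == 0),
                            censor_rate = rate,
                            config = cfg),
                       class = "ground_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Concordance of the generative risk (simulation ceiling)
#'
#' Scores the true (generative) risk against the simulated outcomes. This is
#' the concordance an ideal model would achieve on the cohort; any fitted
#' model's C-index can be compared against it as a ceiling. Ties in the true
#' risk (e.g. a null simulation) get half credit so a signal-free cohort
#' scores ~0.5.
#'
#' @param cohort,truth output of [simulate_cohort()].
#' @param tie_policy passed to [concordance_index()]; default `"half"`.
#' @return the oracle C-index (numeric scalar).
#' @export
oracle_cindex <- function(cohort, truth, tie_policy = "half") {
  stopifnot(identical(names(truth$true_risk), cohort$sample_ids))
  concordance_index(truth$true_risk, cohort$time, cohort$event,
                    tie_policy = tie_policy)$cindex
}

#' Write a simulated cohort and its ground truth to disk
#'
#' Writes the expression and clinical TSVs (see [write_cohort()]), a
#' ground-truth TSV (`gene`, `true_beta`) and a JSON sidecar of the
#' simulation configuration.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    clinical = file.path(dir, paste0(prefix, "_clinical.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    config = file.path(dir, paste0(prefix, "_config.json"))
  )
  write_cohort(sim$cohort, paths[["expression"]], paths[["clinical"]])
  utils::write.table(
    data.frame(gene = names(sim$truth$true_beta),
               true_beta = sim$truth$true_beta),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$truth$config
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
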