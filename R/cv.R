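#' Repeated k-fold plan with train/validation/test role rotation
#'
#' For each of `n_rounds` rounds (each reseeded with `base_seed + round`),
#' samples are partitioned into `n_folds` folds whose sizes differ by at most
#' one. Within a round every fold serves as the test set exactly once; the
#' validation fold is the next fold cyclically (`(test %% n_folds) + 1`) and
#' the remaining folds train. Defaults realize the 5-fold x 20-round = 100
#' independent train/validation/test runs protocol.
#'
#' @param n_samples number of samples (>= n_folds).
#' @param n_folds folds per round (default 5).
#' @param n_rounds rounds with different split seeds (default 20).
#' @param base_seed integer; round r uses seed `base_seed + r`.
#' @return An object of class `fold_plan`: list with `folds` (per-round
#'   integer fold labels) and `runs` (data.frame of round, test_fold,
#'   val_fold; `n_folds * n_rounds` rows).
#' @export
make_fold_plan <- function(n_samples, n_folds = 5, n_rounds = 20,
                           base_seed = 1) {
  check_scalar_num(n_samples, "n_samples", lower = 1, integer = TRUE)
  check_scalar_num(n_folds, "n_folds", lower = 2, integer = TRUE)
  check_scalar_num(n_rounds, "n_rounds", lower = 1, integer = TRUE)
  if (n_samples < n_folds) {
    stop_cf("need at least as many samples as folds",
            class = "coxformer_config_error")
  }
  sizes <- rep(n_samples %/% n_folds, n_folds) +
    (seq_len(n_folds) <= n_samples %% n_folds)
  folds <- lapply(seq_len(n_rounds), function(r) {
    with_seed(base_seed + r, sample(rep.int(seq_len(n_folds), sizes)))
  })
  runs <- expand.grid(test_fold = seq_len(n_folds), round = seq_len(n_rounds))
  runs <- data.frame(round = runs$round, test_fold = runs$test_fold)
  runs$val_fold <- (runs$test_fold %% n_folds) + 1L
  structure(list(n_samples = as.integer(n_samples),
                 n_folds = as.integer(n_folds),
                 n_rounds = as.integer(n_rounds),
                 base_seed = as.integer(base_seed),
                 folds = folds, runs = runs),
            class = "fold_plan")
}

#' Serialize / deserialize a fold plan as JSON
#'
#' @param plan a `fold_plan`.
#' @param path JSON path.
#' @return `write_fold_plan` invisibly returns `path`; `read_fold_plan`
#'   returns the `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_samples = as.integer(raw$n_samples),
                 n_folds = as.integer(raw$n_folds),
                 n_rounds = as.integer(raw$n_rounds),
                 base_seed = as.integer(raw$base_seed),
                 folds = lapply(seq_len(raw$n_rounds), function(r) {
                   as.integer(if (is.list(raw$folds)) raw$folds[[r]]
                              else raw$folds[r, ])
                 }),
                 runs = as.data.frame(raw$runs)),
            class = "fold_plan")
}

#' Model specifications for the cross-validation harness
#'
#' A model spec is the minimal adapter contract the harness needs:
#' `fit(train, val, seed)` returning a fitted object, and the shared
#' [predict_risk()] generic. Models flagged `needs_validation = FALSE` are
#' fitted on all non-test folds combined.
#'
#' @param name model label used in result tables.
#' @param fit function(cohort_train, cohort_val, seed) -> fitted model.
#' @param needs_validation whether the model consumes a validation fold.
#' @return a `model_spec`.
#' @export
new_model_spec <- function(name, fit, needs_validation = TRUE) {
  stopifnot(is.character(name), is.function(fit))
  structure(list(name = name, fit = fit,
                 needs_validation = isTRUE(needs_validation)),
            class = "model_spec")
}

#' @rdname new_model_spec
#' @param token_dim,num_heads,num_blocks,dropout,norm_placement passed to
#'   [model_config()] (n_features is taken from the training cohort at fit
#'   time).
#' @param tcfg a [train_config()]; its seed is replaced by the harness's
#'   per-run seed.
#' @export
coxformer_spec <- function(token_dim = 64, num_heads = 8, num_blocks = 2,
                           dropout = 0.1, norm_placement = "pre",
                           tcfg = train_config()) {
  new_model_spec("coxformer", function(train, val, seed) {
    mcfg <- model_config(ncol(train$X), token_dim = token_dim,
                         num_heads = num_heads, num_blocks = num_blocks,
                         dropout = dropout, norm_placement = norm_placement)
    tcfg$seed <- as.integer(seed)
    train_coxformer(train, val, mcfg, tcfg)
  })
}

#' @rdname new_model_spec
#' @export
linear_cox_spec <- function(tcfg = train_config()) {
  new_model_spec("linear_cox", function(train, val, seed) {
    tcfg$seed <- as.integer(seed)
    train_linear_cox(train, val, tcfg)
  })
}

run_seed <- function(base_seed, round, fold) {
  as.integer((base_seed + 10000L * round + 101L * fold) %% .Machine$integer.max)
}

#' Run a model through a repeated k-fold plan
#'
#' For every run of the plan: the training folds' statistics standardize all
#' roles (fitting happens inside the model spec, on the training cohort
#' only), the model trains with early stopping on the validation fold, and
#' train/validation/test C-indices are recorded. Runs that fail (e.g. a
#' degenerate fold with no events) are recorded with their reason and
#' excluded from aggregates.
#'
#' @param cohort an aligned `survival_cohort`.
#' @param spec a `model_spec`.
#' @param plan a [make_fold_plan()] for `nrow(cohort$X)` samples.
#' @param tie_policy C-index tie policy for scoring (default `"strict"`).
#' @param verbose print one line per run.
#' @return An object of class `cv_result`: data.frame with columns round,
#'   fold, model, train_c, val_c, test_c, seed, status, reason.
#' @export
run_cv <- function(cohort, spec, plan, tie_policy = "strict",
                   verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(plan, "fold_plan"))
  if (nrow(cohort$X) != plan$n_samples) {
    stop_cf("plan was made for ", plan$n_samples, " samples but cohort has ",
            nrow(cohort$X), class = "coxformer_validation_error")
  }
  runs <- plan$runs
  out <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    rd <- runs$round[k]; tf <- runs$test_fold[k]; vf <- runs$val_fold[k]
    labels <- plan$folds[[rd]]
    seed <- run_seed(plan$base_seed, rd, tf)
    res <- tryCatch({
      test_rows <- which(labels == tf)
      if (spec$needs_validation) {
        val_rows <- which(labels == vf)
        train_rows <- which(labels != tf & labels != vf)
      } else {
        val_rows <- integer()
        train_rows <- which(labels != tf)
      }
      tr <- subset_cohort(cohort, train_rows)
      va <- if (length(val_rows)) subset_cohort(cohort, val_rows) else NULL
      te <- subset_cohort(cohort, test_rows)
      fit <- spec$fit(tr, va, seed)
      score <- function(co) {
        concordance_index(predict_risk(fit, co), co$time, co$event,
                          tie_policy = tie_policy)$cindex
      }
      data.frame(round = rd, fold = tf, model = spec$name,
                 train_c = score(tr),
                 val_c = if (is.null(va)) NA_real_ else score(va),
                 test_c = score(te),
                 seed = seed, status = "ok", reason = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(round = rd, fold = tf, model = spec$name,
                 train_c = NA_real_, val_c = NA_real_, test_c = NA_real_,
                 seed = seed, status = "failed",
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if (verbose) {
      message(sprintf("round %d fold %d [%s]: test C = %s", rd, tf,
                      res$status, format(res$test_c, digits = 4)))
    }
    out[[k]] <- res
  }
  structure(do.call(rbind, out), class = c("cv_result", "data.frame"))
}

#' Aggregate a cross-validation result
#'
#' Mean and standard deviation of the test C-index per model over successful
#' runs, plus failure counts.
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data.frame with columns model, n_runs, n_failed, mean_test_c,
#'   sd_test_c.
#' @export
summary.cv_result <- function(object, ...) {
  sp <- split(as.data.frame(object), object$model)
  do.call(rbind, lapply(sp, function(d) {
    ok <- d[d$status == "ok", , drop = FALSE]
    data.frame(model = d$model[1L],
               n_runs = nrow(d),
               n_failed = sum(d$status != "ok"),
               mean_test_c = mean(ok$test_c),
               sd_test_c = stats::sd(ok$test_c),
               stringsAsFactors = FALSE)
  }))
}

#' Write per-run and summary CV tables as CSV
#'
#' @param result a `cv_result`.
#' @param runs_path,summary_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cv_result <- function(result, runs_path, summary_path) {
  utils::write.csv(as.data.frame(result), runs_path, row.names = FALSE)
  utils::write.csv(summary.cv_result(result), summary_path, row.names = FALSE)
  invisible(c(runs_path, summary_path))
}

#' Grid search over architecture/training hyperparameters
#'
#' Evaluates every point of the Cartesian grid on a one-round k-fold plan,
#' scoring each by the across-fold mean of (train C-index + validation
#' C-index) — or validation C-index alone — and returns the argmax, ties
#' broken by enumeration order. The selected configuration is then reusable
#' across a full multi-round protocol.
#'
#' @param cohort an aligned `survival_cohort`.
#' @param grid named list of candidate values, e.g.
#'   `list(token_dim = c(32, 64), num_heads = c(4, 8))`.
#' @param plan a one-round [make_fold_plan()].
#' @param spec_factory function taking one named grid point (as a list) and
#'   returning a `model_spec`; defaults to [coxformer_spec()] fed the grid
#'   point's fields.
#' @param score `"train_plus_val"` (default) or `"val_only"`.
#' @param verbose print one line per grid point.
#' @return list with `best` (named list of the selected point), `scores`
#'   (data.frame of grid points and their selection scores) and `results`
#'   (per-point `cv_result`s).
#' @export
grid_search <- function(cohort, grid, plan, spec_factory = NULL,
                        score = c("train_plus_val", "val_only"),
                        verbose = FALSE) {
  score <- match.arg(score)
  if (!is.list(grid) || length(grid) == 0L) {
    stop_cf("grid must be a non-empty named list",
            class = "coxformer_config_error")
  }
  if (plan$n_rounds != 1L) {
    stop_cf("grid search expects a one-round fold plan",
            class = "coxformer_config_error")
  }
  if (is.null(spec_factory)) {
    spec_factory <- function(point) do.call(coxformer_spec, point)
  }
  points <- expand.grid(grid, stringsAsFactors = FALSE)  # deterministic order
  scores <- numeric(nrow(points))
  results <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    point <- as.list(points[i, , drop = FALSE])
    names(point) <- names(points)
    spec <- spec_factory(point)
    cv <- run_cv(cohort, spec, plan)
    ok <- cv[cv$status == "ok", , drop = FALSE]
    scores[i] <- if (nrow(ok) == 0L) {
      -Inf
    } else if (score == "train_plus_val") {
      mean(ok$train_c + ok$val_c)
    } else {
      mean(ok$val_c)
    }
    results[[i]] <- cv
    if (verbose) {
      message(sprintf("grid point %d/%d (%s): score %.5f", i, nrow(points),
                      paste(names(point), unlist(point), sep = "=",
                            collapse = ", "), scores[i]))
    }
  }
  best_i <- which.max(scores)  # earliest argmax on ties
  best <- as.list(points[best_i, , drop = FALSE])
  names(best) <- names(points)
  list(best = best,
       scores = cbind(points, selection_score = scores),
       results = results)
}
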