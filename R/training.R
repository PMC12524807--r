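#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.002).
#' @param weight_decay L2 regularization strength applied to dense weight
#'   matrices (not to biases, layer-norm parameters, or the CLS vector).
#'   Default 0.1, the middle of the tuning grid `{0.05, 0.1, 0.3}`.
#' @param max_epochs maximum optimization epochs (default 200).
#' @param patience early-stopping rounds: training stops after this many
#'   epochs without improvement of the validation criterion; the best
#'   validation-epoch weights are returned. `0` disables early stopping
#'   (default 20; must be <= max_epochs).
#' @param batch_size `NULL` for full-cohort batches (exact Cox risk sets,
#'   the default) or an integer for shuffled minibatches with risk sets
#'   formed within each batch.
#' @param seed integer seed governing initialization, dropout and batch
#'   shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.002, weight_decay = 0.1,
                         max_epochs = 200, patience = 20,
                         batch_size = NULL, seed = 1) {
  check_scalar_num(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  check_scalar_num(weight_decay, "weight_decay", lower = 0)
  check_scalar_num(max_epochs, "max_epochs", lower = 0, integer = TRUE)
  check_scalar_num(patience, "patience", lower = 0, upper = max(max_epochs, 1),
                   integer = TRUE)
  if (!is.null(batch_size)) {
    check_scalar_num(batch_size, "batch_size", lower = 2, integer = TRUE)
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, theta, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + state$eps))
}

# 1 where the flattened parameter is part of a dense weight matrix (decayed),
# 0 for biases / layer norms / CLS (not decayed)
decay_mask <- function(params) {
  unlist(rapply(params, function(x) {
    x[] <- if (is.matrix(x)) 1 else 0
    x
  }, how = "replace"), use.names = FALSE)
}

validation_metric <- function(risks, val) {
  # early stopping tracks validation concordance (half-credit ties so
  # near-constant early outputs score 0.5, not 0); with < 2 validation
  # events concordance is too unstable and the criterion falls back to
  # negative validation loss
  if (sum(val$event) >= 2L) {
    tryCatch(
      concordance_index(risks, val$time, val$event, tie_policy = "half")$cindex,
      coxformer_metric_error = function(e)
        -cox_nll(risks, val$time, val$event) / sum(val$event))
  } else {
    -cox_nll(risks, val$time, val$event) / max(1, sum(val$event))
  }
}

run_train_loop <- function(theta, skel, fwd_loss, val_fwd, tcfg, has_val) {
  n_par <- length(theta)
  opt <- adam_init(n_par)
  dmask <- decay_mask(skel)
  record <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), val_cindex = numeric())
  best_theta <- theta
  best_metric <- -Inf
  best_epoch <- 0L
  stall <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    fl <- fwd_loss(utils::relist(theta, skel))
    if (!is.finite(fl$loss)) {
      stop_cf("non-finite training loss at epoch ", epoch,
              class = "coxformer_divergence_error")
    }
    grad <- unlist(fl$grads, use.names = FALSE) +
      tcfg$weight_decay * dmask * theta
    st <- adam_step(opt, theta, grad, tcfg$learning_rate)
    opt <- st$state
    theta <- st$theta
    if (has_val) {
      vm <- val_fwd(utils::relist(theta, skel))
      record <- rbind(record, data.frame(
        epoch = epoch, train_loss = fl$loss,
        val_loss = vm$loss, val_cindex = vm$cindex))
      if (vm$metric > best_metric + 1e-12) {
        best_metric <- vm$metric
        best_theta <- theta
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (tcfg$patience > 0L && stall >= tcfg$patience) break
      }
    } else {
      record <- rbind(record, data.frame(
        epoch = epoch, train_loss = fl$loss,
        val_loss = NA_real_, val_cindex = NA_real_))
      best_theta <- theta
      best_epoch <- epoch
    }
  }
  list(theta = best_theta, record = record, best_epoch = best_epoch)
}

prep_training_pair <- function(cohort_train, cohort_val, standardize) {
  std <- NULL
  if (standardize) {
    std <- fit_standardizer(cohort_train)
    cohort_train <- apply_standardizer(std, cohort_train)
    if (!is.null(cohort_val)) cohort_val <- apply_standardizer(std, cohort_val)
  }
  list(train = cohort_train, val = cohort_val, std = std)
}

minibatches <- function(n, batch_size) {
  if (is.null(batch_size) || batch_size >= n) return(list(seq_len(n)))
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Train the transformer survival model
#'
#' Minimizes the Cox negative log partial likelihood ([cox_nll()]) over the
#' training cohort with Adam plus L2 weight decay, evaluating the validation
#' cohort after every epoch and returning the weights of the best validation
#' epoch (early stopping). With full-cohort batches (the default) risk sets
#' are exact; in minibatch mode risk sets are formed within each shuffled
#' batch.
#'
#' @param cohort_train training `survival_cohort` (>= 1 event).
#' @param cohort_val validation `survival_cohort`, or `NULL` (allowed only
#'   with `patience = 0`; training then runs all epochs and keeps the final
#'   weights).
#' @param mcfg a [model_config()]; its `n_features` must match the cohort.
#' @param tcfg a [train_config()].
#' @param standardize fit a per-gene [fit_standardizer()] on the training
#'   cohort and bundle it with the model (default `TRUE`).
#' @return An object of class `coxformer_model`: list with `params`, `cfg`,
#'   `tcfg`, `standardizer`, `genes` and `record` (a `train_record`
#'   data.frame of per-epoch train loss, validation loss and validation
#'   C-index, with attribute `best_epoch`).
#' @export
train_coxformer <- function(cohort_train, cohort_val = NULL, mcfg, tcfg,
                            standardize = TRUE) {
  stopifnot(inherits(mcfg, "model_config"), inherits(tcfg, "train_config"))
  if (is.null(cohort_val) && tcfg$patience > 0L) {
    stop_cf("a validation cohort is required unless patience = 0",
            class = "coxformer_config_error")
  }
  if (ncol(cohort_train$X) != mcfg$n_features) {
    stop_cf("cohort has ", ncol(cohort_train$X),
            " genes but model_config expects ", mcfg$n_features,
            class = "coxformer_validation_error")
  }
  pp <- prep_training_pair(cohort_train, cohort_val, standardize)
  tr <- pp$train; va <- pp$val
  params <- coxformer_init(mcfg, seed = tcfg$seed)
  skel <- params
  theta <- unlist(params, use.names = FALSE)
  res <- with_seed(tcfg$seed + 1L, {
    fwd_loss <- function(p) {
      batches <- minibatches(nrow(tr$X), tcfg$batch_size)
      total <- 0
      grads <- NULL
      n_ev <- sum(tr$event)
      for (b in batches) {
        fw <- coxformer_forward(p, tr$X[b, , drop = FALSE], mcfg,
                                training = TRUE)
        cl <- cox_nll(fw$pi, tr$time[b], tr$event[b], grad = TRUE)
        g <- coxformer_backward(p, mcfg, fw$cache, cl$grad / n_ev)
        total <- total + cl$value / n_ev
        grads <- if (is.null(grads)) g else {
          mapply_flat_add(grads, g)
        }
      }
      list(loss = total, grads = grads)
    }
    val_fwd <- function(p) {
      fw <- coxformer_forward(p, va$X, mcfg, training = FALSE)
      list(loss = cox_nll(fw$pi, va$time, va$event) / max(1, sum(va$event)),
           cindex = tryCatch(
             concordance_index(fw$pi, va$time, va$event,
                               tie_policy = "half")$cindex,
             coxformer_metric_error = function(e) NA_real_),
           metric = validation_metric(fw$pi, va))
    }
    run_train_loop(theta, skel, fwd_loss,
                   if (!is.null(va)) val_fwd else NULL,
                   tcfg, has_val = !is.null(va))
  })
  record <- res$record
  attr(record, "best_epoch") <- res$best_epoch
  class(record) <- c("train_record", class(record))
  structure(list(params = utils::relist(res$theta, skel), cfg = mcfg,
                 tcfg = tcfg, standardizer = pp$std,
                 genes = cohort_train$genes, record = record),
            class = "coxformer_model")
}

# elementwise sum of two parameter-shaped gradient lists
mapply_flat_add <- function(a, b) {
  utils::relist(unlist(a, use.names = FALSE) + unlist(b, use.names = FALSE), a)
}

#' Train the linear Cox baseline
#'
#' The degenerate single-linear-layer case of the same objective: the risk is
#' `X beta`, optimized with the identical Adam/early-stopping loop. Serves as
#' the in-repo proportional-hazards baseline against which the attention
#' model's nonlinear gains are measured.
#'
#' @inheritParams train_coxformer
#' @return An object of class `linear_cox_model` with fields `beta` (named
#'   fitted coefficients), `standardizer`, `genes`, `tcfg` and `record`.
#' @export
train_linear_cox <- function(cohort_train, cohort_val = NULL, tcfg,
                             standardize = TRUE) {
  stopifnot(inherits(tcfg, "train_config"))
  if (is.null(cohort_val) && tcfg$patience > 0L) {
    stop_cf("a validation cohort is required unless patience = 0",
            class = "coxformer_config_error")
  }
  pp <- prep_training_pair(cohort_train, cohort_val, standardize)
  tr <- pp$train; va <- pp$val
  G <- ncol(tr$X)
  skel <- list(beta = matrix(0, G, 1L))
  theta <- unlist(skel, use.names = FALSE)
  res <- with_seed(tcfg$seed + 1L, {
    fwd_loss <- function(p) {
      batches <- minibatches(nrow(tr$X), tcfg$batch_size)
      total <- 0
      gbeta <- matrix(0, G, 1L)
      n_ev <- sum(tr$event)
      for (b in batches) {
        r <- drop(tr$X[b, , drop = FALSE] %*% p$beta)
        cl <- cox_nll(r, tr$time[b], tr$event[b], grad = TRUE)
        total <- total + cl$value / n_ev
        gbeta <- gbeta + crossprod(tr$X[b, , drop = FALSE], cl$grad) / n_ev
      }
      list(loss = total, grads = list(beta = gbeta))
    }
    val_fwd <- function(p) {
      r <- drop(va$X %*% p$beta)
      list(loss = cox_nll(r, va$time, va$event) / max(1, sum(va$event)),
           cindex = tryCatch(
             concordance_index(r, va$time, va$event,
                               tie_policy = "half")$cindex,
             coxformer_metric_error = function(e) NA_real_),
           metric = validation_metric(r, va))
    }
    run_train_loop(theta, skel, fwd_loss,
                   if (!is.null(va)) val_fwd else NULL,
                   tcfg, has_val = !is.null(va))
  })
  record <- res$record
  attr(record, "best_epoch") <- res$best_epoch
  class(record) <- c("train_record", class(record))
  structure(list(beta = stats::setNames(drop(res$theta), tr$genes),
                 standardizer = pp$std, genes = cohort_train$genes,
                 tcfg = tcfg, record = record),
            class = "linear_cox_model")
}

#' Predict per-sample risk (Prognosis Index)
#'
#' Deterministic evaluation-mode forward pass (dropout off). If the model
#' was trained with standardization, the bundled training standardizer is
#' applied to the cohort first, so the caller passes raw (unstandardized)
#' expression.
#'
#' @param model a `coxformer_model` or `linear_cox_model`.
#' @param cohort a `survival_cohort` on the model's gene space (or a plain
#'   numeric matrix, taken as already standardized).
#' @return numeric vector of risk scores, one per sample, in cohort order;
#'   higher = worse predicted prognosis.
#' @export
predict_risk <- function(model, cohort) UseMethod("predict_risk")

prep_predict_matrix <- function(model, cohort) {
  if (is.matrix(cohort)) return(cohort)
  stopifnot(inherits(cohort, "survival_cohort"))
  if (!identical(model$genes, cohort$genes)) {
    stop_cf("cohort gene space does not match the model",
            class = "coxformer_validation_error")
  }
  if (!is.null(model$standardizer)) {
    cohort <- apply_standardizer(model$standardizer, cohort)
  }
  cohort$X
}

#' @export
predict_risk.coxformer_model <- function(model, cohort) {
  X <- prep_predict_matrix(model, cohort)
  coxformer_forward(model$params, X, model$cfg, training = FALSE)$pi
}

#' @export
predict_risk.linear_cox_model <- function(model, cohort) {
  X <- prep_predict_matrix(model, cohort)
  drop(X %*% model$beta)
}

#' @rdname predict_risk
#' @export
predict_pi <- predict_risk

#' Export a per-epoch training record as CSV
#'
#' @param model a trained model with a `record` field.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_train_record <- function(model, path) {
  utils::write.csv(as.data.frame(model$record), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a self-contained model checkpoint
#'
#' The checkpoint bundles the weights, architecture configuration, fitted
#' standardizer and gene list, so [predict_risk()] on a reloaded checkpoint
#' needs nothing else.
#'
#' @param model a trained model.
#' @param path checkpoint file path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
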