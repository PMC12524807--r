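# Sampling-based Shapley attribution of the Prognosis Index to genes.
# Coalitions are drawn with probability proportional to the Shapley kernel
# weight of their size; feature values outside a coalition are replaced by
# background-sample values; attributions come from the final least-squares
# solve with the local-accuracy constraint enforced exactly.

shapley_kernel_sizes <- function(G, n_half) {
  s <- seq_len(G - 1L)
  w <- (G - 1) / (s * (G - s))
  sample(s, n_half, replace = TRUE, prob = w / sum(w))
}

sample_coalitions <- function(G, n_coalitions) {
  n_half <- n_coalitions %/% 2L
  sizes <- shapley_kernel_sizes(G, n_half)
  Z <- matrix(FALSE, 2L * n_half, G)
  for (k in seq_len(n_half)) {
    on <- sample.int(G, sizes[k])
    Z[2L * k - 1L, on] <- TRUE
    Z[2L * k, -on] <- TRUE  # antithetic complement
  }
  Z
}

# mean model output over the background for every coalition of one explained
# sample, evaluated in chunks to bound memory
coalition_values <- function(f, x, Bg, Z, chunk_coalitions) {
  n_bg <- nrow(Bg)
  nC <- nrow(Z)
  v <- numeric(nC)
  for (start in seq(1L, nC, by = chunk_coalitions)) {
    block <- start:min(start + chunk_coalitions - 1L, nC)
    M <- Bg[rep(seq_len(n_bg), length(block)), , drop = FALSE]
    for (bi in seq_along(block)) {
      z <- Z[block[bi], ]
      if (any(z)) {
        rows <- (bi - 1L) * n_bg + seq_len(n_bg)
        M[rows, z] <- rep(x[z], each = n_bg)
      }
    }
    fv <- f(M)
    v[block] <- colMeans(matrix(fv, n_bg, length(block)))
  }
  v
}

solve_shapley_ls <- function(Z, v, f0, fx) {
  G <- ncol(Z)
  Zn <- Z * 1
  y <- v - f0 - Zn[, G] * (fx - f0)
  Zc <- Zn[, -G, drop = FALSE] - Zn[, G]
  A <- crossprod(Zc)
  diag(A) <- diag(A) + 1e-8  # ridge jitter for rank-deficient draws
  phi_head <- drop(solve(A, crossprod(Zc, y)))
  c(phi_head, (fx - f0) - sum(phi_head))
}

#' Shapley gene attributions for a trained survival model
#'
#' Estimates, per explained sample and gene, the Shapley contribution of
#' that gene to the model's Prognosis Index relative to a background
#' expectation. Random feature coalitions are sampled in antithetic pairs
#' with probability proportional to the Shapley kernel weight; genes outside
#' a coalition take background-sample values; the final constrained
#' least-squares solve makes `baseline + sum(attributions)` equal each
#' sample's prediction exactly (local accuracy).
#'
#' For a well-posed solve, `n_coalitions` should exceed the number of genes.
#'
#' @param model a `coxformer_model` or `linear_cox_model`.
#' @param cohort `survival_cohort` of samples to explain (model gene space).
#' @param background `survival_cohort` supplying the reference distribution,
#'   typically training data; subsampled to `n_background` rows.
#' @param n_coalitions number of sampled coalitions per explained sample
#'   (rounded down to an even count; default 2048).
#' @param n_background background rows to keep (default 50).
#' @param background_mode `"sample"` (default) averages model output over the
#'   background rows for every coalition; `"mean"` imputes missing features
#'   with the background column means (one synthetic reference row), which
#'   removes background-sampling noise from the estimate at the price of a
#'   mean-imputation approximation for nonlinear models.
#' @param seed RNG seed controlling the background subsample and coalition
#'   draws.
#' @param chunk_coalitions coalitions evaluated per model call (memory
#'   knob).
#' @return An object of class `attribution_result`: list with `phi`
#'   (samples x genes matrix), `baseline` (expected PI over the background),
#'   `pi` (explained samples' predictions), and `genes`.
#' @export
shapley_attributions <- function(model, cohort, background,
                                 n_coalitions = 2048, n_background = 50,
                                 seed = 1, chunk_coalitions = 256,
                                 background_mode = c("sample", "mean")) {
  background_mode <- match.arg(background_mode)
  stopifnot(inherits(cohort, "survival_cohort"),
            inherits(background, "survival_cohort"))
  if (!identical(model$genes, cohort$genes) ||
      !identical(model$genes, background$genes)) {
    stop_cf("model, cohort and background gene spaces must match",
            class = "coxformer_validation_error")
  }
  if (nrow(background$X) == 0L) {
    stop_cf("background must be non-empty", class = "coxformer_validation_error")
  }
  n_coalitions <- 2L * (as.integer(n_coalitions) %/% 2L)
  if (n_coalitions < 2L) {
    stop_cf("n_coalitions must be at least 2", class = "coxformer_config_error")
  }
  # work in the model's standardized input space; column-wise affine
  # standardization commutes with coalition mixing
  Xe <- prep_predict_matrix(model, cohort)
  Bg <- prep_predict_matrix(model, background)
  f <- function(M) predict_risk(model, M)
  G <- ncol(Xe)
  if (n_coalitions < G) {
    warning("n_coalitions < number of genes: the least-squares solve is ",
            "under-determined and attributions will be heavily shrunk")
  }
  with_seed(seed, {
    if (background_mode == "mean") {
      Bg <- matrix(colMeans(Bg), 1L, G)
    } else if (nrow(Bg) > n_background) {
      Bg <- Bg[sample.int(nrow(Bg), n_background), , drop = FALSE]
    }
    f0 <- mean(f(Bg))
    fx <- f(Xe)
    phi <- matrix(0, nrow(Xe), G,
                  dimnames = list(cohort$sample_ids, cohort$genes))
    for (s in seq_len(nrow(Xe))) {
      Z <- sample_coalitions(G, n_coalitions)
      v <- coalition_values(f, Xe[s, ], Bg, Z, chunk_coalitions)
      phi[s, ] <- solve_shapley_ls(Z, v, f0, fx[s])
    }
    structure(list(phi = phi, baseline = f0, pi = fx, genes = cohort$genes,
                   n_coalitions = n_coalitions),
              class = "attribution_result")
  })
}

#' Exact Shapley values by subset enumeration (small gene counts)
#'
#' Enumerates all 2^G coalitions and applies the Shapley weighting directly.
#' Exponential in G; guarded to G <= 14. Used as the independent oracle for
#' the sampling estimator.
#'
#' @inheritParams shapley_attributions
#' @param x numeric feature vector of the single sample to explain (in the
#'   model's standardized input space).
#' @param Bg background matrix (same space).
#' @param f prediction function over matrices.
#' @return numeric vector of exact Shapley values (length G).
#' @export
exact_shapley <- function(f, x, Bg) {
  G <- length(x)
  if (G > 14L) {
    stop_cf("exact enumeration is limited to 14 features",
            class = "coxformer_config_error")
  }
  n_bg <- nrow(Bg)
  masks <- 0:(2^G - 1L)
  Zall <- t(vapply(masks, function(m) as.logical(bitwAnd(m, 2^(0:(G - 1L))) > 0),
                   logical(G)))
  # value of every coalition
  v <- numeric(length(masks))
  for (k in seq_along(masks)) {
    M <- Bg
    z <- Zall[k, ]
    if (any(z)) M[, z] <- rep(x[z], each = n_bg)
    v[k] <- mean(f(M))
  }
  sizes <- rowSums(Zall)
  phi <- numeric(G)
  # |S|! (G-|S|-1)! / G!  (only needed for |S| <= G-1; the full coalition
  # never appears as a "without-j" set)
  wt <- ifelse(sizes <= G - 1,
               exp(lgamma(sizes + 1) + lgamma(G - sizes) - lgamma(G + 1)), 0)
  for (j in seq_len(G)) {
    without <- which(!Zall[, j])
    with_j <- without + 2^(j - 1L)
    phi[j] <- sum(wt[without] * (v[with_j] - v[without]))
  }
  phi
}

#' Closed-form Shapley values for a linear risk model
#'
#' For risk `f(x) = beta' x`, the Shapley value of gene j explaining sample
#' x against a background B is `beta_j * (x_j - mean_B(x_j))`.
#'
#' @param beta coefficient vector.
#' @param x explained feature vector.
#' @param Bg background matrix.
#' @return numeric vector of analytic Shapley values.
#' @export
linear_shapley <- function(beta, x, Bg) {
  drop(beta * (x - colMeans(Bg)))
}

#' Rank genes by global attribution magnitude
#'
#' Global importance is the mean absolute attribution over explained
#' samples; signed means are reported alongside. Ties break by gene order.
#'
#' @param result an `attribution_result`.
#' @param top_k optionally keep only the first `top_k` ranked genes (clipped
#'   with a warning if larger than the gene count).
#' @return data.frame with columns `gene`, `mean_abs`, `mean_signed`,
#'   ordered by decreasing `mean_abs`.
#' @export
rank_genes <- function(result, top_k = NULL) {
  stopifnot(inherits(result, "attribution_result"))
  mean_abs <- colMeans(abs(result$phi))
  mean_signed <- colMeans(result$phi)
  ord <- order(-mean_abs, seq_along(mean_abs))
  out <- data.frame(gene = result$genes[ord],
                    mean_abs = mean_abs[ord],
                    mean_signed = mean_signed[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(top_k)) {
    if (top_k > nrow(out)) {
      warning("top_k exceeds gene count; returning all genes")
      top_k <- nrow(out)
    }
    out <- out[seq_len(top_k), , drop = FALSE]
  }
  out
}

#' Write attribution outputs as CSV
#'
#' @param result an `attribution_result`.
#' @param matrix_path per-sample attribution matrix CSV.
#' @param ranking_path global ranking CSV.
#' @return invisibly, the two paths.
#' @export
write_attributions <- function(result, matrix_path, ranking_path) {
  utils::write.csv(as.data.frame(result$phi), matrix_path, row.names = TRUE)
  utils::write.csv(rank_genes(result), ranking_path, row.names = FALSE)
  invisible(c(matrix_path, ranking_path))
}
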