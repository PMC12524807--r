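test_that("the token count follows the floor rule and the CLS extends the sequence", {
  cfg <- model_config(539, token_dim = 64)
  expect_equal(cfg$num_tokens, 8L)   # floor(539 / 64)
  expect_equal(cfg$d_k, 8L)
  p <- coxformer_init(cfg, seed = 1)
  X <- withr::with_seed(2, matrix(rnorm(3 * 539), 3, 539))
  seq3 <- embed_features(X, p, cfg)
  expect_equal(dim(seq3), c(3, 9, 64))   # num_tokens + 1 with CLS
  # CLS position is the same learned vector for every sample
  expect_equal(seq3[1, 1, ], seq3[2, 1, ])
  expect_equal(seq3[1, 1, ], unname(p$cls))

  cfg2 <- model_config(64, token_dim = 64)
  expect_equal(cfg2$num_tokens, 1L)
  expect_error(model_config(32, token_dim = 64),
               class = "coxformer_config_error")
  expect_error(model_config(128, token_dim = 64, num_heads = 7),
               class = "coxformer_config_error")
})

test_that("scaled dot-product attention matches hand-computed cases", {
  # m = 1: softmax of a single score is 1, output is V
  V <- matrix(c(2, 3), 1, 2)
  expect_equal(scaled_dot_product_attention(matrix(1), matrix(5), V), V)
  # identical keys: uniform weights, every output row is the V column mean
  Q <- withr::with_seed(1, matrix(rnorm(6), 3, 2))
  K <- matrix(1, 3, 2)
  V2 <- withr::with_seed(2, matrix(rnorm(9), 3, 3))
  out <- scaled_dot_product_attention(Q, K, V2)
  for (i in 1:3) expect_equal(out[i, ], colMeans(V2))
  # d_k = 1, Q = K = V = [[1], [0]]: first row weight e/(e+1)
  M <- matrix(c(1, 0), 2, 1)
  res <- scaled_dot_product_attention(M, M, M, return_weights = TRUE)
  expect_equal(res$weights[1, ], c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(res$output[1, 1], exp(1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(rowSums(res$weights), c(1, 1))
})

test_that("attention weights sum to one at every head inside the encoder", {
  cfg <- model_config(24, token_dim = 8, num_heads = 4, num_blocks = 2,
                      dropout = 0)
  p <- coxformer_init(cfg, seed = 3)
  X <- withr::with_seed(4, matrix(rnorm(5 * 24), 5, 24))
  fw <- coxformer:::coxformer_forward(p, X, cfg)
  for (bc in fw$cache$bcaches) {
    for (A_h in bc$at$cache$A) {
      for (A in A_h) expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
    }
  }
})

test_that("a block with zero weights is the identity map (residual wiring)", {
  cfg <- model_config(16, token_dim = 4, num_heads = 2, num_blocks = 1,
                      dropout = 0)
  p <- coxformer_init(cfg, seed = 1)
  p$blocks[[1]] <- rapply(p$blocks[[1]], function(x) x * 0, how = "replace")
  X <- withr::with_seed(5, matrix(rnorm(4 * 16), 4, 16))
  cfg0 <- model_config(16, token_dim = 4, num_heads = 2, num_blocks = 0,
                       dropout = 0)
  p0 <- p; p0$blocks <- list()
  fw1 <- coxformer:::coxformer_forward(p, X, cfg)
  fw0 <- coxformer:::coxformer_forward(p0, X, cfg0)
  expect_equal(fw1$pi, fw0$pi, tolerance = 1e-12)
})

test_that("blocks preserve sequence shape for one and two layers", {
  X <- withr::with_seed(6, matrix(rnorm(3 * 32), 3, 32))
  for (nb in 1:2) {
    cfg <- model_config(32, token_dim = 8, num_heads = 2, num_blocks = nb,
                        dropout = 0)
    p <- coxformer_init(cfg, seed = 2)
    fw <- coxformer:::coxformer_forward(p, X, cfg)
    expect_length(fw$pi, 3)
  }
})

test_that("with no encoder blocks the head sees only the sample-independent CLS", {
  cfg <- model_config(16, token_dim = 8, num_heads = 2, num_blocks = 0,
                      dropout = 0)
  p <- coxformer_init(cfg, seed = 1)
  X <- withr::with_seed(7, matrix(rnorm(6 * 16), 6, 16))
  pi_hat <- coxformer:::coxformer_forward(p, X, cfg)$pi
  expect_equal(diff(range(pi_hat)), 0)
})

test_that("permuting tokens together with the embedding map leaves the PI unchanged", {
  cfg <- model_config(40, token_dim = 8, num_heads = 2, num_blocks = 2,
                      dropout = 0)
  p <- coxformer_init(cfg, seed = 8)
  m0 <- cfg$num_tokens; d <- cfg$token_dim
  perm <- withr::with_seed(9, sample(m0))
  # embedding output column c holds (token t, channel k) with
  # t = ((c-1) %% m0) + 1, k = ((c-1) %/% m0) + 1
  col_of <- function(t, k) (k - 1L) * m0 + t
  new_cols <- integer(m0 * d)
  for (k in seq_len(d)) for (t in seq_len(m0)) {
    new_cols[col_of(t, k)] <- col_of(perm[t], k)
  }
  p2 <- p
  p2$embed_W <- p$embed_W[, new_cols]
  p2$embed_b <- p$embed_b[new_cols]
  X <- withr::with_seed(10, matrix(rnorm(5 * 40), 5, 40))
  expect_equal(coxformer:::coxformer_forward(p2, X, cfg)$pi,
               coxformer:::coxformer_forward(p, X, cfg)$pi,
               tolerance = 1e-10)
})

test_that("inference is deterministic, batch-independent and order-equivariant", {
  cfg <- model_config(24, token_dim = 8, num_heads = 2, num_blocks = 2,
                      dropout = 0.5)  # dropout must be inert in eval mode
  p <- coxformer_init(cfg, seed = 4)
  X <- withr::with_seed(11, matrix(rnorm(7 * 24), 7, 24))
  f <- function(M) coxformer:::coxformer_forward(p, M, cfg)$pi
  expect_identical(f(X), f(X))
  one_by_one <- vapply(1:7, function(i) f(X[i, , drop = FALSE]), numeric(1))
  expect_equal(f(X), one_by_one, tolerance = 1e-5)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  expect_equal(f(X[perm, ]), f(X)[perm], tolerance = 1e-10)
})

test_that("a zeroed prediction head yields PI 0 for every sample", {
  cfg <- model_config(16, token_dim = 8, num_heads = 2, num_blocks = 1,
                      dropout = 0)
  p <- coxformer_init(cfg, seed = 5)
  p$head_w <- p$head_w * 0
  p$head_b <- 0
  X <- withr::with_seed(12, matrix(rnorm(4 * 16), 4, 16))
  expect_equal(coxformer:::coxformer_forward(p, X, cfg)$pi, rep(0, 4))
})

test_that("the parameter count is a deterministic function of the configuration", {
  cfg <- model_config(128, token_dim = 32, num_heads = 4, num_blocks = 2,
                      dropout = 0.1)
  p <- coxformer_init(cfg, seed = 1)
  # hand count: input LN 2*128; embed 128*128 + 128; cls 32;
  # per block: 2 LNs 4*32, attn 4*(32*32 + 32), ffn 32*128 + 128 + 128*32 + 32;
  # output LN 64; head 32 + 1
  per_block <- 4 * 32 + 4 * (32 * 32 + 32) + 32 * 128 + 128 + 128 * 32 + 32
  expected <- 2 * 128 + (128 * 128 + 128) + 32 + 2 * per_block + 64 + 33
  expect_equal(coxformer_n_params(p), expected)
  expect_equal(coxformer_n_params(coxformer_init(cfg, seed = 99)), expected)
})

test_that("the full backward pass matches finite differences (pre and post norm)", {
  X <- withr::with_seed(9, matrix(rnorm(6 * 8), 6, 8))
  tt <- withr::with_seed(10, runif(6))
  ee <- c(1, 1, 0, 1, 0, 1)
  for (np in c("pre", "post")) {
    cfg <- model_config(8, token_dim = 4, num_heads = 2, num_blocks = 2,
                        dropout = 0, norm_placement = np)
    p <- coxformer_init(cfg, seed = 2)
    fw <- coxformer:::coxformer_forward(p, X, cfg)
    cl <- cox_nll(fw$pi, tt, ee, grad = TRUE)
    gr <- coxformer:::coxformer_backward(p, cfg, fw$cache, cl$grad)
    th <- unlist(p); gth <- unlist(gr)
    idx <- withr::with_seed(1, sample(length(th), 40))
    lf <- function(v) {
      f <- coxformer:::coxformer_forward(utils::relist(v, p), X, cfg)
      cox_nll(f$pi, tt, ee)
    }
    h <- 1e-5
    fd <- vapply(idx, function(i) {
      up <- th; up[i] <- up[i] + h
      dn <- th; dn[i] <- dn[i] - h
      (lf(up) - lf(dn)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(gth[idx] - fd)), 1e-4)
  }
})
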