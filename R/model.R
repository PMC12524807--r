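#' Model architecture configuration
#'
#' The encoder consumes a length-G expression vector, layer-normalizes it,
#' projects it with one dense map into `num_tokens = floor(G / token_dim)`
#' tokens of width `token_dim`, prepends a learnable CLS token, runs
#' `num_blocks` multi-head self-attention encoder blocks, and maps the
#' normalized CLS output to the scalar Prognosis Index. The dense projection
#' consumes all G features (every token can see every gene); the floor
#' formula fixes only the token count.
#'
#' @param n_features number of input genes G (after signature alignment).
#' @param token_dim token width (default 64).
#' @param num_heads attention heads; must divide `token_dim` (default 8).
#' @param num_blocks encoder blocks (default 2). 0 is allowed as a wiring
#'   check: the head then sees the (sample-independent) CLS embedding.
#' @param dropout dropout rate in \[0, 1) applied after the attention and
#'   feed-forward sub-layers during training (default 0.1).
#' @param norm_placement `"pre"` (normalize before each sub-layer; default)
#'   or `"post"`.
#' @param ffn_mult hidden width of the position-wise feed-forward sub-layer
#'   as a multiple of `token_dim` (default 4, GELU activation).
#' @return a `model_config` list; `d_k = token_dim / num_heads` is the
#'   per-head key dimension.
#' @export
model_config <- function(n_features, token_dim = 64, num_heads = 8,
                         num_blocks = 2, dropout = 0.1,
                         norm_placement = c("pre", "post"), ffn_mult = 4) {
  norm_placement <- match.arg(norm_placement)
  check_scalar_num(n_features, "n_features", lower = 1, integer = TRUE)
  check_scalar_num(token_dim, "token_dim", lower = 1, integer = TRUE)
  check_scalar_num(num_heads, "num_heads", lower = 1, integer = TRUE)
  check_scalar_num(num_blocks, "num_blocks", lower = 0, integer = TRUE)
  check_scalar_num(dropout, "dropout", lower = 0, upper = 1)
  if (dropout >= 1) {
    stop_cf("dropout must be < 1", class = "coxformer_config_error")
  }
  num_tokens <- n_features %/% token_dim
  if (num_tokens < 1L) {
    stop_cf("n_features (", n_features, ") < token_dim (", token_dim,
            "): num_tokens would be 0", class = "coxformer_config_error")
  }
  if (token_dim %% num_heads != 0L) {
    stop_cf("token_dim must be divisible by num_heads",
            class = "coxformer_config_error")
  }
  structure(list(n_features = as.integer(n_features),
                 token_dim = as.integer(token_dim),
                 num_tokens = as.integer(num_tokens),
                 num_heads = as.integer(num_heads),
                 num_blocks = as.integer(num_blocks),
                 dropout = dropout,
                 norm_placement = norm_placement,
                 ffn_mult = as.integer(ffn_mult),
                 d_k = as.integer(token_dim %/% num_heads)),
            class = "model_config")
}

# fan-in uniform, the conventional dense-layer initialization
init_linear <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  list(W = matrix(stats::runif(nin * nout, -lim, lim), nin, nout),
       b = stats::runif(nout, -lim, lim))
}

#' Initialize encoder parameters
#'
#' Dense maps use fan-in uniform initialization, layer norms start at
#' identity, the CLS vector is small-normal, and the head bias is zero. All
#' draws come from `seed`.
#'
#' @param cfg a [model_config()].
#' @param seed integer RNG seed.
#' @return nested parameter list (internal layout; see [coxformer_n_params()]).
#' @export
coxformer_init <- function(cfg, seed = 1) {
  with_seed(seed, {
    G <- cfg$n_features; d <- cfg$token_dim
    emb <- init_linear(G, cfg$num_tokens * d)
    hid <- cfg$ffn_mult * d
    blocks <- lapply(seq_len(cfg$num_blocks), function(b) {
      a <- list(Wq = init_linear(d, d), Wk = init_linear(d, d),
                Wv = init_linear(d, d), Wo = init_linear(d, d))
      f1 <- init_linear(d, hid); f2 <- init_linear(hid, d)
      list(ln1_g = rep(1, d), ln1_b = rep(0, d),
           attn = list(Wq = a$Wq$W, bq = a$Wq$b, Wk = a$Wk$W, bk = a$Wk$b,
                       Wv = a$Wv$W, bv = a$Wv$b, Wo = a$Wo$W, bo = a$Wo$b),
           ln2_g = rep(1, d), ln2_b = rep(0, d),
           W1 = f1$W, b1 = f1$b, W2 = f2$W, b2 = f2$b)
    })
    head <- init_linear(d, 1L)
    list(ln_in_g = rep(1, G), ln_in_b = rep(0, G),
         embed_W = emb$W, embed_b = emb$b,
         cls = stats::rnorm(d, sd = 0.02),
         blocks = blocks,
         ln_out_g = rep(1, d), ln_out_b = rep(0, d),
         head_w = drop(head$W), head_b = 0)
  })
}

#' Number of trainable parameters
#'
#' @param params parameter list from [coxformer_init()].
#' @return integer parameter count.
#' @export
coxformer_n_params <- function(params) length(unlist(params, use.names = FALSE))

#' Embed an expression batch into a token sequence
#'
#' Layer-normalizes each sample's feature vector, applies the dense token
#' projection, reshapes into `num_tokens` tokens of width `token_dim`, and
#' prepends the learned CLS token.
#'
#' @param X numeric matrix (samples x n_features).
#' @param params parameters from [coxformer_init()].
#' @param cfg the matching [model_config()].
#' @return 3D array samples x (num_tokens + 1) x token_dim; position 1 along
#'   the token axis is the CLS token.
#' @export
embed_features <- function(X, params, cfg) {
  fw <- coxformer_forward(params, X, cfg, training = FALSE)
  S0 <- fw$cache$S0
  n <- fw$cache$n; m <- fw$cache$m; d <- fw$cache$d
  A <- array(0, c(n, m, d))
  for (i in seq_len(m)) A[, i, ] <- S0[token_rows(i, n), ]
  A
}

block_fwd <- function(Sm, n, m, p, cfg, training) {
  if (cfg$norm_placement == "pre") {
    l1 <- ln_fwd(Sm, p$ln1_g, p$ln1_b)
    at <- mha_fwd(l1$Y, n, m, p$attn, cfg$num_heads)
    d1 <- dropout_fwd(at$Y, cfg$dropout, training)
    Sm1 <- Sm + d1$Y
    l2 <- ln_fwd(Sm1, p$ln2_g, p$ln2_b)
    f1 <- linear_fwd(l2$Y, p$W1, p$b1)
    ge <- gelu_fwd(f1$Y)
    f2 <- linear_fwd(ge$Y, p$W2, p$b2)
    d2 <- dropout_fwd(f2$Y, cfg$dropout, training)
    out <- Sm1 + d2$Y
  } else {
    at <- mha_fwd(Sm, n, m, p$attn, cfg$num_heads)
    d1 <- dropout_fwd(at$Y, cfg$dropout, training)
    l1 <- ln_fwd(Sm + d1$Y, p$ln1_g, p$ln1_b)
    Sm1 <- l1$Y
    f1 <- linear_fwd(Sm1, p$W1, p$b1)
    ge <- gelu_fwd(f1$Y)
    f2 <- linear_fwd(ge$Y, p$W2, p$b2)
    d2 <- dropout_fwd(f2$Y, cfg$dropout, training)
    l2 <- ln_fwd(Sm1 + d2$Y, p$ln2_g, p$ln2_b)
    out <- l2$Y
  }
  list(S = out,
       cache = list(l1 = l1, at = at, d1 = d1, l2 = l2,
                    f1 = f1, ge = ge, f2 = f2, d2 = d2, n = n, m = m))
}

block_bwd <- function(dSm, cache, p, cfg) {
  g <- list()
  if (cfg$norm_placement == "pre") {
    dd2 <- dropout_bwd(dSm, cache$d2)
    b2 <- linear_bwd(dd2, cache$f2, p$W2)
    dge <- gelu_bwd(b2$dX, cache$ge)
    b1 <- linear_bwd(dge, cache$f1, p$W1)
    l2b <- ln_bwd(b1$dX, cache$l2, p$ln2_g)
    dSm1 <- dSm + l2b$dX
    dd1 <- dropout_bwd(dSm1, cache$d1)
    ab <- mha_bwd(dd1, cache$at$cache, p$attn)
    l1b <- ln_bwd(ab$dX, cache$l1, p$ln1_g)
    dIn <- dSm1 + l1b$dX
  } else {
    l2b <- ln_bwd(dSm, cache$l2, p$ln2_g)
    dres2 <- l2b$dX
    dd2 <- dropout_bwd(dres2, cache$d2)
    b2 <- linear_bwd(dd2, cache$f2, p$W2)
    dge <- gelu_bwd(b2$dX, cache$ge)
    b1 <- linear_bwd(dge, cache$f1, p$W1)
    dSm1 <- dres2 + b1$dX
    l1b <- ln_bwd(dSm1, cache$l1, p$ln1_g)
    dres1 <- l1b$dX
    dd1 <- dropout_bwd(dres1, cache$d1)
    ab <- mha_bwd(dd1, cache$at$cache, p$attn)
    dIn <- dres1 + ab$dX
  }
  g$ln1_g <- l1b$dg; g$ln1_b <- l1b$db
  g$attn <- ab$grads
  g$ln2_g <- l2b$dg; g$ln2_b <- l2b$db
  g$W1 <- b1$dW; g$b1 <- b1$db; g$W2 <- b2$dW; g$b2 <- b2$db
  list(dIn = dIn, grads = g)
}

# Full forward pass. In training mode dropout masks are drawn from the
# active RNG stream and cached for the backward pass.
coxformer_forward <- function(params, X, cfg, training = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != cfg$n_features) {
    stop_cf("input has ", ncol(X), " features but the model expects ",
            cfg$n_features, class = "coxformer_validation_error")
  }
  n <- nrow(X)
  li <- ln_fwd(X, params$ln_in_g, params$ln_in_b)
  le <- linear_fwd(li$Y, params$embed_W, params$embed_b)
  m <- cfg$num_tokens + 1L
  d <- cfg$token_dim
  Sm <- matrix(0, n * m, d)
  Sm[seq_len(n), ] <- matrix(params$cls, n, d, byrow = TRUE)
  Earr <- array(le$Y, c(n, cfg$num_tokens, d))
  for (t in seq_len(cfg$num_tokens)) {
    Et <- Earr[, t, , drop = FALSE]; dim(Et) <- c(n, d)
    Sm[token_rows(t + 1L, n), ] <- Et
  }
  S0 <- Sm
  bcaches <- vector("list", cfg$num_blocks)
  for (b in seq_len(cfg$num_blocks)) {
    bf <- block_fwd(Sm, n, m, params$blocks[[b]], cfg, training)
    Sm <- bf$S
    bcaches[[b]] <- bf$cache
  }
  cls_out <- Sm[seq_len(n), , drop = FALSE]
  lo <- ln_fwd(cls_out, params$ln_out_g, params$ln_out_b)
  pi_hat <- drop(lo$Y %*% params$head_w) + params$head_b
  list(pi = pi_hat,
       cache = list(li = li, le = le, S0 = S0, bcaches = bcaches,
                    lo = lo, n = n, m = m, d = d))
}

coxformer_backward <- function(params, cfg, cache, dpi) {
  n <- cache$n; m <- cache$m; d <- cache$d
  grads <- rapply(params, function(x) x * 0, how = "replace")
  grads$head_w <- drop(crossprod(cache$lo$Y, dpi))
  grads$head_b <- sum(dpi)
  dlo <- outer(dpi, params$head_w)
  lob <- ln_bwd(dlo, cache$lo, params$ln_out_g)
  grads$ln_out_g <- lob$dg; grads$ln_out_b <- lob$db
  dSm <- matrix(0, n * m, d)
  dSm[seq_len(n), ] <- lob$dX
  for (b in rev(seq_len(cfg$num_blocks))) {
    bb <- block_bwd(dSm, cache$bcaches[[b]], params$blocks[[b]], cfg)
    dSm <- bb$dIn
    grads$blocks[[b]] <- bb$grads
  }
  grads$cls <- colSums(dSm[seq_len(n), , drop = FALSE])
  dEarr <- array(0, c(n, cfg$num_tokens, d))
  for (t in seq_len(cfg$num_tokens)) {
    dEarr[, t, ] <- dSm[token_rows(t + 1L, n), ]
  }
  dE <- dEarr; dim(dE) <- c(n, cfg$num_tokens * d)
  eb <- linear_bwd(dE, cache$le, params$embed_W)
  grads$embed_W <- eb$dW; grads$embed_b <- eb$db
  lib <- ln_bwd(eb$dX, cache$li, params$ln_in_g)
  grads$ln_in_g <- lib$dg; grads$ln_in_b <- lib$db
  grads
}
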