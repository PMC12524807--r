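# Minimal dense-layer toolkit with hand-written backward passes.
# A token sequence for a batch of n samples is held "token-major" as a
# (n * m) x d matrix: rows (i-1)*n + 1 .. i*n hold token i for all samples.
# Linear and normalization ops then run on the whole matrix at once and the
# attention loops slice contiguous row blocks.

token_rows <- function(i, n) ((i - 1L) * n + 1L):(i * n)

linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, X = X)
}

linear_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# layer normalization over the channel (last) dimension, population variance
ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  nr <- nrow(X)
  Y <- xhat * rep(g, each = nr) + rep(b, each = nr)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

# GELU via the sigmoid approximation x * sigmoid(1.702 x); the cached
# sigmoid makes the backward pass a few elementwise ops
gelu_fwd <- function(X) {
  sg <- 1 / (1 + exp(-1.702 * X))
  list(Y = X * sg, X = X, sg = sg)
}

gelu_bwd <- function(dY, cache) {
  dY * (cache$sg + 1.702 * cache$X * cache$sg * (1 - cache$sg))
}

# inverted dropout; mask is drawn from the active RNG stream during training
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

rowmax <- function(M) {
  out <- M[, 1L]
  for (j in seq_len(ncol(M))[-1L]) out <- pmax(out, M[, j])
  out
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with the softmax applied row-wise,
#' so every row of the attention-weight matrix sums to 1. Exposed as a plain
#' matrix operation for inspection and testing; the encoder applies it per
#' sample and per head through learned projections.
#'
#' @param Q,K query and key matrices (m x d_k).
#' @param V value matrix (m x d_v).
#' @param return_weights also return the attention-weight matrix.
#' @return the m x d_v output matrix, or a list with `output` and `weights`.
#' @export
scaled_dot_product_attention <- function(Q, K, V, return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1L, max)
  W <- exp(S)
  W <- W / rowSums(W)
  out <- W %*% V
  if (return_weights) list(output = out, weights = W) else out
}

# Batched multi-head self-attention over a token-major (n*m) x d matrix.
# Per head, per-token row blocks are sliced once into lists of n x d_k
# matrices; attention scores and weighted sums accumulate with vectorized
# arithmetic over the batch dimension.
mha_fwd <- function(Yn, n, m, p, num_heads) {
  d <- ncol(Yn)
  dk <- d %/% num_heads
  lq <- linear_fwd(Yn, p$Wq, p$bq)
  lk <- linear_fwd(Yn, p$Wk, p$bk)
  lv <- linear_fwd(Yn, p$Wv, p$bv)
  Om <- matrix(0, n * m, d)
  A_all <- vector("list", num_heads)
  QKV <- vector("list", num_heads)
  scale <- 1 / sqrt(dk)
  for (h in seq_len(num_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    Qh <- vector("list", m); Kh <- vector("list", m); Vh <- vector("list", m)
    for (i in seq_len(m)) {
      r <- token_rows(i, n)
      Qh[[i]] <- lq$Y[r, idx, drop = FALSE]
      Kh[[i]] <- lk$Y[r, idx, drop = FALSE]
      Vh[[i]] <- lv$Y[r, idx, drop = FALSE]
    }
    A_h <- vector("list", m)
    for (i in seq_len(m)) {
      S <- matrix(0, n, m)
      Qi <- Qh[[i]]
      for (j in seq_len(m)) S[, j] <- rowSums(Qi * Kh[[j]])
      S <- S * scale
      S <- S - rowmax(S)
      E <- exp(S)
      A <- E / rowSums(E)
      A_h[[i]] <- A
      acc <- A[, 1L] * Vh[[1L]]
      for (j in seq_len(m)[-1L]) acc <- acc + A[, j] * Vh[[j]]
      Om[token_rows(i, n), idx] <- acc
    }
    A_all[[h]] <- A_h
    QKV[[h]] <- list(Q = Qh, K = Kh, V = Vh)
  }
  lo <- linear_fwd(Om, p$Wo, p$bo)
  list(Y = lo$Y,
       cache = list(lq = lq, lk = lk, lv = lv, lo = lo,
                    QKV = QKV, A = A_all,
                    n = n, m = m, dk = dk, num_heads = num_heads))
}

mha_bwd <- function(dY, cache, p) {
  n <- cache$n; m <- cache$m; dk <- cache$dk
  d <- dk * cache$num_heads
  bo <- linear_bwd(dY, cache$lo, p$Wo)
  dQm <- matrix(0, n * m, d)
  dKm <- matrix(0, n * m, d)
  dVm <- matrix(0, n * m, d)
  scale <- 1 / sqrt(dk)
  for (h in seq_len(cache$num_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    Qh <- cache$QKV[[h]]$Q; Kh <- cache$QKV[[h]]$K; Vh <- cache$QKV[[h]]$V
    A_h <- cache$A[[h]]
    dVh <- vector("list", m)
    dKh <- vector("list", m)
    zero <- matrix(0, n, dk)
    for (j in seq_len(m)) { dVh[[j]] <- zero; dKh[[j]] <- zero }
    for (i in seq_len(m)) {
      dOi <- bo$dX[token_rows(i, n), idx, drop = FALSE]
      A <- A_h[[i]]
      dA <- matrix(0, n, m)
      for (j in seq_len(m)) {
        dA[, j] <- rowSums(dOi * Vh[[j]])
        dVh[[j]] <- dVh[[j]] + A[, j] * dOi
      }
      dS <- A * (dA - rowSums(dA * A)) * scale
      dQi <- dS[, 1L] * Kh[[1L]]
      for (j in seq_len(m)[-1L]) dQi <- dQi + dS[, j] * Kh[[j]]
      dQm[token_rows(i, n), idx] <- dQi
      Qi <- Qh[[i]]
      for (j in seq_len(m)) dKh[[j]] <- dKh[[j]] + dS[, j] * Qi
    }
    for (j in seq_len(m)) {
      r <- token_rows(j, n)
      dKm[r, idx] <- dKh[[j]]
      dVm[r, idx] <- dVh[[j]]
    }
  }
  bq <- linear_bwd(dQm, cache$lq, p$Wq)
  bk <- linear_bwd(dKm, cache$lk, p$Wk)
  bv <- linear_bwd(dVm, cache$lv, p$Wv)
  list(dX = bq$dX + bk$dX + bv$dX,
       grads = list(Wq = bq$dW, bq = bq$db, Wk = bk$dW, bk = bk$db,
                    Wv = bv$dW, bv = bv$db, Wo = bo$dW, bo = bo$db))
}
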