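# Internal forward/backward primitives for the network engine.
# Feature maps are (H, W, C) arrays; token matrices are N x d (tokens in
# rows). Every *_fwd returns list(out, cache); *_bwd consumes the cache and
# the upstream gradient and returns gradients for inputs and parameters.

softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

# broadcast a per-column vector over the rows of a column-major matrix
bycol <- function(v, n) rep(v, each = n)

relu_fwd <- function(x) { x[x < 0] <- 0; x }

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + bycol(b, nrow(Y))
  Y
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(X)
  Y <- xhat * bycol(g, n) + bycol(b, n)
  list(out = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  dxhat <- dY * bycol(g, nrow(dY))
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# GELU x * Phi(x); Phi cached for the backward pass
ffn_fwd <- function(X, p) {
  H1pre <- linear_fwd(X, p$W1, p$b1)
  Phi <- pnorm(H1pre)
  H1 <- H1pre * Phi
  Y <- linear_fwd(H1, p$W2, p$b2)
  list(out = Y, cache = list(X = X, H1pre = H1pre, H1 = H1, Phi = Phi))
}

ffn_bwd <- function(dY, cache, p) {
  dW2 <- crossprod(cache$H1, dY)
  db2 <- colSums(dY)
  dH1 <- tcrossprod(dY, p$W2)
  dH1pre <- dH1 * (cache$Phi + cache$H1pre * dnorm(cache$H1pre))
  dW1 <- crossprod(cache$X, dH1pre)
  db1 <- colSums(dH1pre)
  dX <- tcrossprod(dH1pre, p$W1)
  list(dX = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

gelu_fwd <- function(x) x * pnorm(x)

# Multi-head self-attention over a set of (possibly windowed) token groups.
# X: N x d. p: list(Wq d x dm, Wk d x dm, Wv d x dv, B (T x T x heads) or
# NULL, Wo (dv x dout) or NULL). windows: list of row-index vectors into X
# (disjoint, covering the rows that attend). masks: NULL, or a list parallel
# to windows of additive T x T matrices (entries 0 / -1e9), or NULL entries.
msa_fwd <- function(X, p, windows, masks = NULL, n_heads, scale) {
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  dm <- ncol(Q); dv <- ncol(V)
  hq <- dm %/% n_heads; hv <- dv %/% n_heads
  Out <- matrix(0, nrow(X), dv)
  A_list <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    idx <- windows[[w]]
    Tn <- length(idx)
    Aw <- array(0, dim = c(Tn, Tn, n_heads))
    for (h in seq_len(n_heads)) {
      qc <- (h - 1L) * hq + seq_len(hq)
      vc <- (h - 1L) * hv + seq_len(hv)
      S <- tcrossprod(Q[idx, qc, drop = FALSE], K[idx, qc, drop = FALSE]) * scale
      if (!is.null(p$B)) S <- S + p$B[, , h]
      if (!is.null(masks) && !is.null(masks[[w]])) S <- S + masks[[w]]
      A <- softmax_rows(S)
      Aw[, , h] <- A
      Out[idx, vc] <- A %*% V[idx, vc, drop = FALSE]
    }
    A_list[[w]] <- Aw
  }
  Y <- if (is.null(p$Wo)) Out else Out %*% p$Wo
  list(out = Y,
       cache = list(X = X, Q = Q, K = K, V = V, Out = Out, A_list = A_list,
                    windows = windows, n_heads = n_heads, scale = scale))
}

msa_bwd <- function(dY, cache, p) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V
  n_heads <- cache$n_heads; scale <- cache$scale
  dm <- ncol(Q); dv <- ncol(V)
  hq <- dm %/% n_heads; hv <- dv %/% n_heads
  if (is.null(p$Wo)) {
    dOut <- dY; dWo <- NULL
  } else {
    dWo <- crossprod(cache$Out, dY)
    dOut <- tcrossprod(dY, p$Wo)
  }
  dQ <- matrix(0, nrow(Q), dm); dK <- matrix(0, nrow(K), dm)
  dV <- matrix(0, nrow(V), dv)
  dB <- if (is.null(p$B)) NULL else array(0, dim = dim(p$B))
  for (w in seq_along(cache$windows)) {
    idx <- cache$windows[[w]]
    Aw <- cache$A_list[[w]]
    for (h in seq_len(n_heads)) {
      qc <- (h - 1L) * hq + seq_len(hq)
      vc <- (h - 1L) * hv + seq_len(hv)
      A <- Aw[, , h]
      dO <- dOut[idx, vc, drop = FALSE]
      Vi <- V[idx, vc, drop = FALSE]
      dA <- tcrossprod(dO, Vi)
      dV[idx, vc] <- dV[idx, vc] + crossprod(A, dO)
      dS <- A * (dA - rowSums(dA * A))
      if (!is.null(dB)) dB[, , h] <- dB[, , h] + dS
      dQ[idx, qc] <- dQ[idx, qc] + dS %*% K[idx, qc, drop = FALSE] * scale
      dK[idx, qc] <- dK[idx, qc] + crossprod(dS, Q[idx, qc, drop = FALSE]) * scale
    }
  }
  dX <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  grads <- list(Wq = crossprod(X, dQ), Wk = crossprod(X, dK),
                Wv = crossprod(X, dV))
  if (!is.null(dB)) grads$B <- dB
  if (!is.null(dWo)) grads$Wo <- dWo
  list(dX = dX, grads = grads)
}

# ---- convolutions (im2col / col2im based) ----------------------------------

conv_fwd <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x); H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  outH <- (H + 2L * pad - k) %/% stride + 1L
  outW <- (Wd + 2L * pad - k) %/% stride + 1L
  cols <- .im2col(as.numeric(x), H, Wd, C, k, stride, pad)
  Y <- cols %*% W
  if (!is.null(b)) Y <- Y + bycol(b, nrow(Y))
  dim(Y) <- c(outH, outW, ncol(W))
  list(out = Y,
       cache = list(cols = cols, in_dim = d, k = k, stride = stride, pad = pad))
}

conv_bwd <- function(dout, cache, W) {
  dmat <- dout
  dim(dmat) <- c(length(dout) %/% ncol(W), ncol(W))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, W)
  d <- cache$in_dim
  dx <- .col2im(dcols, d[1L], d[2L], d[3L], cache$k, cache$stride, cache$pad)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution doubling the spatial side: zero-stuff every other
# position (stride-2 upsampling) then run an ordinary 3x3 convolution.
upsample_zero <- function(x) {
  d <- dim(x)
  up <- array(0, dim = c(2L * d[1L], 2L * d[2L], d[3L]))
  up[seq(1L, 2L * d[1L], by = 2L), seq(1L, 2L * d[2L], by = 2L), ] <- x
  up
}

convT_fwd <- function(x, W, b, k = 3L) {
  up <- upsample_zero(x)
  cf <- conv_fwd(up, W, b, k = k, stride = 1L)
  cf$cache$orig_dim <- dim(x)
  cf
}

convT_bwd <- function(dout, cache, W) {
  cb <- conv_bwd(dout, cache, W)
  d <- cache$orig_dim
  dx <- cb$dx[seq(1L, 2L * d[1L], by = 2L), seq(1L, 2L * d[2L], by = 2L), ,
              drop = FALSE]
  list(dx = dx, dW = cb$dW, db = cb$db)
}

# ---- nested parameter-list utilities ---------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

assign_params <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1L]]
    p[[path]] <- flat[[key]]
  }
  p
}

zero_like <- function(p) rapply(p, function(x) array(0, dim = dim(x) %||% length(x)),
                                how = "replace")

`%||%` <- function(a, b) if (is.null(a)) b else a
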