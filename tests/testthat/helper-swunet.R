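# shared fixtures and independent oracles, built in code

rand_grid <- function(channels, side, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feature_grid(array(rnorm(channels * side * side), c(channels, side, side)))
}

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_side = 32L, base_width = 4L, encoder_depth = 2L,
         token_dim = 32L, widening_rate = 2L, n_heads = 2L,
         window_side = 4L, shift = 2L, n_classes = 2L), list(...))
  do.call(model_config, args)
}

tiny_phantoms <- function(n = 6L, seed = 1L, n_classes = 2L) {
  make_phantom_set(n, phantom_spec(side = 32L, n_lesions = 1L,
                                   lesion_radius_range = c(3, 6),
                                   n_classes = n_classes, seed = seed))
}

# dense multi-head attention by explicit loops (independent of msa_fwd)
dense_attention_oracle <- function(x, params) {
  n <- nrow(x); nh <- params$n_heads
  hq <- params$d_m / nh; hv <- params$d / nh
  out <- matrix(0, n, params$d)
  for (h in seq_len(nh)) {
    qc <- (h - 1) * hq + seq_len(hq)
    vc <- (h - 1) * hv + seq_len(hv)
    Q <- x %*% params$Wq[, qc]; K <- x %*% params$Wk[, qc]
    V <- x %*% params$Wv[, vc]
    for (i in seq_len(n)) {
      s <- vapply(seq_len(n), function(j) sum(Q[i, ] * K[j, ]), numeric(1)) *
        params$scale + params$B[i, , h]
      a <- exp(s - max(s)); a <- a / sum(a)
      out[i, vc] <- colSums(a * V)
    }
  }
  out
}

# brute-force double-loop directed Hausdorff (percentile 100)
hausdorff_oracle <- function(X, Y) {
  dxy <- max(vapply(seq_len(nrow(X)), function(i)
    min(sqrt((X[i, 1] - Y[, 1])^2 + (X[i, 2] - Y[, 2])^2)), numeric(1)))
  dyx <- max(vapply(seq_len(nrow(Y)), function(i)
    min(sqrt((Y[i, 1] - X[, 1])^2 + (Y[i, 2] - X[, 2])^2)), numeric(1)))
  max(dxy, dyx)
}

dice_oracle <- function(pred, true) {
  p <- pred == 1; t <- true == 1
  if (sum(p) + sum(t) == 0) return(1)
  2 * sum(p & t) / (sum(p) + sum(t))
}

random_mask <- function(side = 16L, p = 0.3) {
  matrix(as.integer(runif(side * side) < p), side, side)
}
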