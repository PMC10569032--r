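trunc_normal <- function(n, sd = 0.02) pmin(pmax(rnorm(n, 0, sd), -2 * sd), 2 * sd)

init_mat <- function(nr, nc, sd = 0.02, zero = FALSE) {
  if (zero) matrix(0, nr, nc) else matrix(trunc_normal(nr * nc, sd), nr, nc)
}

#' Parameters for widened windowed multi-head self-attention
#'
#' The query/key projections are widened to `d_m = E * d` (E the widening
#' rate) while the value projection keeps dimension `d`; this trades depth
#' for width so a single transformer block suffices. A learnable relative
#' position bias `B` (one `M^2 x M^2` table per head) is added to the
#' attention scores inside each window.
#'
#' @param d token/channel dimension.
#' @param widening_rate widening rate `E`; `d_m = E * d`.
#' @param n_heads number of attention heads; must divide both `d` and `d_m`.
#' @param window_side window side `M` (the bias tables are `M^2 x M^2`).
#' @param init `"random"` (truncated-normal weights, zero bias) or `"zero"`.
#' @param seed optional RNG seed for reproducible initialization.
#' @return list of class `"attention_params"` with `Wq`, `Wk` (`d x d_m`),
#'   `Wv` (`d x d`), `B` (`M^2 x M^2 x n_heads`), `n_heads`, `d`, `d_m`,
#'   `window_side` and `scale` (`1/sqrt(d_m / n_heads)`, the per-head scaled
#'   dot-product factor).
#' @export
attention_params <- function(d = 256L, widening_rate = 2L, n_heads = 4L,
                             window_side = 4L, init = c("random", "zero"),
                             seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  d <- as.integer(d); d_m <- as.integer(widening_rate * d)
  if (d %% n_heads != 0L || d_m %% n_heads != 0L)
    stop("n_heads must divide both d and d_m = widening_rate * d")
  M2 <- as.integer(window_side)^2
  zero <- init == "zero"
  structure(list(
    Wq = init_mat(d, d_m, zero = zero),
    Wk = init_mat(d, d_m, zero = zero),
    Wv = init_mat(d, d, zero = zero),
    B = array(0, dim = c(M2, M2, n_heads)),
    n_heads = as.integer(n_heads), d = d, d_m = d_m,
    window_side = as.integer(window_side),
    scale = 1 / sqrt(d_m / n_heads)), class = "attention_params")
}

#' Windowed multi-head self-attention on one window
#'
#' Computes, per head, `Softmax(Q K^T * scale + B + mask) V` over the tokens
#' of one window and concatenates the heads. `Q`/`K` use the widened
#' projections of `params` and `V` keeps dimension `d`, so the output has
#' the same shape as the input. With an additive mask entry of `-1e9`, the
#' post-softmax weight between the corresponding token pair is numerically
#' zero.
#'
#' @param x token matrix (`M^2 x d`, tokens in rows).
#' @param params an [attention_params()].
#' @param mask optional additive `M^2 x M^2` mask with entries in
#'   `{0, -1e9}` (see [build_shift_masks()]).
#' @return the attended token matrix, same shape as `x`.
#' @export
window_attention <- function(x, params, mask = NULL) {
  if (!all(is.finite(x)))
    stop("window_attention: input contains non-finite values")
  if (ncol(x) != params$d)
    stop(sprintf("token dim %d does not match params d = %d", ncol(x), params$d))
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(nrow(x), nrow(x))))
      stop("mask shape does not match token count")
    if (!all(mask %in% c(0, MASK_NEG)))
      stop("mask entries must be 0 or -1e9")
  }
  fw <- msa_fwd(x, params, windows = list(seq_len(nrow(x))),
                masks = if (is.null(mask)) NULL else list(mask),
                n_heads = params$n_heads, scale = params$scale)
  fw$out
}

#' Parameters for the sliding-window transformer block
#'
#' Bundles every learnable array of the block: two layer-norm / widened
#' windowed attention stages (regular and shifted), two feed-forward
#' sublayers (hidden width `4d`, GELU), and the final global self-attention
#' layer that consolidates information across all tokens.
#'
#' @param d token dimension.
#' @param widening_rate widening rate `E` for the windowed stages.
#' @param n_heads heads for every attention stage.
#' @param window_side window side `M`.
#' @param hidden_mult feed-forward hidden width multiplier (hidden = `4d`).
#' @param init `"random"` or `"zero"` (all arrays zero; the block is then
#'   the identity thanks to the residual connections).
#' @param seed optional RNG seed.
#' @return nested list of class `"swtb_params"`.
#' @export
swtb_params <- function(d = 256L, widening_rate = 2L, n_heads = 4L,
                        window_side = 4L, hidden_mult = 4L,
                        init = c("random", "zero"), seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  zero <- init == "zero"
  d <- as.integer(d)
  dh <- as.integer(hidden_mult * d)
  M2 <- as.integer(window_side)^2
  ln <- function() list(g = if (zero) rep(0, d) else rep(1, d), b = rep(0, d))
  att <- function() list(Wq = init_mat(d, widening_rate * d, zero = zero),
                         Wk = init_mat(d, widening_rate * d, zero = zero),
                         Wv = init_mat(d, d, zero = zero),
                         B = array(0, dim = c(M2, M2, n_heads)))
  ffn <- function() list(W1 = init_mat(d, dh, zero = zero), b1 = rep(0, dh),
                         W2 = init_mat(dh, d, zero = zero), b2 = rep(0, d))
  structure(list(
    ln1 = ln(), wmsa = att(), ln2 = ln(), ffn1 = ffn(),
    ln3 = ln(), swmsa = att(), ln4 = ln(), ffn2 = ffn(),
    ln5 = ln(),
    gmsa = list(Wq = init_mat(d, d, zero = zero),
                Wk = init_mat(d, d, zero = zero),
                Wv = init_mat(d, d, zero = zero),
                Wo = init_mat(d, d, zero = zero)),
    d = d, n_heads = as.integer(n_heads),
    widening_rate = as.integer(widening_rate),
    window_side = as.integer(window_side),
    scale_w = 1 / sqrt((widening_rate * d) / n_heads),
    scale_g = 1 / sqrt(d / n_heads)), class = "swtb_params")
}

# window index lists on the cyclically shifted grid, expressed as indices
# into the *unshifted* row-major token order (so no data movement is needed)
shifted_window_index <- function(spec) {
  H <- spec$grid_height; W <- spec$grid_width; s <- spec$shift
  idx <- window_token_index(spec)
  lapply(idx, function(tid) {
    r <- (tid - 1L) %/% W; c <- (tid - 1L) %% W   # 0-based shifted coords
    ((r + s) %% H) * W + ((c + s) %% W) + 1L
  })
}

# Full block forward with optional cache for backprop. X: N x d tokens.
swtb_fwd <- function(X, p, spec, use_sliding_window = TRUE, keep_cache = FALSE) {
  win <- window_token_index(spec)
  if (use_sliding_window && spec$shift > 0L) {
    win_s <- shifted_window_index(spec)
    masks <- build_shift_masks(spec)$per_window_mask
  } else {
    win_s <- win
    masks <- NULL
  }
  cc <- list()
  l1 <- layernorm_fwd(X, p$ln1$g, p$ln1$b)
  a1 <- msa_fwd(l1$out, p$wmsa, win, NULL, p$n_heads, p$scale_w)
  h1 <- X + a1$out                                     # z0'
  l2 <- layernorm_fwd(h1, p$ln2$g, p$ln2$b)
  f1 <- ffn_fwd(l2$out, p$ffn1)
  h2 <- h1 + f1$out                                    # z1
  l3 <- layernorm_fwd(h2, p$ln3$g, p$ln3$b)
  a2 <- msa_fwd(l3$out, p$swmsa, win_s, masks, p$n_heads, p$scale_w)
  h3 <- h2 + a2$out                                    # z1'
  l4 <- layernorm_fwd(h3, p$ln4$g, p$ln4$b)
  f2 <- ffn_fwd(l4$out, p$ffn2)
  h4 <- h3 + f2$out                                    # z2
  l5 <- layernorm_fwd(h4, p$ln5$g, p$ln5$b)
  a3 <- msa_fwd(l5$out, p$gmsa, list(seq_len(nrow(X))), NULL,
                p$n_heads, p$scale_g)
  out <- h4 + a3$out
  if (keep_cache)
    cc <- list(l1 = l1, a1 = a1, l2 = l2, f1 = f1, l3 = l3, a2 = a2,
               l4 = l4, f2 = f2, l5 = l5, a3 = a3)
  list(out = out, cache = cc)
}

swtb_bwd <- function(dout, cache, p) {
  g <- list()
  b3 <- msa_bwd(dout, cache$a3$cache, p$gmsa)
  l5 <- layernorm_bwd(b3$dX, cache$l5$cache)
  g$gmsa <- b3$grads; g$ln5 <- list(g = l5$dg, b = l5$db)
  dh4 <- dout + l5$dX
  b2 <- ffn_bwd(dh4, cache$f2$cache, p$ffn2)
  l4 <- layernorm_bwd(b2$dX, cache$l4$cache)
  g$ffn2 <- b2$grads; g$ln4 <- list(g = l4$dg, b = l4$db)
  dh3 <- dh4 + l4$dX
  a2 <- msa_bwd(dh3, cache$a2$cache, p$swmsa)
  l3 <- layernorm_bwd(a2$dX, cache$l3$cache)
  g$swmsa <- a2$grads; g$ln3 <- list(g = l3$dg, b = l3$db)
  dh2 <- dh3 + l3$dX
  b1 <- ffn_bwd(dh2, cache$f1$cache, p$ffn1)
  l2 <- layernorm_bwd(b1$dX, cache$l2$cache)
  g$ffn1 <- b1$grads; g$ln2 <- list(g = l2$dg, b = l2$db)
  dh1 <- dh2 + l2$dX
  a1 <- msa_bwd(dh1, cache$a1$cache, p$wmsa)
  l1 <- layernorm_bwd(a1$dX, cache$l1$cache)
  g$wmsa <- a1$grads; g$ln1 <- list(g = l1$dg, b = l1$db)
  dX <- dh1 + l1$dX
  list(dX = dX, grads = g)
}

#' Sliding-window transformer block forward pass
#'
#' Applies, with residual connections throughout: layer norm + regular
#' windowed attention; layer norm + feed-forward; layer norm + shifted
#' (cyclic-shift, masked) windowed attention; layer norm + feed-forward;
#' and a final layer norm + global self-attention over all tokens. The
#' output has exactly the shape of the input.
#'
#' @param z0 input token sequence, a `d x N` matrix (see [grid_to_tokens()]).
#' @param params a [swtb_params()].
#' @param spec a [window_spec()] whose grid has `N` tokens.
#' @param use_sliding_window if `FALSE` the second attention stage runs
#'   unshifted and unmasked (the non-sliding ablation arm).
#' @return the output token sequence `z2`, a `d x N` matrix.
#' @export
swtb_forward <- function(z0, params, spec, use_sliding_window = TRUE) {
  N <- ncol(z0)
  if (N != spec$grid_height * spec$grid_width)
    stop(sprintf("sequence length %d does not match %d x %d token grid",
                 N, spec$grid_height, spec$grid_width))
  if (nrow(z0) != params$d)
    stop(sprintf("token dim %d does not match params d = %d", nrow(z0), params$d))
  out <- swtb_fwd(t(z0), params, spec, use_sliding_window)$out
  structure(t(out), grid_height = spec$grid_height,
            grid_width = spec$grid_width, stage_tag = "z2",
            class = c("token_sequence", "matrix"))
}

#' Analytic attention complexity
#'
#' Operation counts of global windowless multi-head self-attention,
#' `4 H W C^2 + 2 H^2 W^2 C`, versus the windowed sliding-window variant,
#' `4 H W C^2 + 2 M^2 H W C`, for an `H x W` feature map with `C` channels
#' and window side `M`. Windowing turns the quadratic dependence on the
#' token count into a linear one.
#'
#' @param H,W,C feature map height, width and channels (positive integers).
#' @param M window side (positive integer).
#' @return list with `cost_w_msa` and `cost_sw_msa` (exact counts).
#' @export
attention_cost <- function(H, W, C, M) {
  for (v in list(H = H, W = W, C = C, M = M))
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v))
      stop("attention_cost: all arguments must be positive integers")
  H <- as.numeric(H); W <- as.numeric(W); C <- as.numeric(C); M <- as.numeric(M)
  list(cost_w_msa = 4 * H * W * C^2 + 2 * H^2 * W^2 * C,
       cost_sw_msa = 4 * H * W * C^2 + 2 * M^2 * H * W * C)
}
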