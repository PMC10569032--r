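#' Model configuration for the hybrid CNN / transformer segmentation network
#'
#' The network encodes a single-channel `input_side x input_side` slice with
#' a small CNN (widths doubling from `base_width` per downsampling level),
#' expands the bottom feature map into a token sequence of dimension
#' `token_dim`, runs one sliding-window transformer block, contracts back to
#' a feature map and decodes with transposed convolutions and skip
#' connections to per-pixel class logits.
#'
#' @param in_channels input channels (CT slices: 1).
#' @param input_side input image side in pixels; must be divisible by
#'   `2^encoder_depth` and the resulting token grid by `window_side`.
#' @param base_width convolution kernels at the first level (doubles per level).
#' @param encoder_depth number of stride-2 downsamplings (1-3; default 2, so a
#'   128 input yields a 32 x 32 token grid).
#' @param token_dim transformer token dimension `d`.
#' @param widening_rate query/key widening rate `E` (`d_m = E d`).
#' @param n_heads attention heads.
#' @param window_side attention window side `M`.
#' @param shift cyclic shift `s` for the shifted stage (default `M/2`).
#' @param n_classes output classes (2 = background/nodule, 3 = adds tumor).
#' @param use_sliding_window if `FALSE`, the shifted attention stage runs
#'   unshifted and unmasked (ablation arm).
#' @return list of class `"model_config"`.
#' @export
model_config <- function(in_channels = 1L, input_side = 128L, base_width = 16L,
                         encoder_depth = 2L, token_dim = 256L,
                         widening_rate = 2L, n_heads = 4L, window_side = 4L,
                         shift = window_side %/% 2L, n_classes = 2L,
                         use_sliding_window = TRUE) {
  encoder_depth <- as.integer(encoder_depth)
  if (encoder_depth < 1L || encoder_depth > 3L)
    stop("encoder_depth must be 1, 2 or 3")
  input_side <- as.integer(input_side)
  if (input_side %% 2L^encoder_depth != 0L)
    stop(sprintf("input_side %d not divisible by 2^%d", input_side, encoder_depth))
  grid_side <- input_side %/% 2L^encoder_depth
  if (grid_side %% as.integer(window_side) != 0L)
    stop(sprintf("token grid side %d not divisible by window side %d",
                 grid_side, window_side))
  if (as.integer(token_dim) %% as.integer(n_heads) != 0L)
    stop("n_heads must divide token_dim")
  cfg <- list(in_channels = as.integer(in_channels), input_side = input_side,
              base_width = as.integer(base_width), encoder_depth = encoder_depth,
              token_dim = as.integer(token_dim),
              widening_rate = as.integer(widening_rate),
              n_heads = as.integer(n_heads), window_side = as.integer(window_side),
              shift = as.integer(shift), n_classes = as.integer(n_classes),
              use_sliding_window = isTRUE(use_sliding_window),
              grid_side = grid_side)
  structure(cfg, class = "model_config")
}

enc_widths <- function(cfg) cfg$base_width * 2L^(0:cfg$encoder_depth)

conv_init <- function(k, cin, cout, zero = FALSE) {
  fan_in <- k * k * cin
  W <- if (zero) matrix(0, fan_in, cout)
       else matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  list(W = W, b = rep(0, cout))
}

swtb_meta <- function(cfg) {
  list(d = cfg$token_dim, n_heads = cfg$n_heads,
       widening_rate = cfg$widening_rate, window_side = cfg$window_side,
       scale_w = 1 / sqrt((cfg$widening_rate * cfg$token_dim) / cfg$n_heads),
       scale_g = 1 / sqrt(cfg$token_dim / cfg$n_heads))
}

swtb_weights_of <- function(p) {
  p[c("ln1", "wmsa", "ln2", "ffn1", "ln3", "swmsa", "ln4", "ffn2",
      "ln5", "gmsa")]
}

init_params <- function(cfg, zero = FALSE) {
  w <- enc_widths(cfg)
  D <- cfg$encoder_depth
  enc <- list(lev0 = list(c1 = conv_init(3L, cfg$in_channels, w[1L], zero),
                          c2 = conv_init(3L, w[1L], w[1L], zero)))
  for (l in seq_len(D)) {
    enc[[paste0("lev", l)]] <- list(
      down = conv_init(3L, w[l], w[l + 1L], zero),
      c1 = conv_init(3L, w[l + 1L], w[l + 1L], zero),
      c2 = conv_init(3L, w[l + 1L], w[l + 1L], zero))
  }
  d <- cfg$token_dim
  sw <- swtb_params(d = d, widening_rate = cfg$widening_rate,
                    n_heads = cfg$n_heads, window_side = cfg$window_side,
                    init = if (zero) "zero" else "random")
  dec <- list()
  for (l in seq(D, 1L)) {
    dec[[paste0("lev", l)]] <- list(
      up = conv_init(3L, w[l + 1L], w[l], zero),
      c1 = conv_init(3L, 2L * w[l], w[l], zero),
      c2 = conv_init(3L, w[l], w[l], zero))
  }
  list(enc = enc,
       expand = conv_init(1L, w[D + 1L], d, zero),
       swtb = swtb_weights_of(sw),
       contract = list(c1 = conv_init(1L, d, w[D + 1L], zero),
                       c2 = conv_init(3L, w[D + 1L], w[D + 1L], zero)),
       dec = dec,
       head = conv_init(1L, w[1L], cfg$n_classes, zero))
}

#' Instantiate a segmentation model
#'
#' @param cfg a [model_config()].
#' @param seed optional RNG seed for reproducible weight initialization.
#' @param init `"random"` (truncated-normal / fan-in-scaled weights) or
#'   `"zero"`.
#' @return list of class `"swunet_model"` with elements `cfg` and `params`.
#' @export
swunet_init <- function(cfg = model_config(), seed = NULL,
                        init = c("random", "zero")) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  structure(list(cfg = cfg, params = init_params(cfg, zero = init == "zero")),
            class = "swunet_model")
}

# ---- internal staged forward/backward --------------------------------------

conv_block_fwd <- function(x, cp, k, stride = 1L, keep = FALSE) {
  cf <- conv_fwd(x, cp$W, cp$b, k = k, stride = stride)
  out <- relu_fwd(cf$out)
  list(out = out, cache = if (keep) list(conv = cf$cache, pre = cf$out) else NULL)
}

conv_block_bwd <- function(dout, cache, cp) {
  dpre <- dout * (cache$pre > 0)
  conv_bwd(dpre, cache$conv, cp$W)
}

enc_fwd <- function(x, P, cfg, keep = FALSE) {
  D <- cfg$encoder_depth
  caches <- list()
  b0a <- conv_block_fwd(x, P$enc$lev0$c1, 3L, keep = keep)
  b0b <- conv_block_fwd(b0a$out, P$enc$lev0$c2, 3L, keep = keep)
  skips <- list(b0b$out)
  caches$lev0 <- list(c1 = b0a$cache, c2 = b0b$cache)
  cur <- b0b$out
  for (l in seq_len(D)) {
    nm <- paste0("lev", l)
    dw <- conv_block_fwd(cur, P$enc[[nm]]$down, 3L, stride = 2L, keep = keep)
    c1 <- conv_block_fwd(dw$out, P$enc[[nm]]$c1, 3L, keep = keep)
    c2 <- conv_block_fwd(c1$out, P$enc[[nm]]$c2, 3L, keep = keep)
    caches[[nm]] <- list(down = dw$cache, c1 = c1$cache, c2 = c2$cache)
    cur <- c2$out
    if (l < D) skips <- c(skips, list(cur))
  }
  list(bottom = cur, skips = skips, cache = caches)
}

enc_bwd <- function(dbottom, dskips, cache, P, cfg) {
  D <- cfg$encoder_depth
  g <- list()
  cur <- dbottom
  for (l in seq(D, 1L)) {
    nm <- paste0("lev", l)
    if (l < D && !is.null(dskips[[l + 1L]])) cur <- cur + dskips[[l + 1L]]
    c2 <- conv_block_bwd(cur, cache[[nm]]$c2, P$enc[[nm]]$c2)
    c1 <- conv_block_bwd(c2$dx, cache[[nm]]$c1, P$enc[[nm]]$c1)
    dw <- conv_block_bwd(c1$dx, cache[[nm]]$down, P$enc[[nm]]$down)
    g[[nm]] <- list(down = list(W = dw$dW, b = dw$db),
                    c1 = list(W = c1$dW, b = c1$db),
                    c2 = list(W = c2$dW, b = c2$db))
    cur <- dw$dx
  }
  cur <- cur + dskips[[1L]]
  c2 <- conv_block_bwd(cur, cache$lev0$c2, P$enc$lev0$c2)
  c1 <- conv_block_bwd(c2$dx, cache$lev0$c1, P$enc$lev0$c1)
  g$lev0 <- list(c1 = list(W = c1$dW, b = c1$db),
                 c2 = list(W = c2$dW, b = c2$db))
  list(dx = c1$dx, grads = g)
}

# row-major token order <-> column-major storage permutation for an h x w grid
rowmajor_perm <- function(h, w) {
  t <- seq_len(h * w) - 1L
  (t %% w) * h + (t %/% w) + 1L            # cm position of row-major token t
}

expand_fwd <- function(bottom, P, cfg, keep = FALSE) {
  cf <- conv_fwd(bottom, P$expand$W, P$expand$b, k = 1L, pad = 0L)
  h <- dim(bottom)[1L]; w <- dim(bottom)[2L]
  perm <- rowmajor_perm(h, w)
  Xcm <- matrix(cf$out, nrow = h * w)
  X <- Xcm[perm, , drop = FALSE]
  list(out = X, cache = if (keep) list(conv = cf$cache, perm = perm,
                                       h = h, w = w) else list(perm = perm, h = h, w = w))
}

expand_bwd <- function(dX, cache, P) {
  dcm <- matrix(0, nrow(dX), ncol(dX))
  dcm[cache$perm, ] <- dX
  dout <- array(dcm, dim = c(cache$h, cache$w, ncol(dX)))
  cb <- conv_bwd(dout, cache$conv, P$expand$W)
  list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
}

contract_fwd <- function(X2, P, cfg, h, w, keep = FALSE) {
  perm <- rowmajor_perm(h, w)
  Xcm <- matrix(0, nrow(X2), ncol(X2))
  Xcm[perm, ] <- X2
  grid <- array(Xcm, dim = c(h, w, ncol(X2)))
  c1 <- conv_block_fwd(grid, P$contract$c1, 1L, keep = keep)
  c2 <- conv_block_fwd(c1$out, P$contract$c2, 3L, keep = keep)
  list(out = c2$out,
       cache = if (keep) list(c1 = c1$cache, c2 = c2$cache, perm = perm) else NULL)
}

contract_bwd <- function(dout, cache, P) {
  c2 <- conv_block_bwd(dout, cache$c2, P$contract$c2)
  c1 <- conv_block_bwd(c2$dx, cache$c1, P$contract$c1)
  dgrid <- matrix(c1$dx, nrow = prod(dim(c1$dx)[1:2]))
  dX2 <- dgrid[cache$perm, , drop = FALSE]
  list(dX = dX2, grads = list(c1 = list(W = c1$dW, b = c1$db),
                              c2 = list(W = c2$dW, b = c2$db)))
}

dec_fwd <- function(bottle, skips, P, cfg, keep = FALSE) {
  D <- cfg$encoder_depth
  caches <- list()
  cur <- bottle
  for (l in seq(D, 1L)) {
    nm <- paste0("lev", l)
    up <- convT_fwd(cur, P$dec[[nm]]$up$W, P$dec[[nm]]$up$b)
    upre <- relu_fwd(up$out)
    skip <- skips[[l]]
    cat_in <- array(c(upre, skip), dim = c(dim(upre)[1:2],
                                           dim(upre)[3L] + dim(skip)[3L]))
    c1 <- conv_block_fwd(cat_in, P$dec[[nm]]$c1, 3L, keep = keep)
    c2 <- conv_block_fwd(c1$out, P$dec[[nm]]$c2, 3L, keep = keep)
    caches[[nm]] <- if (keep) list(up = up$cache, up_pre = up$out,
                                   nup = dim(upre)[3L],
                                   c1 = c1$cache, c2 = c2$cache) else NULL
    cur <- c2$out
  }
  hd <- conv_fwd(cur, P$head$W, P$head$b, k = 1L, pad = 0L)
  caches$head <- if (keep) hd$cache else NULL
  list(out = hd$out, cache = caches)
}

dec_bwd <- function(dlogits, cache, P, cfg) {
  D <- cfg$encoder_depth
  g <- list()
  hb <- conv_bwd(dlogits, cache$head, P$head$W)
  g$head <- list(W = hb$dW, b = hb$db)
  cur <- hb$dx
  dskips <- vector("list", D)
  for (l in seq_len(D)) {
    nm <- paste0("lev", l)
    cc <- cache[[nm]]
    c2 <- conv_block_bwd(cur, cc$c2, P$dec[[nm]]$c2)
    c1 <- conv_block_bwd(c2$dx, cc$c1, P$dec[[nm]]$c1)
    nup <- cc$nup
    dup_post <- c1$dx[, , seq_len(nup), drop = FALSE]
    dskips[[l]] <- c1$dx[, , nup + seq_len(dim(c1$dx)[3L] - nup), drop = FALSE]
    dup <- dup_post * (cc$up_pre > 0)
    ub <- convT_bwd(dup, cc$up, P$dec[[nm]]$up$W)
    g[[nm]] <- list(up = list(W = ub$dW, b = ub$db),
                    c1 = list(W = c1$dW, b = c1$db),
                    c2 = list(W = c2$dW, b = c2$db))
    cur <- ub$dx
  }
  list(dbottle = cur, dskips = dskips, grads = g)
}

net_fwd <- function(P, cfg, x, keep = FALSE) {
  en <- enc_fwd(x, P, cfg, keep = keep)
  ex <- expand_fwd(en$bottom, P, cfg, keep = keep)
  spec <- window_spec(cfg$window_side, cfg$shift, cfg$grid_side, cfg$grid_side)
  sw_p <- c(P$swtb, swtb_meta(cfg))
  sw <- swtb_fwd(ex$out, sw_p, spec, cfg$use_sliding_window, keep_cache = keep)
  ct <- contract_fwd(sw$out, P, cfg, cfg$grid_side, cfg$grid_side, keep = keep)
  de <- dec_fwd(ct$out, en$skips, P, cfg, keep = keep)
  list(logits = de$out,
       cache = if (keep) list(en = en, ex = ex, sw = sw, ct = ct, de = de,
                              spec = spec) else NULL)
}

net_bwd <- function(dlogits, cache, P, cfg) {
  de <- dec_bwd(dlogits, cache$de$cache, P, cfg)
  ct <- contract_bwd(de$dbottle, cache$ct$cache, P)
  sw_p <- c(P$swtb, swtb_meta(cfg))
  sw <- swtb_bwd(ct$dX, cache$sw$cache, sw_p)
  ex <- expand_bwd(sw$dX, cache$ex$cache, P)
  en <- enc_bwd(ex$dx, de$dskips, cache$en$cache, P, cfg)
  dec_g <- de$grads
  head_g <- dec_g$head
  dec_g$head <- NULL
  list(grads = list(enc = en$grads, expand = ex$grads, swtb = sw$grads,
                    contract = ct$grads, dec = dec_g, head = head_g))
}

# ---- public staged API ------------------------------------------------------

as_hwc_image <- function(image, cfg) {
  if (inherits(image, "feature_grid")) image <- grid_to_hwc(image)
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (d[1L] != cfg$input_side || d[2L] != cfg$input_side ||
      d[3L] != cfg$in_channels)
    stop(sprintf("input is %d x %d x %d but config expects %d x %d x %d",
                 d[1L], d[2L], d[3L], cfg$input_side, cfg$input_side,
                 cfg$in_channels))
  image
}

#' CNN encoder: image to bottom feature map plus skip stack
#'
#' Two 3x3 convolutions per level with stride-2 convolutional downsampling
#' between levels; channel width doubles per level. Level `l` of the skip
#' stack has side `input_side / 2^l` and `base_width * 2^l` channels.
#'
#' @param model a [swunet_init()] model.
#' @param image `input_side x input_side` matrix (or single-channel
#'   [feature_grid()]).
#' @return list with `bottom` (a [feature_grid()]) and `skips` (list of
#'   feature grids, shallowest first).
#' @export
encode <- function(model, image) {
  x <- as_hwc_image(image, model$cfg)
  en <- enc_fwd(x, model$params, model$cfg)
  list(bottom = hwc_to_grid(en$bottom), skips = lapply(en$skips, hwc_to_grid))
}

#' Expand the encoder bottom into a transformer token sequence
#'
#' A 1x1 convolution widens the channel count to `token_dim` and the two
#' spatial dims are merged (row-major) into the sequence axis.
#'
#' @param model a [swunet_init()] model.
#' @param bottom the bottom [feature_grid()] from [encode()].
#' @return a `token_dim x N` token sequence (stage `z0`).
#' @export
expand_features <- function(model, bottom) {
  gd <- grid_dims(bottom)
  expected <- enc_widths(model$cfg)[model$cfg$encoder_depth + 1L]
  if (gd$channels != expected)
    stop(sprintf("bottom has %d channels, expected %d", gd$channels, expected))
  ex <- expand_fwd(grid_to_hwc(bottom), model$params, model$cfg)
  structure(t(ex$out), grid_height = gd$height, grid_width = gd$width,
            stage_tag = "z0", class = c("token_sequence", "matrix"))
}

#' Contract a token sequence back to a decoder-ready feature map
#'
#' The sequence is reshaped onto its spatial grid and two convolutions
#' reduce the channel count to the encoder-bottom width, restoring the
#' feature-map shape the decoder expects.
#'
#' @param model a [swunet_init()] model.
#' @param z2 output token sequence of [swtb_forward()] (`d x N`); `N` must be
#'   a perfect square if the grid dims are not stored on the sequence.
#' @return a [feature_grid()] with the encoder-bottom shape.
#' @export
contract_features <- function(model, z2) {
  N <- ncol(z2)
  h <- attr(z2, "grid_height"); w <- attr(z2, "grid_width")
  if (is.null(h) || is.null(w)) {
    side <- sqrt(N)
    if (side != floor(side))
      stop(sprintf("token count %d is not a perfect square", N))
    h <- w <- as.integer(side)
  }
  ct <- contract_fwd(t(unclass(z2)), model$params, model$cfg, h, w)
  hwc_to_grid(ct$out)
}

#' CNN decoder: bottleneck plus skips to per-pixel class logits
#'
#' Each level applies a stride-2 transposed 3x3 convolution (doubling the
#' spatial side), concatenates the matching encoder skip features, and
#' refines with two 3x3 convolutions; a final 1x1 convolution maps to
#' `n_classes` logits at full input resolution.
#'
#' @param model a [swunet_init()] model.
#' @param bottleneck [feature_grid()] from [contract_features()].
#' @param skips skip stack from [encode()].
#' @return logits [feature_grid()] of dim `(n_classes, input_side, input_side)`.
#' @export
decode <- function(model, bottleneck, skips) {
  D <- model$cfg$encoder_depth
  if (length(skips) != D)
    stop(sprintf("expected %d skip levels, got %d", D, length(skips)))
  de <- dec_fwd(grid_to_hwc(bottleneck), lapply(skips, grid_to_hwc),
                model$params, model$cfg)
  hwc_to_grid(de$out)
}

#' Full forward pass
#'
#' Composes encode, feature expansion, the sliding-window transformer block,
#' feature contraction and decode. Deterministic for fixed weights.
#'
#' @param model a [swunet_init()] model.
#' @param x one `input_side x input_side` matrix, or a list of them (a batch).
#' @return logits [feature_grid()] (`n_classes x side x side`), or a list of
#'   them for a batch.
#' @export
swunet_forward <- function(model, x) {
  if (is.list(x)) return(lapply(x, function(xi) swunet_forward(model, xi)))
  xi <- as_hwc_image(x, model$cfg)
  fw <- net_fwd(model$params, model$cfg, xi)
  hwc_to_grid(fw$logits)
}

#' Count trainable parameters
#'
#' @param cfg a [model_config()].
#' @return total number of trainable scalars (exact integer).
#' @export
count_parameters <- function(cfg = model_config()) {
  flat <- flatten_params(init_params(cfg, zero = TRUE))
  sum(vapply(flat, length, numeric(1)))
}

#' Analytic multiply-accumulate count for one forward pass
#'
#' Per-stage MAC counts (1 MAC = 1 FLOP unit): convolutions as
#' `outH*outW*k^2*Cin*Cout`, the attention stages by delegation to
#' [attention_cost()] evaluated on the token grid, and the feed-forward
#' sublayers as affine-map products.
#'
#' @param cfg a [model_config()].
#' @return list with `stages` (named numeric vector), `total`, and
#'   `attention_cost` (the verbatim [attention_cost()] output for the token
#'   grid).
#' @export
estimate_flops <- function(cfg = model_config()) {
  w <- enc_widths(cfg); D <- cfg$encoder_depth
  side <- cfg$input_side
  cmac <- function(out_side, k, cin, cout) out_side^2 * k^2 * cin * cout
  enc <- cmac(side, 3, cfg$in_channels, w[1]) + cmac(side, 3, w[1], w[1])
  s <- side
  for (l in seq_len(D)) {
    s <- s / 2
    enc <- enc + cmac(s, 3, w[l], w[l + 1]) + 2 * cmac(s, 3, w[l + 1], w[l + 1])
  }
  gs <- cfg$grid_side; d <- cfg$token_dim
  ac <- attention_cost(gs, gs, d, cfg$window_side)
  N <- gs^2
  expand <- N * w[D + 1] * d
  ffn <- 2 * (N * d * 4 * d * 2)
  contract <- N * d * w[D + 1] + cmac(gs, 3, w[D + 1], w[D + 1])
  dec <- 0
  s <- gs
  for (l in seq(D, 1)) {
    s <- s * 2
    dec <- dec + cmac(s, 3, w[l + 1], w[l]) + cmac(s, 3, 2 * w[l], w[l]) +
      cmac(s, 3, w[l], w[l])
  }
  head <- side^2 * w[1] * cfg$n_classes
  stages <- c(encoder = enc, expand = expand,
              attention_windowed = ac$cost_sw_msa,
              attention_windowed_shifted = ac$cost_sw_msa,
              ffn = ffn, attention_global = ac$cost_w_msa,
              contract = contract, decoder = dec, head = head)
  list(stages = stages, total = sum(stages), attention_cost = ac)
}
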