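test_that("window attention matches a dense double-loop oracle", {
  set.seed(10)
  for (trial in 1:3) {
    ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                           window_side = 4)
    x <- matrix(rnorm(16 * 8), 16, 8)
    expect_lt(max(abs(window_attention(x, ap) - dense_attention_oracle(x, ap))),
              1e-5)
  }
})

test_that("relative position bias enters the attention scores", {
  set.seed(11)
  ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                         window_side = 4)
  x <- matrix(rnorm(16 * 8), 16, 8)
  base <- window_attention(x, ap)
  ap$B[, , 1] <- matrix(rnorm(256), 16, 16)
  expect_gt(max(abs(window_attention(x, ap) - base)), 1e-8)
  expect_lt(max(abs(window_attention(x, ap) - dense_attention_oracle(x, ap))),
            1e-5)
})

test_that("zero value projection zeroes the output regardless of Q and K", {
  set.seed(12)
  ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                         window_side = 4)
  ap$Wv[] <- 0
  x <- matrix(rnorm(16 * 8), 16, 8)
  expect_true(all(window_attention(x, ap) == 0))
})

test_that("masked token pairs receive numerically zero attention weight", {
  set.seed(13)
  ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                         window_side = 4)
  mask <- matrix(0, 16, 16)
  blocked <- c(13:16)
  mask[blocked, -blocked] <- -1e9
  mask[-blocked, blocked] <- -1e9
  x <- matrix(rnorm(16 * 8), 16, 8)
  base <- window_attention(x, ap, mask)
  # perturb a blocked token: outputs of tokens masked from it must not move
  x2 <- x; x2[1, ] <- x2[1, ] + 10
  pert <- window_attention(x2, ap, mask)
  expect_lt(max(abs(pert[blocked, ] - base[blocked, ])), 1e-6)
  expect_gt(max(abs(pert[-blocked, ] - base[-blocked, ])), 1e-6)
})

test_that("attention softmax rows sum to one, with and without masks", {
  set.seed(14)
  sp <- window_spec(4, 2, 8, 8)
  masks <- build_shift_masks(sp)$per_window_mask
  X <- matrix(rnorm(64 * 8), 64, 8)
  ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                         window_side = 4)
  for (msk in list(NULL, masks[[4]])) {
    fw <- swunet:::msa_fwd(X[1:16, ], ap, list(1:16),
                           if (is.null(msk)) NULL else list(msk),
                           n_heads = 2, scale = ap$scale)
    for (h in 1:2) {
      A <- fw$cache$A_list[[1]][, , h]
      expect_true(all(abs(rowSums(A) - 1) < 1e-6))
    }
  }
})

test_that("window attention validates inputs", {
  ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                         window_side = 4)
  x <- matrix(rnorm(16 * 8), 16, 8)
  xb <- x; xb[3, 3] <- NaN
  expect_error(window_attention(xb, ap), "non-finite")
  badmask <- matrix(1, 16, 16)
  expect_error(window_attention(x, ap, badmask), "0 or -1e9")
})

test_that("no attention leakage across masked entries in the shifted stage", {
  set.seed(15)
  sp <- window_spec(4, 2, 8, 8)
  win_s <- swunet:::shifted_window_index(sp)
  masks <- build_shift_masks(sp)$per_window_mask
  ap <- attention_params(d = 8, widening_rate = 2, n_heads = 2,
                         window_side = 4)
  X <- matrix(rnorm(64 * 8), 64, 8)
  base <- swunet:::msa_fwd(X, ap, win_s, masks, 2, ap$scale)$out
  # perturb each of a few tokens; only tokens sharing an unmasked pair in
  # the same shifted window may change
  for (tok in c(1L, 7L, 23L, 64L)) {
    X2 <- X; X2[tok, ] <- X2[tok, ] + 5
    pert <- swunet:::msa_fwd(X2, ap, win_s, masks, 2, ap$scale)$out
    moved <- which(rowSums(abs(pert - base)) > 1e-6)
    allowed <- integer(0)
    for (w in seq_along(win_s)) {
      pos <- match(tok, win_s[[w]])
      if (!is.na(pos)) {
        vis <- which(masks[[w]][, pos] == 0)
        allowed <- c(allowed, win_s[[w]][vis])
      }
    }
    expect_true(all(moved %in% allowed))
  }
})

test_that("transformer block with zero weights is the identity", {
  set.seed(16)
  p0 <- swtb_params(d = 8, widening_rate = 2, n_heads = 2, window_side = 4,
                    init = "zero")
  z0 <- matrix(rnorm(8 * 64), 8, 64)
  sp <- window_spec(4, 2, 8, 8)
  expect_identical(max(abs(swtb_forward(z0, p0, sp) - z0)), 0)
})

test_that("transformer block preserves the d x N shape at full size", {
  set.seed(17)
  p <- swtb_params(d = 256, widening_rate = 2, n_heads = 4, window_side = 4)
  z0 <- matrix(rnorm(256 * 1024, 0, 0.1), 256, 1024)
  sp <- window_spec(4, 2, 32, 32)
  z2 <- swtb_forward(z0, p, sp)
  expect_equal(dim(z2), c(256, 1024))
  expect_true(all(is.finite(z2)))
})

test_that("transformer block equals the staged composition of its sublayers", {
  set.seed(18)
  p <- swtb_params(d = 8, widening_rate = 2, n_heads = 2, window_side = 4)
  sp <- window_spec(4, 2, 8, 8)
  z0 <- matrix(rnorm(8 * 64), 8, 64)
  z2 <- swtb_forward(z0, p, sp)

  ln <- function(X, l) swunet:::layernorm_fwd(X, l$g, l$b)$out
  win <- swunet:::window_token_index(sp)
  win_s <- swunet:::shifted_window_index(sp)
  masks <- build_shift_masks(sp)$per_window_mask
  X <- t(z0)
  h1 <- X + swunet:::msa_fwd(ln(X, p$ln1), p$wmsa, win, NULL, 2, p$scale_w)$out
  h2 <- h1 + swunet:::ffn_fwd(ln(h1, p$ln2), p$ffn1)$out
  h3 <- h2 + swunet:::msa_fwd(ln(h2, p$ln3), p$swmsa, win_s, masks, 2,
                              p$scale_w)$out
  h4 <- h3 + swunet:::ffn_fwd(ln(h3, p$ln4), p$ffn2)$out
  h5 <- h4 + swunet:::msa_fwd(ln(h4, p$ln5), p$gmsa, list(1:64), NULL, 2,
                              p$scale_g)$out
  expect_lt(max(abs(z2 - t(h5))), 1e-12)
})

test_that("block rejects mismatched sequence lengths", {
  p <- swtb_params(d = 8, widening_rate = 2, n_heads = 2, window_side = 4,
                   init = "zero")
  sp <- window_spec(4, 2, 8, 8)
  expect_error(swtb_forward(matrix(0, 8, 60), p, sp), "token grid")
})

test_that("analytic attention costs evaluate the closed forms exactly", {
  ac <- attention_cost(32, 32, 256, 4)
  expect_identical(ac$cost_w_msa, 805306368)
  expect_identical(ac$cost_sw_msa, 276824064)
  # windowless and windowed coincide when one window covers the whole map
  ac2 <- attention_cost(4, 4, 16, 4)
  expect_identical(ac2$cost_w_msa, ac2$cost_sw_msa)
  # linear-vs-quadratic ordering and growth in channels
  ac3 <- attention_cost(16, 16, 32, 4)
  expect_lt(ac3$cost_sw_msa, ac3$cost_w_msa)
  ac4 <- attention_cost(16, 16, 64, 4)
  expect_gt(ac4$cost_w_msa, ac3$cost_w_msa)
  expect_gt(ac4$cost_sw_msa, ac3$cost_sw_msa)
  expect_error(attention_cost(0, 32, 256, 4), "positive")
})
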