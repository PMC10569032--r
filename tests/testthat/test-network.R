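test_that("encoder produces the documented bottom shape and skip stack", {
  model <- swunet_init(model_config(), seed = 1)
  img <- matrix(runif(128 * 128), 128, 128)
  en <- encode(model, img)
  expect_equal(dim(en$bottom), c(64, 32, 32))
  expect_length(en$skips, 2)
  expect_equal(dim(en$skips[[1]]), c(16, 128, 128))
  expect_equal(dim(en$skips[[2]]), c(32, 64, 64))
  expect_error(encode(model, matrix(0, 127, 127)), "127")

  m64 <- swunet_init(model_config(input_side = 64L), seed = 1)
  expect_equal(dim(encode(m64, matrix(runif(64 * 64), 64, 64))$bottom),
               c(64, 16, 16))
})

test_that("feature expansion and contraction preserve the spatial layout", {
  model <- swunet_init(model_config(), seed = 2)
  en <- encode(model, matrix(runif(128 * 128), 128, 128))
  z0 <- expand_features(model, en$bottom)
  expect_equal(dim(z0), c(256, 1024))
  expect_identical(attr(z0, "stage_tag"), "z0")
  back <- contract_features(model, z0)
  expect_equal(dim(back), c(64, 32, 32))
  # token order is row-major and invertible: token t carries the channel
  # vector of pixel (r, c) of the expanded map
  ex <- swunet:::expand_fwd(swunet:::grid_to_hwc(en$bottom), model$params,
                            model$cfg)
  tok_rm <- t(unclass(z0))
  expect_equal(tok_rm, ex$out, ignore_attr = TRUE)

  bad <- matrix(0, 256, 1023)
  expect_error(contract_features(model, bad), "perfect square")
  expect_error(expand_features(model, rand_grid(32, 32)), "channels")
})

test_that("shape chain closes for every encoder depth and class count", {
  for (D in 1:3) {
    for (K in c(2L, 3L)) {
      cfg <- model_config(input_side = 32L, base_width = 2L,
                          encoder_depth = D, token_dim = 16L,
                          widening_rate = 2L, n_heads = 2L, window_side = 4L,
                          n_classes = K)
      m <- swunet_init(cfg, seed = 3)
      lg <- swunet_forward(m, matrix(runif(32 * 32), 32, 32))
      expect_equal(dim(lg), c(K, 32, 32))
      expect_true(all(is.finite(lg)))
    }
  }
})

test_that("forward pass is deterministic and batches element-wise", {
  cfg <- tiny_cfg()
  m <- swunet_init(cfg, seed = 4)
  x1 <- matrix(runif(32 * 32), 32, 32)
  x2 <- matrix(runif(32 * 32), 32, 32)
  out <- swunet_forward(m, list(x1, x2))
  expect_length(out, 2)
  expect_identical(unclass(out[[1]]), unclass(swunet_forward(m, x1)))
  expect_identical(unclass(swunet_forward(m, x1)),
                   unclass(swunet_forward(m, x1)))
})

test_that("disabling the sliding window changes the computation", {
  set.seed(5)
  x <- matrix(runif(32 * 32), 32, 32)
  m_sw <- swunet_init(tiny_cfg(use_sliding_window = TRUE), seed = 6)
  m_no <- swunet_init(tiny_cfg(use_sliding_window = FALSE), seed = 6)
  # identical weights, different attention wiring
  expect_identical(swunet:::flatten_params(m_sw$params),
                   swunet:::flatten_params(m_no$params))
  expect_gt(max(abs(swunet_forward(m_sw, x) - swunet_forward(m_no, x))), 1e-8)
})

test_that("every trainable array receives gradient after one step", {
  cfg <- model_config(input_side = 16L, base_width = 2L, encoder_depth = 2L,
                      token_dim = 8L, widening_rate = 2L, n_heads = 2L,
                      window_side = 4L, n_classes = 2L)
  m <- swunet_init(cfg, seed = 7)
  sl <- make_nodule_phantom(phantom_spec(side = 16L, n_lesions = 1L,
                                         lesion_radius_range = c(2, 3),
                                         seed = 8))
  st <- swunet:::step_one(m$params, cfg, sl, loss_config())
  dead <- names(st$grads)[vapply(st$grads, function(g) all(g == 0), logical(1))]
  expect_identical(dead, character(0))
})

test_that("backpropagation matches central finite differences", {
  set.seed(9)
  cfg <- model_config(input_side = 16L, base_width = 2L, encoder_depth = 2L,
                      token_dim = 8L, widening_rate = 2L, n_heads = 2L,
                      window_side = 4L, n_classes = 2L)
  m <- swunet_init(cfg, seed = 10)
  # jitter all parameters (including zero-initialized biases) so no ReLU
  # pre-activation sits exactly on its kink
  pf <- swunet:::flatten_params(m$params)
  for (k in names(pf)) pf[[k]] <- pf[[k]] + rnorm(length(pf[[k]]), 0, 0.05)
  m$params <- swunet:::assign_params(m$params, pf)
  x <- array(runif(16 * 16), c(16, 16, 1))
  R <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  lossfn <- function(P) sum(swunet:::net_fwd(P, cfg, x)$logits * R)
  fw <- swunet:::net_fwd(m$params, cfg, x, keep = TRUE)
  bw <- swunet:::net_bwd(R, fw$cache, m$params, cfg)
  gf <- swunet:::flatten_params(bw$grads)
  expect_setequal(names(gf), names(pf))
  eps <- 1e-5
  for (k in sample(names(pf), 20)) {
    i <- sample(length(pf[[k]]), 1)
    p2 <- pf; p2[[k]][i] <- p2[[k]][i] + eps
    lp <- lossfn(swunet:::assign_params(m$params, p2))
    p2[[k]][i] <- p2[[k]][i] - 2 * eps
    lm <- lossfn(swunet:::assign_params(m$params, p2))
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gf[[k]][i]) / max(1e-4, abs(num) + abs(gf[[k]][i])),
              1e-4)
  }
})

test_that("parameter count respects the lightweight budget and grows with d", {
  expect_lte(count_parameters(model_config()), 32e6)
  expect_gt(count_parameters(model_config(token_dim = 256L)),
            count_parameters(model_config(token_dim = 128L)))
  # closed form for one affine map: d_in * d_out + d_out. Adding one output
  # class adds exactly one 1x1 kernel (base_width weights) plus one bias.
  expect_identical(count_parameters(tiny_cfg(n_classes = 3L)) -
                     count_parameters(tiny_cfg(n_classes = 2L)),
                   4 + 1)
})

test_that("flop accounting delegates attention stages and scales sensibly", {
  cfg <- model_config()
  fl <- estimate_flops(cfg)
  ac <- attention_cost(cfg$grid_side, cfg$grid_side, cfg$token_dim,
                       cfg$window_side)
  expect_identical(unname(fl$stages["attention_windowed"]), ac$cost_sw_msa)
  expect_identical(unname(fl$stages["attention_windowed_shifted"]),
                   ac$cost_sw_msa)
  expect_identical(unname(fl$stages["attention_global"]), ac$cost_w_msa)
  expect_identical(fl$total, sum(fl$stages))
  expect_gt(estimate_flops(model_config(input_side = 128L))$total,
            estimate_flops(model_config(input_side = 64L))$total)
  # convolution cost is quadratic in width: doubling more than doubles it
  e16 <- estimate_flops(model_config(base_width = 16L))$stages["encoder"]
  e32 <- estimate_flops(model_config(base_width = 32L))$stages["encoder"]
  expect_gt(unname(e32), 2 * unname(e16))
})
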