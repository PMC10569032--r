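#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-5, the full-scale
#'   setting; desk-scale overfitting runs use a larger rate).
#' @param batch_size images per optimizer step (default 48); automatically
#'   shrunk, with a message, when the training set is smaller.
#' @param max_epochs maximum epochs (default 100).
#' @param patience early-stopping patience on the monitored loss.
#' @param loss a [loss_config()].
#' @param seed RNG seed covering initialization, shuffling and batching.
#' @param device descriptor string (informational; all computation is CPU).
#' @param stop_train_dice optional early-exit threshold: stop once the
#'   epoch-mean training Dice exceeds it and a confirming forward pass over
#'   the training set agrees (used by desk-scale overfitting runs; `NULL`
#'   disables).
#' @param lr_decay multiplicative per-epoch learning-rate decay factor
#'   (default 1 = constant rate).
#' @return list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 48L,
                         max_epochs = 100L, patience = 15L,
                         loss = loss_config(), seed = 1L, device = "cpu",
                         stop_train_dice = NULL, lr_decay = 1) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), loss = loss,
                 seed = as.integer(seed), device = device,
                 stop_train_dice = stop_train_dice, lr_decay = lr_decay),
            class = "train_config")
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(state, flat, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, flat = flat)
}

flat_add <- function(a, b) { for (k in names(b)) a[[k]] <- (a[[k]] %||% 0) + b[[k]]; a }
flat_scale <- function(a, s) { for (k in names(a)) a[[k]] <- a[[k]] * s; a }

resolve_data <- function(data) {
  if (is.character(data)) load_dataset(data) else data
}

slice_dice <- function(probs, mask, n_classes) {
  pred <- argmax_classes(probs)
  mean(vapply(seq_len(n_classes - 1L), function(cl)
    dice_coefficient(confusion(pred, mask, cl)), numeric(1)))
}

# forward + loss/grad for one labeled slice
step_one <- function(P, cfg, sl, loss_cfg, want_grad = TRUE) {
  x <- array(sl$image, dim = c(dim(sl$image), 1L))
  fw <- net_fwd(P, cfg, x, keep = want_grad)
  lg <- seg_loss_grad(fw$logits, sl$mask, loss_cfg)
  out <- list(loss = lg$loss, probs = lg$probs,
              dice = slice_dice(lg$probs, sl$mask, cfg$n_classes))
  if (want_grad) {
    bw <- net_bwd(lg$dlogits, fw$cache, P, cfg)
    out$grads <- flatten_params(bw$grads)
  }
  out
}

#' Train the segmentation network
#'
#' Adam optimization of the compound Dice + Focal loss with seeded
#' shuffling, optional validation-based early stopping and best-checkpoint
#' selection. Only items of the training partition ever contribute
#' gradients; the batch ids drawn at every step are logged so this can be
#' audited.
#'
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param data a manifest path (see [make_dataset()]) or a named list of
#'   [labeled_slice()] objects.
#' @param split a [split_dataset()] plan, `NULL` to derive one (seeded from
#'   `train_cfg$seed`), or `"none"` to train on everything with no
#'   validation (monitoring then falls back to the training loss).
#' @param out_dir optional run directory for the checkpoint, the per-epoch
#'   CSV log and a JSON run summary.
#' @return list of class `"swunet_fit"`: `model` (best checkpoint),
#'   `final_model`, `log` (per-epoch data frame), `split`, `batch_ids`,
#'   `final_train_loss`, `final_train_dice`, `checkpoint` (path or `NULL`).
#' @export
train_swunet <- function(model_cfg, train_cfg = train_config(), data,
                         split = NULL, out_dir = NULL) {
  slices <- resolve_data(data)
  ids <- names(slices) %||% as.character(seq_along(slices))
  names(slices) <- ids
  if (identical(split, "none")) {
    split <- list(train_ids = ids, val_ids = character(0),
                  test_ids = character(0), seed = train_cfg$seed)
  } else if (is.null(split)) {
    split <- split_dataset(ids, seed = train_cfg$seed)
  }
  if (length(split$train_ids) == 0L) stop("empty training split")
  n_train <- length(split$train_ids)
  batch_size <- train_cfg$batch_size
  if (batch_size > n_train) {
    message(sprintf("batch_size %d exceeds training-set size %d; shrinking",
                    batch_size, n_train))
    batch_size <- n_train
  }
  set.seed(train_cfg$seed)
  model <- swunet_init(model_cfg)
  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  wait <- 0L
  log_rows <- list()
  batch_log <- list()
  for (epoch in seq_len(train_cfg$max_epochs)) {
    order_ids <- sample(split$train_ids)
    ep_loss <- c(); ep_dice <- c()
    for (b0 in seq(1L, n_train, by = batch_size)) {
      bids <- order_ids[b0:min(b0 + batch_size - 1L, n_train)]
      batch_log[[length(batch_log) + 1L]] <- bids
      P <- assign_params(model$params, flat)
      gsum <- NULL; lsum <- 0; dsum <- 0
      for (id in bids) {
        st <- step_one(P, model_cfg, slices[[id]], train_cfg$loss)
        gsum <- if (is.null(gsum)) st$grads else flat_add(gsum, st$grads)
        lsum <- lsum + st$loss; dsum <- dsum + st$dice
      }
      nb <- length(bids)
      if (!is.finite(lsum))
        stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
      upd <- adam_step(opt, flat, flat_scale(gsum, 1 / nb),
                       train_cfg$learning_rate *
                         (train_cfg$lr_decay %||% 1)^(epoch - 1L))
      opt <- upd$state; flat <- upd$flat
      ep_loss <- c(ep_loss, lsum / nb); ep_dice <- c(ep_dice, dsum / nb)
    }
    val_loss <- NA_real_; val_dice <- NA_real_
    if (length(split$val_ids) > 0L) {
      P <- assign_params(model$params, flat)
      vl <- vapply(split$val_ids, function(id) {
        st <- step_one(P, model_cfg, slices[[id]], train_cfg$loss,
                       want_grad = FALSE)
        c(st$loss, st$dice)
      }, numeric(2))
      val_loss <- mean(vl[1L, ]); val_dice <- mean(vl[2L, ])
    }
    monitored <- if (is.na(val_loss)) mean(ep_loss) else val_loss
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(ep_loss), train_dice = mean(ep_dice),
      val_loss = val_loss, val_dice = val_dice)
    if (monitored < best$loss - 1e-12) {
      best <- list(loss = monitored, flat = flat, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
    if (!is.null(train_cfg$stop_train_dice) &&
        mean(ep_dice) > train_cfg$stop_train_dice) {
      # confirm on the training set with the current (post-update) weights
      Pc <- assign_params(model$params, flat)
      cur_dice <- mean(vapply(split$train_ids, function(id)
        step_one(Pc, model_cfg, slices[[id]], train_cfg$loss,
                 want_grad = FALSE)$dice, numeric(1)))
      if (cur_dice > train_cfg$stop_train_dice) {
        best <- list(loss = monitored, flat = flat, epoch = epoch)
        break
      }
    }
  }
  log_df <- do.call(rbind, log_rows)
  final_model <- structure(list(cfg = model_cfg,
                                params = assign_params(model$params, flat)),
                           class = "swunet_model")
  best_model <- structure(list(cfg = model_cfg,
                               params = assign_params(model$params, best$flat)),
                          class = "swunet_model")
  # forward-only pass with the final weights for offline loss verification
  fin <- vapply(split$train_ids, function(id) {
    st <- step_one(final_model$params, model_cfg, slices[[id]],
                   train_cfg$loss, want_grad = FALSE)
    c(st$loss, st$dice)
  }, numeric(2))
  ckpt <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(best_model, ckpt)
    write.csv(log_df, file.path(out_dir, "training_log.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(split = lapply(unclass(split), as.character),
                              best_epoch = best$epoch,
                              final_train_loss = mean(fin[1L, ]),
                              final_train_dice = mean(fin[2L, ])),
                         file.path(out_dir, "run.json"), auto_unbox = TRUE)
  }
  structure(list(model = best_model, final_model = final_model, log = log_df,
                 split = split, batch_ids = batch_log,
                 final_train_loss = mean(fin[1L, ]),
                 final_train_dice = mean(fin[2L, ]),
                 best_epoch = best$epoch, checkpoint = ckpt),
            class = "swunet_fit")
}

#' Save / load a model checkpoint
#'
#' A single serialized archive holding the weights together with the model
#' configuration embedded as JSON.
#'
#' @param model a [swunet_init()] model.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config_json = jsonlite::toJSON(unclass(model$cfg),
                                              auto_unbox = TRUE),
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored `"swunet_model"`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- jsonlite::fromJSON(ck$config_json)
  cfg <- do.call(model_config,
                 cfg[intersect(names(cfg), names(formals(model_config)))])
  structure(list(cfg = cfg, params = ck$params), class = "swunet_model")
}

#' Evaluate a model on labeled slices
#'
#' Runs the forward pass on every case, takes the per-pixel argmax and
#' computes the per-case and aggregate metric report (accuracy, Dice,
#' sensitivity, specificity, H95).
#'
#' @param model a `"swunet_model"` or a checkpoint path.
#' @param data manifest path or list of [labeled_slice()] objects.
#' @param out_dir optional directory for `metrics.json` and `metrics.csv`
#'   (CSV columns in the order Accuracy, Dice, Sensitivity, Specificity,
#'   H95).
#' @return list with `per_case` data frame, `mean` named vector,
#'   `reports` (per-case [full_report()] objects), `n_undefined`.
#' @export
evaluate_swunet <- function(model, data, out_dir = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  slices <- resolve_data(data)
  K <- model$cfg$n_classes
  bad <- vapply(slices, function(sl) max(sl$mask) >= K, logical(1))
  if (any(bad))
    stop("data contains labels outside the model's class range")
  reports <- lapply(slices, function(sl) {
    logits <- swunet_forward(model, sl$image)
    pred <- argmax_classes(grid_to_hwc(logits))
    full_report(pred, sl$mask, n_classes = K)
  })
  agg <- aggregate_reports(reports)
  per_case <- agg$per_case
  per_case$case <- names(slices) %||% as.character(seq_along(slices))
  res <- list(per_case = per_case, mean = agg$mean, reports = reports,
              n_undefined = agg$n_undefined)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(per_case = per_case, mean = as.list(agg$mean),
                              n_undefined = agg$n_undefined),
                         file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    write.csv(per_case[c("case", "Accuracy", "Dice", "Sensitivity",
                         "Specificity", "H95")],
              file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  res
}

#' Predict a segmentation mask for one image
#'
#' Writes the argmax label mask and an overlay PNG: organ/nodule pixels
#' (class 1) tinted green, tumor pixels (class 2) tinted yellow over the
#' grayscale input.
#'
#' @param model a `"swunet_model"` or checkpoint path.
#' @param image an image matrix or a PNG path.
#' @param out_mask,out_overlay optional output PNG paths.
#' @return the integer label mask, invisibly.
#' @export
predict_swunet <- function(model, image, out_mask = NULL, out_overlay = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  img <- if (is.character(image)) read_slice_png(image) else image
  logits <- swunet_forward(model, img)
  mask <- argmax_classes(grid_to_hwc(logits))
  if (!is.null(out_mask)) write_slice_png(mask, out_mask, is_mask = TRUE)
  if (!is.null(out_overlay)) {
    rgb <- array(rep(img, 3L), dim = c(dim(img), 3L))
    g <- mask == 1L; y <- mask == 2L
    blend <- function(ch, sel, col) ch[sel] * 0.5 + 0.5 * col
    rgb[, , 1L][g] <- blend(rgb[, , 1L], g, 0); rgb[, , 2L][g] <- blend(rgb[, , 2L], g, 1)
    rgb[, , 3L][g] <- blend(rgb[, , 3L], g, 0)
    rgb[, , 1L][y] <- blend(rgb[, , 1L], y, 1); rgb[, , 2L][y] <- blend(rgb[, , 2L], y, 1)
    rgb[, , 3L][y] <- blend(rgb[, , 3L], y, 0)
    png::writePNG(rgb, out_overlay)
  }
  invisible(mask)
}

#' Run a named ablation experiment
#'
#' Trains one model per arm on a shared split and seed and reports test-set
#' Dice and H95 per arm: `"sliding_window"` compares the block without and
#' with the shifted-window stage (2 arms); `"downsampling_depth"` compares
#' encoder depths 1, 2 and 3 (3 arms).
#'
#' @param name `"sliding_window"` or `"downsampling_depth"`.
#' @param data manifest path or list of [labeled_slice()] objects.
#' @param base_cfg baseline [model_config()] the arms are derived from.
#' @param train_cfg a [train_config()].
#' @param out_dir optional directory for the comparison CSV.
#' @return data frame with one row per arm (`arm`, `Dice`, `H95`).
#' @export
run_ablation <- function(name = c("sliding_window", "downsampling_depth"),
                         data, base_cfg = model_config(),
                         train_cfg = train_config(), out_dir = NULL) {
  name <- match.arg(name)
  slices <- resolve_data(data)
  ids <- names(slices) %||% as.character(seq_along(slices))
  names(slices) <- ids
  split <- split_dataset(ids, seed = train_cfg$seed)
  arms <- if (name == "sliding_window") {
    list(`No SW` = { c <- base_cfg; c$use_sliding_window <- FALSE; c },
         `With SW` = { c <- base_cfg; c$use_sliding_window <- TRUE; c })
  } else {
    stats::setNames(lapply(1:3, function(d) {
      do.call(model_config, utils::modifyList(
        unclass(base_cfg)[setdiff(names(base_cfg), "grid_side")],
        list(encoder_depth = d)))
    }), paste("Depth", 1:3))
  }
  eval_ids <- if (length(split$test_ids) > 0L) split$test_ids else split$train_ids
  rows <- lapply(names(arms), function(arm) {
    fit <- train_swunet(arms[[arm]], train_cfg, slices, split = split)
    ev <- evaluate_swunet(fit$model, slices[eval_ids])
    data.frame(arm = arm, Dice = unname(ev$mean["Dice"]),
               H95 = unname(ev$mean["H95"]))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, paste0("ablation_", name, ".csv")),
              row.names = FALSE)
  }
  tab
}

#' Model size and cost summary
#'
#' @param cfg a [model_config()].
#' @param json_path optional path for a JSON dump.
#' @return list with `parameters`, `parameters_millions`, `flops_total`,
#'   `flops_g` and the per-stage FLOP table.
#' @export
summarize_model <- function(cfg = model_config(), json_path = NULL) {
  np <- count_parameters(cfg)
  fl <- estimate_flops(cfg)
  out <- list(parameters = np, parameters_millions = np / 1e6,
              flops_total = fl$total, flops_g = fl$total / 1e9,
              stages = fl$stages)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  out
}

#' Dump the shift masks of a window configuration as JSON
#'
#' Debug helper: one record per window with the additive mask encoded in
#' base64 (doubles, little-endian) plus the distinct-pattern census.
#'
#' @param spec a [window_spec()].
#' @param path optional JSON output path.
#' @return the JSON string, invisibly if written to `path`.
#' @export
inspect_masks <- function(spec, path = NULL) {
  ms <- build_shift_masks(spec)
  recs <- lapply(seq_along(ms$per_window_mask), function(w) {
    list(window_index = w,
         mask_base64 = jsonlite::base64_enc(
           writeBin(as.numeric(ms$per_window_mask[[w]]), raw(),
                    endian = "little")))
  })
  js <- jsonlite::toJSON(list(window_side = spec$window_side,
                              shift = spec$shift,
                              grid = c(spec$grid_height, spec$grid_width),
                              n_distinct_patterns = ms$n_distinct_patterns,
                              windows = recs), auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
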