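#' Loss configuration
#'
#' Weights and constants for the compound segmentation loss
#' `L = alpha * L_Dice + beta * L_Focal`.
#'
#' @param alpha Dice-loss weight (default 0.8).
#' @param beta Focal-loss weight (default 0.2).
#' @param gamma focal modulation exponent (default 2; 0 recovers plain
#'   cross-entropy).
#' @param epsilon Dice smoothing constant.
#' @param clip probability clip for the focal log terms.
#' @return list of class `"loss_config"`.
#' @export
loss_config <- function(alpha = 0.8, beta = 0.2, gamma = 2,
                        epsilon = 1e-5, clip = 1e-7) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon, clip = clip), class = "loss_config")
}

#' Pixelwise confusion counts for one class
#'
#' One-vs-rest TP/FP/FN/TN counts between an integer predicted mask and an
#' integer reference mask.
#'
#' @param pred_mask,true_mask integer label arrays of identical shape.
#' @param class_id the class evaluated as "positive".
#' @return list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred_mask, true_mask, class_id = 1L) {
  if (!identical(dim(pred_mask) %||% length(pred_mask),
                 dim(true_mask) %||% length(true_mask)))
    stop("confusion: mask shapes differ")
  p <- pred_mask == class_id
  t <- true_mask == class_id
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Dice similarity coefficient from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; 1 means perfect overlap. When both masks are
#' empty (`2TP + FP + FN = 0`) the coefficient is defined as 1.
#'
#' @param counts output of [confusion()].
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  2 * counts$TP / den
}

#' Hausdorff distance between two point sets
#'
#' Directed distance `d(X, Y)`: for every point of `X` take its minimum
#' Euclidean distance to `Y`, then aggregate at the given percentile (100 =
#' the classical maximum; 95 gives the outlier-robust H95). The returned
#' value is `max(d(X, Y), d(Y, X))` and is symmetric in its arguments.
#'
#' @param X,Y point sets: `n x 2` matrices of (row, col) coordinates in
#'   pixels. Both must be non-empty.
#' @param percentile 100 or 95 (any value in (0, 100] is accepted).
#' @return distance in pixels.
#' @export
hausdorff_distance <- function(X, Y, percentile = 100) {
  X <- as_points(X); Y <- as_points(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L)
    stop("hausdorff_distance is undefined for an empty point set")
  max(directed_hausdorff(X, Y, percentile),
      directed_hausdorff(Y, X, percentile))
}

as_points <- function(P) {
  P <- as.matrix(P)
  if (length(P) && ncol(P) != 2L) stop("point sets must be n x 2 matrices")
  storage.mode(P) <- "double"
  P
}

directed_hausdorff <- function(X, Y, percentile) {
  # min distance from each X point to Y, chunked to bound memory
  mins <- numeric(nrow(X))
  step <- max(1L, floor(2e6 / nrow(Y)))
  for (i0 in seq(1L, nrow(X), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(X))
    d2 <- outer(X[ii, 1L], Y[, 1L], "-")^2 + outer(X[ii, 2L], Y[, 2L], "-")^2
    mins[ii] <- sqrt(apply(d2, 1L, min))
  }
  if (percentile >= 100) max(mins)
  else as.numeric(quantile(mins, percentile / 100, type = 7, names = FALSE))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(y y') + eps) / (sum(y) + sum(y') + eps)` over all pixels,
#' with `y` the binary reference and `y'` the predicted foreground
#' probability. Zero for a perfect prediction; the smoothing `eps` makes the
#' empty-vs-empty case exactly 0.
#'
#' @param pred_probs predicted probabilities in `[0, 1]`.
#' @param true_mask binary reference mask, same shape.
#' @param eps smoothing constant.
#' @return loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_probs, true_mask, eps = 1e-5) {
  if (any(pred_probs < 0 | pred_probs > 1))
    stop("dice_loss: probabilities must lie in [0, 1]")
  y <- as.numeric(true_mask); p <- as.numeric(pred_probs)
  1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)
}

#' Focal loss
#'
#' Sum over pixels of
#' `-y (1-y')^gamma log(y') - (1-y) y'^gamma log(1-y')`, which down-weights
#' easy pixels and counteracts the extreme foreground/background imbalance
#' of small lesions. `gamma = 0` collapses to the plain binary cross-entropy
#' sum. Probabilities are clipped away from 0/1 before the logs.
#'
#' @param pred_probs predicted probabilities.
#' @param true_mask binary reference mask, same shape.
#' @param gamma modulation exponent.
#' @param clip probability clip.
#' @return non-negative loss value.
#' @export
focal_loss <- function(pred_probs, true_mask, gamma = 2, clip = 1e-7) {
  y <- as.numeric(true_mask)
  p <- pmin(pmax(as.numeric(pred_probs), clip), 1 - clip)
  sum(-y * (1 - p)^gamma * log(p) - (1 - y) * p^gamma * log(1 - p))
}

#' Compound segmentation loss
#'
#' `alpha * L_Dice + beta * L_Focal`. For a binary problem supply the
#' foreground probability plane; for a multi-class problem supply an
#' `H x W x K` probability array and an integer label mask, in which case
#' the Dice term is averaged and the Focal term summed over the foreground
#' classes (one-vs-rest), which reduces to the binary form when `K = 2`.
#'
#' @param pred probabilities (plane, or `H x W x K` array).
#' @param true binary mask, or integer label mask for the array form.
#' @param cfg a [loss_config()].
#' @return loss value.
#' @export
combined_loss <- function(pred, true, cfg = loss_config()) {
  if (is.array(pred) && length(dim(pred)) == 3L) {
    K <- dim(pred)[3L]
    fg <- seq_len(K - 1L)
    dce <- vapply(fg, function(c)
      dice_loss(pred[, , c + 1L], true == c, cfg$epsilon), numeric(1))
    foc <- vapply(fg, function(c)
      focal_loss(pred[, , c + 1L], true == c, cfg$gamma, cfg$clip), numeric(1))
    cfg$alpha * mean(dce) + cfg$beta * sum(foc)
  } else {
    cfg$alpha * dice_loss(pred, true, cfg$epsilon) +
      cfg$beta * focal_loss(pred, true, cfg$gamma, cfg$clip)
  }
}

# loss + gradient w.r.t. logits for training. probs = softmax(logits) over
# the 3rd dim; y integer labels in 0..K-1.
seg_loss_grad <- function(logits, y, cfg = loss_config()) {
  d <- dim(logits); K <- d[3L]
  probs <- softmax_classes(logits)
  loss <- combined_loss(probs, y, cfg)
  dP <- array(0, dim = d)
  nfg <- K - 1L
  for (c in seq_len(nfg)) {
    p <- probs[, , c + 1L]
    yc <- (y == c) * 1
    S <- sum(yc * p); Dn <- sum(yc) + sum(p) + cfg$epsilon
    ddice <- -(2 * yc * Dn - (2 * S + cfg$epsilon)) / Dn^2
    pc <- pmin(pmax(p, cfg$clip), 1 - cfg$clip)
    g <- cfg$gamma
    dfoc <- -yc * (1 - pc)^(g - 1) * ((1 - pc) / pc - g * log(pc)) -
      (1 - yc) * pc^(g - 1) * (g * log(1 - pc) - pc / (1 - pc))
    dP[, , c + 1L] <- cfg$alpha * ddice / nfg + cfg$beta * dfoc
  }
  # softmax jacobian: dlogit_k = p_k * (dP_k - sum_j dP_j p_j)
  inner <- array(0, dim = d[1:2])
  for (k in seq_len(K)) inner <- inner + dP[, , k] * probs[, , k]
  dlogits <- array(0, dim = d)
  for (k in seq_len(K)) dlogits[, , k] <- probs[, , k] * (dP[, , k] - inner)
  list(loss = loss, probs = probs, dlogits = dlogits)
}

softmax_classes <- function(logits) {
  d <- dim(logits); K <- d[3L]
  m <- logits[, , 1L]
  if (K > 1L) for (k in 2:K) m <- pmax(m, logits[, , k])
  e <- exp(logits - as.vector(m))
  tot <- array(0, dim = d[1:2])
  for (k in seq_len(K)) tot <- tot + e[, , k]
  e / as.vector(tot)
}

argmax_classes <- function(logits) {
  d <- dim(logits)
  flat <- matrix(logits, ncol = d[3L])
  matrix(max.col(flat, ties.method = "first") - 1L, d[1L], d[2L])
}

#' Boundary pixels of a class region
#'
#' Pixels of the class that touch (4-neighbourhood) a pixel of another class
#' or the image border; these are the points used for the Hausdorff metric.
#'
#' @param mask integer label matrix.
#' @param class_id class whose boundary is extracted.
#' @return `n x 2` matrix of (row, col) coordinates.
#' @export
boundary_points <- function(mask, class_id = 1L) {
  m <- mask == class_id
  if (!any(m)) return(matrix(numeric(0), 0L, 2L))
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  interior <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(m & !interior, arr.ind = TRUE)
}

#' Per-class segmentation metrics report
#'
#' For every foreground class: pixel accuracy `(TP+TN)/total`, Dice,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the Hausdorff
#' distance at the requested percentile computed between the class boundary
#' point sets. Degenerate quantities (empty reference or prediction for the
#' Hausdorff; zero denominators) are reported as `NA` and counted in
#' `n_undefined` rather than silently zeroed.
#'
#' @param pred_mask,true_mask integer label matrices on the same raster.
#' @param n_classes total class count (labels `0..n_classes-1`).
#' @param percentile Hausdorff percentile (default 95).
#' @return object of class `"metrics_report"`: `per_class` data frame with
#'   columns `class`, `Accuracy`, `Dice`, `Sensitivity`, `Specificity`,
#'   `H95`; `aggregate` (unweighted mean over foreground classes, `NA`
#'   excluded); `n_undefined`.
#' @export
full_report <- function(pred_mask, true_mask, n_classes = 2L,
                        percentile = 95) {
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop("full_report: masks must share one raster")
  fg <- seq_len(n_classes - 1L)
  rows <- lapply(fg, function(cl) {
    cc <- confusion(pred_mask, true_mask, cl)
    tot <- cc$TP + cc$FP + cc$FN + cc$TN
    sens <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
    spec <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_
    bp <- boundary_points(pred_mask, cl)
    bt <- boundary_points(true_mask, cl)
    h95 <- if (nrow(bp) > 0L && nrow(bt) > 0L)
      hausdorff_distance(bp, bt, percentile) else NA_real_
    data.frame(class = cl, Accuracy = (cc$TP + cc$TN) / tot,
               Dice = dice_coefficient(cc), Sensitivity = sens,
               Specificity = spec, H95 = h95)
  })
  per_class <- do.call(rbind, rows)
  metric_cols <- c("Accuracy", "Dice", "Sensitivity", "Specificity", "H95")
  aggregate <- colMeans(per_class[metric_cols], na.rm = TRUE)
  structure(list(per_class = per_class, aggregate = aggregate,
                 n_undefined = sum(is.na(per_class[metric_cols]))),
            class = "metrics_report")
}

#' Aggregate per-case metric reports
#'
#' Unweighted mean of the per-case aggregates; undefined (NA) entries are
#' excluded from the means and their count reported.
#'
#' @param reports list of [full_report()] objects.
#' @return list with `per_case` (data frame, one row per case), `mean`
#'   (named vector) and `n_undefined`.
#' @export
aggregate_reports <- function(reports) {
  per_case <- do.call(rbind, lapply(seq_along(reports), function(i) {
    data.frame(case = i, t(reports[[i]]$aggregate))
  }))
  metric_cols <- c("Accuracy", "Dice", "Sensitivity", "Specificity", "H95")
  list(per_case = per_case,
       mean = colMeans(per_case[metric_cols], na.rm = TRUE),
       n_undefined = sum(vapply(reports, function(r) r$n_undefined, numeric(1))))
}
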