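#' Window specification for windowed attention
#'
#' Describes the square attention windows laid over a token grid: the window
#' side `M`, the cyclic shift `s` applied before the second (shifted)
#' attention stage, and the grid the windows tile.
#'
#' @param window_side window side length `M` in tokens.
#' @param shift cyclic shift `s` in tokens, `0 <= s < M`. Defaults to `M/2`,
#'   the half-window displacement used by the sliding-window stage.
#' @param grid_height,grid_width token grid dims; each must be a multiple of
#'   `window_side`.
#' @return a list of class `"window_spec"`.
#' @export
window_spec <- function(window_side = 4L, shift = window_side %/% 2L,
                        grid_height, grid_width) {
  window_side <- as.integer(window_side)
  shift <- as.integer(shift)
  grid_height <- as.integer(grid_height)
  grid_width <- as.integer(grid_width)
  if (grid_height %% window_side != 0L || grid_width %% window_side != 0L)
    stop(sprintf("window side %d must divide grid dims %d x %d",
                 window_side, grid_height, grid_width))
  if (shift < 0L || shift >= window_side)
    stop(sprintf("shift %d out of range [0, %d)", shift, window_side))
  structure(list(window_side = window_side, shift = shift,
                 grid_height = grid_height, grid_width = grid_width),
            class = "window_spec")
}

# 1-based row-major token indices (into a row-major token sequence) for each
# window; windows ordered row-major over the window grid, tokens row-major
# within each window
window_token_index <- function(spec) {
  M <- spec$window_side; H <- spec$grid_height; W <- spec$grid_width
  nwr <- H %/% M; nwc <- W %/% M
  out <- vector("list", nwr * nwc)
  w <- 0L
  for (wr in seq_len(nwr)) {
    for (wc in seq_len(nwc)) {
      w <- w + 1L
      rows <- (wr - 1L) * M + seq_len(M)
      cols <- (wc - 1L) * M + seq_len(M)
      # token id (row-major): (r-1)*W + c, tokens row-major within window
      out[[w]] <- as.vector(t(outer(rows - 1L, cols, function(r, c) r * W + c)))
    }
  }
  out
}

#' Partition a feature grid into attention windows
#'
#' Splits the grid into non-overlapping `M x M` windows (row-major order) and
#' returns each window as an `M^2 x d` token matrix (tokens row-major within
#' the window). Attention is computed independently inside each window.
#'
#' @param grid a [feature_grid()] with `d` channels.
#' @param spec a [window_spec()] matching the grid's spatial dims.
#' @return list of `(H/M)*(W/M)` matrices, each `M^2 x d`.
#' @seealso [merge_windows()] for the exact inverse.
#' @export
partition_windows <- function(grid, spec) {
  gd <- grid_dims(grid)
  if (gd$height != spec$grid_height || gd$width != spec$grid_width)
    stop(sprintf("grid is %d x %d but window spec expects %d x %d",
                 gd$height, gd$width, spec$grid_height, spec$grid_width))
  if (gd$height %% spec$window_side != 0L || gd$width %% spec$window_side != 0L)
    stop(sprintf("window side %d does not divide grid dims %d x %d",
                 spec$window_side, gd$height, gd$width))
  tok <- t(unclass(grid_to_tokens(grid)))   # N x d
  idx <- window_token_index(spec)
  lapply(idx, function(i) tok[i, , drop = FALSE])
}

#' Merge attention windows back into a feature grid
#'
#' Inverse of [partition_windows()]: given the windows in row-major order,
#' reconstructs the original grid bit-identically.
#'
#' @param windows list of `M^2 x d` window token matrices.
#' @param spec the [window_spec()] used to partition.
#' @return a [feature_grid()] of dim `(d, H, W)`.
#' @export
merge_windows <- function(windows, spec) {
  idx <- window_token_index(spec)
  if (length(windows) != length(idx))
    stop(sprintf("expected %d windows, got %d", length(idx), length(windows)))
  d <- ncol(windows[[1L]])
  N <- spec$grid_height * spec$grid_width
  tok <- matrix(0, nrow = N, ncol = d)
  for (w in seq_along(idx)) tok[idx[[w]], ] <- windows[[w]]
  tokens_to_grid(t(tok), height = spec$grid_height, width = spec$grid_width)
}

#' Cyclically shift a feature grid
#'
#' Rolls the grid contents up and to the left by `s` pixels (wrapping at the
#' borders), which moves the attention windows down-right by `s` relative to
#' the content. `cyclic_shift(g, s)` followed by `cyclic_shift(., -s)` is the
#' identity. The operation is a pure permutation of pixels.
#'
#' @param grid a [feature_grid()].
#' @param s shift in pixels, `|s| < min(H, W)`; negative values roll the
#'   opposite way (the inverse shift).
#' @return the shifted [feature_grid()].
#' @export
cyclic_shift <- function(grid, s) {
  gd <- grid_dims(grid)
  s <- as.integer(s)
  if (abs(s) >= min(gd$height, gd$width))
    stop(sprintf("shift %d out of range: |s| must be < min(H, W) = %d",
                 s, min(gd$height, gd$width)))
  if (s == 0L) return(grid)
  ridx <- ((seq_len(gd$height) - 1L + s) %% gd$height) + 1L
  cidx <- ((seq_len(gd$width) - 1L + s) %% gd$width) + 1L
  feature_grid(unclass(grid)[, ridx, cidx, drop = FALSE])
}

# TRUE where a token of the *shifted* grid wrapped around (its pre-shift
# source lay on the opposite border); rows/cols are shifted-grid coordinates
wrap_indicators <- function(n, s) if (s == 0L) rep(FALSE, n) else seq_len(n) > n - s

#' Build the additive attention masks for the shifted stage
#'
#' After the cyclic shift, windows along the right and bottom edges contain
#' tokens whose pre-shift positions were not adjacent (they wrapped around
#' the border). Attention between such token pairs is meaningless, so each
#' window gets an additive mask with `-1e9` at those pairs and `0`
#' elsewhere; added to the attention scores before the softmax, it drives
#' the offending weights to zero. For a multi-window grid with `0 < s < M`
#' three distinct non-trivial mask patterns arise: right-edge windows
#' (column wrap), bottom-edge windows (row wrap), and the corner window
#' (both).
#'
#' @param spec a [window_spec()].
#' @return a list of class `"mask_set"` with `per_window_mask` (one
#'   `M^2 x M^2` matrix per window, row-major window order) and
#'   `n_distinct_patterns`, the number of distinct non-all-zero masks.
#' @export
build_shift_masks <- function(spec) {
  M <- spec$window_side; H <- spec$grid_height; W <- spec$grid_width
  s <- spec$shift
  wrap_r <- wrap_indicators(H, s)
  wrap_c <- wrap_indicators(W, s)
  idx <- window_token_index(spec)
  masks <- vector("list", length(idx))
  keys <- character(length(idx))
  for (w in seq_along(idx)) {
    tid <- idx[[w]]                      # 1-based row-major token ids
    r <- (tid - 1L) %/% W + 1L
    c <- (tid - 1L) %% W + 1L
    lab <- paste(wrap_r[r], wrap_c[c])   # source-region label per token
    mk <- matrix(0, M * M, M * M)
    mk[outer(lab, lab, "!=")] <- MASK_NEG
    masks[[w]] <- mk
    keys[w] <- paste(as.integer(mk != 0), collapse = "")
  }
  nontrivial <- keys[vapply(masks, function(m) any(m != 0), logical(1L))]
  structure(list(per_window_mask = masks,
                 n_distinct_patterns = length(unique(nontrivial))),
            class = "mask_set")
}
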