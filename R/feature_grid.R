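#' Construct a feature grid
#'
#' A feature grid is the package's spatial feature container: a dense numeric
#' array indexed `(channel, row, col)`. A plain `H x W` matrix is promoted to
#' a single-channel grid.
#'
#' @param values numeric array of dim `(channels, height, width)`, or an
#'   `H x W` matrix (treated as one channel).
#' @return an array of class `"feature_grid"` with dim `(C, H, W)`.
#' @export
feature_grid <- function(values) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, nrow(values), ncol(values)))
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("feature grid values must be a (channels, height, width) array")
  if (any(dim(values) < 1L))
    stop("feature grid dims must all be >= 1")
  if (!all(is.finite(values)))
    stop("feature grid values must be finite")
  structure(values, class = c("feature_grid", "array"))
}

grid_dims <- function(grid) {
  d <- dim(grid)
  list(channels = d[1L], height = d[2L], width = d[3L])
}

#' Flatten a feature grid into a token sequence
#'
#' Tokens are ordered row-major over the spatial grid (row 1 left-to-right,
#' then row 2, ...), each token being the channel vector at that pixel. The
#' result is a `d x N` matrix as expected by [swtb_forward()].
#'
#' @param grid a [feature_grid()].
#' @param stage_tag optional label for the transformer stage this sequence
#'   represents (`"z0"`, `"z1"`, ... ).
#' @return a `d x N` numeric matrix of class `"token_sequence"` with
#'   attributes `grid_height`, `grid_width`, `stage_tag`.
#' @export
grid_to_tokens <- function(grid, stage_tag = "z0") {
  d <- dim(grid)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  # column-major flatten gives spatial order (row fastest); reorder to
  # row-major token order (col fastest)
  m <- matrix(grid, nrow = C)                      # C x (H*W), col-major spatial
  rm_order <- as.vector(t(matrix(seq_len(H * W), nrow = H)))
  tok <- m[, rm_order, drop = FALSE]
  structure(tok, grid_height = H, grid_width = W, stage_tag = stage_tag,
            class = c("token_sequence", "matrix"))
}

#' Reshape a token sequence back into a feature grid
#'
#' Exact inverse of [grid_to_tokens()]; the round trip is lossless.
#'
#' @param tokens a `d x N` token matrix.
#' @param height,width spatial dims; defaults to the attributes stored by
#'   [grid_to_tokens()]. `height * width` must equal `N`.
#' @return a [feature_grid()] of dim `(d, height, width)`.
#' @export
tokens_to_grid <- function(tokens, height = attr(tokens, "grid_height"),
                           width = attr(tokens, "grid_width")) {
  if (is.null(height) || is.null(width))
    stop("height/width not supplied and not stored on the token sequence")
  N <- ncol(tokens)
  if (height * width != N)
    stop(sprintf("token count %d does not match %d x %d grid", N, height, width))
  d <- nrow(tokens)
  cm_order <- as.vector(t(matrix(seq_len(N), ncol = height)))
  m <- tokens[, cm_order, drop = FALSE]
  feature_grid(array(m, dim = c(d, height, width)))
}

# internal layout used by the network engine: (H, W, C) arrays
grid_to_hwc <- function(grid) aperm(unclass(grid), c(2L, 3L, 1L))
hwc_to_grid <- function(x) feature_grid(aperm(x, c(3L, 1L, 2L)))
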