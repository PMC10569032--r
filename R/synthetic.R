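#' Phantom generation settings
#'
#' Parameters of the synthetic CT-like phantoms used for desk-scale runs:
#' bright lesions with Gaussian intensity profiles on a smoothly textured
#' background, either binary (nodule) or 3-class (organ containing a much
#' smaller tumor).
#'
#' @param side image side in pixels.
#' @param n_lesions lesion count (binary phantoms).
#' @param lesion_radius_range min/max lesion semi-axis in pixels; must be
#'   positive and below `side/4`.
#' @param intensity_contrast lesion-vs-background intensity offset (before
#'   the final normalization).
#' @param noise_sd additive noise scale.
#' @param n_classes 2 (nodule) or 3 (organ + tumor).
#' @param seed integer seed; fixes the whole sample.
#' @return list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(side = 128L, n_lesions = 2L,
                         lesion_radius_range = c(3, 10),
                         intensity_contrast = 0.5, noise_sd = 0.08,
                         n_classes = 2L, seed = 1L) {
  if (any(lesion_radius_range <= 0) || max(lesion_radius_range) >= side / 4)
    stop("lesion radii must be positive and < side/4")
  structure(list(side = as.integer(side), n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 intensity_contrast = intensity_contrast, noise_sd = noise_sd,
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth low-frequency background texture around a base gray level
phantom_background <- function(side, base = 0.4, amplitude = 0.05) {
  n <- matrix(rnorm(side * side), side, side)
  sm <- as.matrix(EBImage::gblur(n, sigma = side / 16))
  base + amplitude * (sm - mean(sm)) / stats::sd(sm)
}

# Gaussian-profile rotated ellipse; returns the profile (1 at centre) and
# its half-maximum support. Semi-axes a (along theta) and b.
ellipse_profile <- function(side, ctr, a, b, theta) {
  s1 <- a / sqrt(2 * log(2)); s2 <- b / sqrt(2 * log(2))
  rr <- matrix(seq_len(side), side, side) - ctr[1L]
  cc <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr[2L]
  u1 <- cos(theta) * rr + sin(theta) * cc
  u2 <- -sin(theta) * rr + cos(theta) * cc
  q <- (u1 / s1)^2 + (u2 / s2)^2
  g <- exp(-q / 2)
  list(profile = g, support = g >= 0.5)
}

#' Generate a binary nodule phantom
#'
#' Textured background plus `n_lesions` non-overlapping bright elliptical
#' blobs with Gaussian intensity profiles; the mask is 1 exactly on the
#' half-maximum support of each blob. Additive noise (truncated at two
#' standard deviations) is applied before the final MinMax normalization,
#' so the returned image lies in `[0, 1]`. Fully deterministic under the
#' spec seed.
#'
#' @param spec a [phantom_spec()] with `n_classes = 2`.
#' @return a [labeled_slice()].
#' @export
make_nodule_phantom <- function(spec = phantom_spec()) {
  if (spec$n_classes != 2L) stop("nodule phantoms are binary (n_classes = 2)")
  with_seed(spec$seed, {
    side <- spec$side
    img <- phantom_background(side)
    mask <- matrix(0L, side, side)
    if (spec$n_lesions > 0L) {
      rmax <- max(spec$lesion_radius_range)
      for (i in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (try in seq_len(100L)) {
          a <- runif(1, spec$lesion_radius_range[1L], spec$lesion_radius_range[2L])
          b <- a * runif(1, 0.6, 1)
          ctr <- runif(2, rmax + 2, side - rmax - 1)
          ep <- ellipse_profile(side, ctr, a, b, runif(1, 0, pi))
          if (!any(ep$support & mask == 1L)) {
            img <- img + spec$intensity_contrast * ep$profile
            mask[ep$support] <- 1L
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("phantom generation failed: could not place lesion")
      }
    }
    noise <- matrix(rnorm(side * side, 0, spec$noise_sd), side, side)
    noise <- pmin(pmax(noise, -2 * spec$noise_sd), 2 * spec$noise_sd)
    img <- minmax_normalize(img + noise)
    labeled_slice(img, mask, source_id = sprintf("phantom_nodule_%d", spec$seed))
  })
}

#' Generate a 3-class organ/tumor phantom
#'
#' One large elliptical "organ" region (label 1) containing a much smaller
#' circular "tumor" (label 2) fully inside it; the tumor area is below 15%
#' of the organ area by construction, emulating datasets where tumors are
#' tiny relative to the host organ.
#'
#' @param spec a [phantom_spec()] with `n_classes = 3`.
#' @return a [labeled_slice()] with mask labels in `{0, 1, 2}`.
#' @export
make_organ_tumor_phantom <- function(spec = phantom_spec(n_classes = 3L)) {
  if (spec$n_classes != 3L) stop("organ/tumor phantoms need n_classes = 3")
  with_seed(spec$seed, {
    side <- spec$side
    img <- phantom_background(side)
    mask <- matrix(0L, side, side)
    a <- runif(1, side / 5, side / 3.8)
    b <- a * runif(1, 0.7, 0.95)
    ctr <- side / 2 + runif(2, -side / 12, side / 12)
    theta <- runif(1, 0, pi)
    organ <- ellipse_profile(side, ctr, a, b, theta)
    mask[organ$support] <- 1L
    img <- img + spec$intensity_contrast * 0.6 * organ$profile
    placed <- FALSE
    for (try in seq_len(100L)) {
      rt <- b * runif(1, 0.15, 0.3)
      off <- runif(2, -(b - rt) * 0.5, (b - rt) * 0.5)
      tum <- ellipse_profile(side, ctr + off, rt, rt, 0)
      if (all(mask[tum$support] == 1L)) {
        mask[tum$support] <- 2L
        img <- img + spec$intensity_contrast * tum$profile
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("phantom generation failed: could not place tumor")
    noise <- matrix(rnorm(side * side, 0, spec$noise_sd), side, side)
    noise <- pmin(pmax(noise, -2 * spec$noise_sd), 2 * spec$noise_sd)
    img <- minmax_normalize(img + noise)
    labeled_slice(img, mask, source_id = sprintf("phantom_organ_%d", spec$seed))
  })
}

make_phantom <- function(spec) {
  if (spec$n_classes == 2L) make_nodule_phantom(spec)
  else make_organ_tumor_phantom(spec)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask pairs plus a CSV manifest consumable by
#' [load_dataset()] and the training pipeline. Item `i` uses seed
#' `spec$seed + i`, so regeneration with the same spec reproduces the files
#' bit for bit.
#'
#' @param n number of slices.
#' @param spec a [phantom_spec()]; `n_classes` selects the phantom type.
#' @param out_dir output directory (created if missing).
#' @param format `"png"` (8-bit) or `"nifti"`.
#' @return the manifest path, invisibly.
#' @export
make_dataset <- function(n, spec = phantom_spec(), out_dir,
                         format = c("png", "nifti")) {
  format <- match.arg(format)
  if (n < 1L) stop("n must be >= 1")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", out_dir))
  ext <- if (format == "png") "png" else "nii.gz"
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec; sp$seed <- spec$seed + i
    sl <- make_phantom(sp)
    id <- sprintf("case_%04d", i)
    img_f <- file.path(out_dir, sprintf("%s_image.%s", id, ext))
    msk_f <- file.path(out_dir, sprintf("%s_mask.%s", id, ext))
    if (format == "png") {
      write_slice_png(sl$image, img_f)
      write_slice_png(sl$mask, msk_f, is_mask = TRUE)
    } else {
      write_nifti_volume(array(sl$image, dim = c(dim(sl$image), 1L)), img_f)
      write_nifti_volume(array(sl$mask, dim = c(dim(sl$mask), 1L)), msk_f)
    }
    rows[[i]] <- data.frame(id = id, image = basename(img_f),
                            mask = basename(msk_f), n_classes = sp$n_classes,
                            seed = sp$seed, format = format)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset from a manifest
#'
#' @param manifest path to a `manifest.csv` written by [make_dataset()].
#' @return named list of [labeled_slice()] objects (names = case ids).
#' @export
load_dataset <- function(manifest) {
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  out <- lapply(seq_len(nrow(df)), function(i) {
    if (df$format[i] == "png") {
      img <- read_slice_png(file.path(base, df$image[i]))
      msk <- read_slice_png(file.path(base, df$mask[i]), is_mask = TRUE)
    } else {
      img <- read_nifti_volume(file.path(base, df$image[i]))$volume[, , 1L]
      msk <- read_nifti_volume(file.path(base, df$mask[i]))$volume[, , 1L]
      storage.mode(msk) <- "integer"
    }
    labeled_slice(img, msk, source_id = df$id[i])
  })
  names(out) <- df$id
  out
}

#' Generate a phantom dataset in memory
#'
#' @param n number of slices.
#' @param spec a [phantom_spec()].
#' @return named list of [labeled_slice()] objects.
#' @export
make_phantom_set <- function(n, spec = phantom_spec()) {
  out <- lapply(seq_len(n), function(i) {
    sp <- spec; sp$seed <- spec$seed + i
    make_phantom(sp)
  })
  names(out) <- sprintf("case_%04d", seq_len(n))
  out
}
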