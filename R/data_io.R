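#' Per-image MinMax normalization
#'
#' `(x - min(x)) / (max(x) - min(x))`, mapping every image into `[0, 1]`.
#' A constant image (where the ratio is 0/0) maps to all zeros, preserving
#' the range postcondition. Idempotent.
#'
#' @param image numeric array with finite values.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(image) {
  if (!all(is.finite(image))) stop("minmax_normalize: non-finite values")
  rng <- range(image)
  if (rng[1L] == rng[2L]) return(array(0, dim = dim(image) %||% length(image)))
  (image - rng[1L]) / (rng[2L] - rng[1L])
}

#' Nodule annotation record
#'
#' World-coordinate lesion annotation in the LUNA16 CSV convention: a centre
#' in millimetres plus a diameter.
#'
#' @param series_id scan identifier.
#' @param world_x,world_y,world_z centre, mm.
#' @param diameter lesion diameter, mm (> 0).
#' @return list of class `"nodule_annotation"`.
#' @export
nodule_annotation <- function(series_id, world_x, world_y, world_z, diameter) {
  if (diameter <= 0) stop("annotation diameter must be > 0")
  structure(list(series_id = series_id, world_x = world_x, world_y = world_y,
                 world_z = world_z, diameter = diameter),
            class = "nodule_annotation")
}

#' Read a LUNA16-style annotation CSV
#'
#' Expects the header `seriesuid,coordX,coordY,coordZ,diameter_mm`. If the
#' diameter column is absent a configurable default is substituted.
#'
#' @param path CSV path.
#' @param default_diameter diameter in mm used when the file carries none.
#' @return list of [nodule_annotation()] records.
#' @export
read_annotations <- function(path, default_diameter = 3) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns seriesuid, coordX, coordY, coordZ")
  dm <- if ("diameter_mm" %in% names(df)) df$diameter_mm
        else rep(default_diameter, nrow(df))
  lapply(seq_len(nrow(df)), function(i)
    nodule_annotation(df$seriesuid[i], df$coordX[i], df$coordY[i],
                      df$coordZ[i], dm[i]))
}

#' Rasterize a world-coordinate annotation into a 3-D binary mask
#'
#' Marks every voxel whose centre lies within `diameter/2` mm of the
#' annotation centre (a sphere in world space, an ellipsoid in voxels under
#' anisotropic spacing). Voxel centres are at `origin + index * spacing`
#' with 0-based indices and no axis flips (the MetaImage convention). If the
#' sphere is smaller than a voxel, the single nearest voxel is set.
#'
#' @param ann a [nodule_annotation()].
#' @param origin length-3 world origin, mm.
#' @param spacing length-3 voxel spacing, mm.
#' @param shape length-3 volume dims in voxels (x, y, z).
#' @return binary array of dim `shape`.
#' @export
annotation_to_mask <- function(ann, origin, spacing, shape) {
  ctr_vox <- (c(ann$world_x, ann$world_y, ann$world_z) - origin) / spacing
  if (any(ctr_vox < 0) || any(ctr_vox > shape - 1))
    stop(sprintf("annotation centre (voxel %s) outside volume of shape %s",
                 paste(round(ctr_vox, 2), collapse = ","),
                 paste(shape, collapse = ",")))
  r <- ann$diameter / 2
  mask <- array(0L, dim = shape)
  # bounding box in voxels, then exact mm-distance test
  lo <- pmax(floor(ctr_vox - r / spacing), 0)
  hi <- pmin(ceiling(ctr_vox + r / spacing), shape - 1)
  xs <- lo[1L]:hi[1L]; ys <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  dx2 <- ((xs - ctr_vox[1L]) * spacing[1L])^2
  dy2 <- ((ys - ctr_vox[2L]) * spacing[2L])^2
  dz2 <- ((zs - ctr_vox[3L]) * spacing[3L])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  sub <- array(0L, dim = dim(d2))
  sub[d2 <= r^2] <- 1L
  mask[xs + 1L, ys + 1L, zs + 1L] <- sub
  if (sum(mask) == 0L) {
    nearest <- pmin(pmax(round(ctr_vox), 0), shape - 1) + 1L
    mask[nearest[1L], nearest[2L], nearest[3L]] <- 1L
  }
  mask
}

#' Crop a lesion-centred patch
#'
#' Returns a `side x side` window centred on `centre_px`; at image borders
#' the window is clamped (shifted inside) rather than zero-padded, so the
#' patch always contains real image content.
#'
#' @param slice2d source matrix, at least `side` in both dims.
#' @param centre_px length-2 (row, col) centre in pixels.
#' @param side patch side (default 128).
#' @return `side x side` matrix.
#' @export
crop_patch <- function(slice2d, centre_px, side = 128L) {
  H <- nrow(slice2d); W <- ncol(slice2d)
  if (H < side || W < side)
    stop(sprintf("source %d x %d smaller than patch side %d; resample first",
                 H, W, side))
  r0 <- min(max(round(centre_px[1L]) - side %/% 2L, 1L), H - side + 1L)
  c0 <- min(max(round(centre_px[2L]) - side %/% 2L, 1L), W - side + 1L)
  slice2d[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
}

#' Resample a 2-D image to a square target size
#'
#' Bilinear interpolation for intensity images; nearest-neighbour for label
#' masks (never introducing new label values). A correctly sized input is
#' returned unchanged.
#'
#' @param image 2-D matrix.
#' @param target_side output side (default 128).
#' @param is_mask nearest-neighbour label resampling if `TRUE`.
#' @return `target_side x target_side` matrix.
#' @export
resample_to <- function(image, target_side = 128L, is_mask = FALSE) {
  if (nrow(image) == target_side && ncol(image) == target_side) return(image)
  out <- EBImage::resize(image, w = target_side, h = target_side,
                         filter = if (is_mask) "none" else "bilinear")
  out <- matrix(as.numeric(out), target_side, target_side)
  if (is_mask) {
    out <- round(out)
    storage.mode(out) <- "integer"
  }
  out
}

#' Deterministic train/validation/test split
#'
#' Shuffles the ids with a seeded generator and partitions by the given
#' fractions (sizes by floor, remainder to the training set). The partition
#' is disjoint and exhaustive and identical for identical seeds.
#'
#' @param ids character or integer vector of at least 3 case ids.
#' @param fractions length-3 train/val/test fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param seed integer seed.
#' @return list of class `"split_plan"` with `train_ids`, `val_ids`,
#'   `test_ids`, `seed`.
#' @export
split_dataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ids) < 3L) stop("need at least 3 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  shuffled <- with_seed(seed, sample(ids))
  n <- length(ids)
  n_val <- floor(fractions[2L] * n)
  n_test <- floor(fractions[3L] * n)
  n_train <- n - n_val - n_test
  structure(list(train_ids = shuffled[seq_len(n_train)],
                 val_ids = shuffled[n_train + seq_len(n_val)],
                 test_ids = shuffled[n_train + n_val + seq_len(n_test)],
                 seed = as.integer(seed)), class = "split_plan")
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a split plan as JSON
#' @param plan a [split_dataset()] plan.
#' @param path output path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# ---- file formats -----------------------------------------------------------

#' Read a MetaImage (.mhd + .raw) volume
#'
#' Minimal reader for the uncompressed MetaImage format used by LUNA16:
#' parses the text header and loads the raw voxel block. (No installed R
#' package reads MetaImage, so the format is handled directly.)
#'
#' @param path path to the `.mhd` header.
#' @return list with `volume` (array, x-y-z), `spacing`, `origin`.
#' @export
read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  hdr <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1L]])
  spacing <- if ("ElementSpacing" %in% names(hdr))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1L]]) else rep(1, 3)
  origin <- if ("Offset" %in% names(hdr))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1L]]) else rep(0, 3)
  type <- hdr[["ElementType"]]
  raw_path <- file.path(dirname(path), hdr[["ElementDataFile"]])
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(type,
    "MET_SHORT" = readBin(con, "integer", n, size = 2L, signed = TRUE,
                          endian = "little"),
    "MET_USHORT" = readBin(con, "integer", n, size = 2L, signed = FALSE,
                           endian = "little"),
    "MET_UCHAR" = as.integer(readBin(con, "raw", n)),
    "MET_FLOAT" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "MET_DOUBLE" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop(sprintf("unsupported MetaImage element type %s", type)))
  list(volume = array(as.numeric(vals), dim = dims), spacing = spacing,
       origin = origin)
}

#' Write a MetaImage (.mhd + .raw) volume
#'
#' @param volume 3-D array (x-y-z).
#' @param path output `.mhd` path (the `.raw` is written alongside).
#' @param spacing,origin voxel spacing and world origin, mm.
#' @param type `"MET_FLOAT"` or `"MET_SHORT"`.
#' @export
write_mhd <- function(volume, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      type = c("MET_FLOAT", "MET_SHORT")) {
  type <- match.arg(type)
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(volume), collapse = " ")),
           paste("ElementSpacing =", paste(spacing, collapse = " ")),
           paste("Offset =", paste(origin, collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (type == "MET_SHORT")
    writeBin(as.integer(round(volume)), con, size = 2L, endian = "little")
  else
    writeBin(as.numeric(volume), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path `.nii` / `.nii.gz` path.
#' @return list with `volume` (array), `spacing` (pixdim), `origin`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img),
       origin = as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img)))
}

#' Write a NIfTI volume
#' @param volume array.
#' @param path output path.
#' @param spacing voxel spacing.
#' @export
write_nifti_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 2-D grayscale PNG
#'
#' @param path PNG path.
#' @param is_mask if `TRUE`, gray levels are decoded back to integer labels.
#' @return numeric matrix in `[0, 1]`, or an integer label matrix.
#' @export
read_slice_png <- function(path, is_mask = FALSE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (is_mask) {
    m <- round(img * 255)
    storage.mode(m) <- "integer"
    m
  } else img
}

#' Write a 2-D image or label mask as PNG
#'
#' Intensities are stored as 8-bit gray; label masks store the raw label
#' value as the gray level so they round-trip exactly for < 256 classes.
#'
#' @param image numeric matrix in `[0, 1]`, or integer label matrix.
#' @param path output path.
#' @param is_mask store labels as raw gray levels if `TRUE`.
#' @export
write_slice_png <- function(image, path, is_mask = FALSE) {
  if (is_mask) png::writePNG(image / 255, path)
  else png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Bundle an image and mask as a labeled slice
#'
#' The unit the network consumes: a normalized `side x side` intensity
#' image with a per-pixel integer class mask.
#'
#' @param image matrix in `[0, 1]`.
#' @param mask integer label matrix of the same shape.
#' @param source_id provenance string.
#' @param pixel_spacing optional mm-per-pixel.
#' @return list of class `"labeled_slice"`.
#' @export
labeled_slice <- function(image, mask, source_id = "", pixel_spacing = NULL) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (min(image) < 0 || max(image) > 1)
    stop("image must be normalized to [0, 1]")
  structure(list(image = image, mask = mask, source_id = source_id,
                 pixel_spacing = pixel_spacing), class = "labeled_slice")
}

#' Extract lesion-centred labeled slices from a volume
#'
#' Rasterizes each annotation into the volume, takes every axial slice that
#' intersects the lesion mask, crops a `side x side` patch centred on the
#' in-slice lesion centroid (clamped at borders), and MinMax-normalizes the
#' cropped image.
#'
#' @param volume 3-D intensity array (x, y, z).
#' @param annotations list of [nodule_annotation()].
#' @param origin,spacing volume geometry, mm.
#' @param side patch side (default 128).
#' @return list of [labeled_slice()] objects.
#' @export
extract_labeled_slices <- function(volume, annotations, origin, spacing,
                                   side = 128L) {
  out <- list()
  for (ann in annotations) {
    mask3 <- annotation_to_mask(ann, origin, spacing, dim(volume))
    zs <- which(apply(mask3, 3L, sum) > 0)
    for (z in zs) {
      sl <- volume[, , z]
      mk <- mask3[, , z]
      ctr <- colMeans(which(mk == 1L, arr.ind = TRUE))
      img <- minmax_normalize(crop_patch(sl, ctr, side))
      msk <- crop_patch(mk, ctr, side)
      out <- c(out, list(labeled_slice(img, msk,
                                       source_id = sprintf("%s_z%03d", ann$series_id, z),
                                       pixel_spacing = spacing[1:2])))
    }
  }
  out
}
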