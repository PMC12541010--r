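#' 2D training samples
#'
#' A `sample2d` pairs one axial image slice, stored `(y, x, channel)`, with
#' its integer label slice `(y, x)` and provenance (volume id, 1-based slice
#' index along the axial axis).
#'
#' @param image numeric array `(y, x, channel)`.
#' @param mask integer matrix `(y, x)` with values in \{0, 1, 2, 4\}.
#' @param volume_id character id of the source volume.
#' @param slice_index 1-based axial index within the source volume.
#' @return an object of class `sample2d`.
#' @export
sample2d <- function(image, mask, volume_id = "sample", slice_index = 1L) {
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1L))
  if (length(dim(image)) != 3) stop_acunet("image must be (y, x, channel)")
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop_acunet("image and mask spatial shapes differ")
  }
  check_labels(mask)
  storage.mode(mask) <- "integer"
  structure(list(image = image, mask = mask,
                 volume_id = as.character(volume_id),
                 slice_index = as.integer(slice_index)),
            class = "sample2d")
}

#' @export
print.sample2d <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("sample2d %s[%d]: %d x %d px, %d channel(s), %d tumor px\n",
              x$volume_id, x$slice_index, d[1], d[2], d[3], sum(x$mask > 0)))
  invisible(x)
}

#' Decompose a volume into axial 2D samples
#'
#' Slices a co-registered image/label volume pair along the axial (first
#' spatial) axis into `sample2d` objects in ascending slice order.
#'
#' @param vol an [mm_volume()].
#' @param lab a matching `label_volume`.
#' @param keep_empty if `FALSE`, slices whose label plane is all background
#'   are dropped.
#' @param volume_id id recorded in each sample's provenance.
#' @return list of `sample2d`.
#' @export
extract_slices <- function(vol, lab, keep_empty = TRUE, volume_id = "vol") {
  if (!identical(dim(vol$data)[1:3], dim(lab$data))) {
    stop_acunet("volume and label shapes differ")
  }
  nz <- dim(vol$data)[1]
  out <- vector("list", nz)
  keep <- logical(nz)
  for (z in seq_len(nz)) {
    m <- lab$data[z, , ]
    if (!keep_empty && all(m == 0L)) next
    img <- vol$data[z, , , , drop = FALSE]
    img <- array(img, dim(img)[2:4])
    out[[z]] <- sample2d(img, m, volume_id = volume_id, slice_index = z)
    keep[z] <- TRUE
  }
  out[keep]
}

#' Standardize slice intensities
#'
#' Per-channel intensity standardization of a `(y, x, channel)` image grid:
#' `"zscore"` maps each channel to mean 0, sd 1 over the whole slice
#' (constant channels map to all zeros); `"minmax"` maps each channel into
#' `[0, 1]` (constant channels map to 0).
#'
#' @param image numeric array `(y, x, channel)` (a plain matrix is treated
#'   as one channel).
#' @param mode `"zscore"` or `"minmax"`.
#' @return array of the same shape.
#' @export
normalize_intensity <- function(image, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  was_matrix <- length(dim(image)) == 2 || is.null(dim(image))
  if (is.null(dim(image))) image <- matrix(image, nrow = 1)
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1L))
  if (!all(is.finite(image))) stop_acunet("image must be finite-valued")
  out <- image
  for (c in seq_len(dim(image)[3])) {
    v <- image[, , c]
    if (mode == "zscore") {
      s <- sd(v)
      out[, , c] <- if (s == 0) 0 else (v - mean(v)) / s
    } else {
      r <- range(v)
      out[, , c] <- if (r[1] == r[2]) 0 else (v - r[1]) / (r[2] - r[1])
    }
  }
  if (was_matrix) out[, , 1] else out
}

# nearest-neighbour index map; identity when n_out == n_in
nn_index <- function(n_in, n_out) {
  pmin(n_in, floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L)
}

# separable bilinear interpolation of a matrix to a target shape
bilinear_resize <- function(m, target) {
  hi <- nrow(m); wi <- ncol(m)
  ho <- target[1]; wo <- target[2]
  # sample at pixel centres of the output grid mapped into input coordinates
  yc <- (seq_len(ho) - 0.5) * hi / ho + 0.5
  xc <- (seq_len(wo) - 0.5) * wi / wo + 0.5
  y0 <- pmin(pmax(floor(yc), 1L), hi); y1 <- pmin(y0 + 1L, hi)
  x0 <- pmin(pmax(floor(xc), 1L), wi); x1 <- pmin(x0 + 1L, wi)
  wy <- pmin(pmax(yc - y0, 0), 1); wx <- pmin(pmax(xc - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * ((1 - wy) %o% (1 - wx)) +
    m[y1, x0, drop = FALSE] * (wy %o% (1 - wx)) +
    m[y0, x1, drop = FALSE] * ((1 - wy) %o% wx) +
    m[y1, x1, drop = FALSE] * (wy %o% wx)
  a
}

#' Resample a slice and its mask to a target shape
#'
#' Images are interpolated bilinearly; masks use nearest-neighbour indexing
#' so the label set is preserved (and resampling to the input's own shape is
#' an exact identity).
#'
#' @param image numeric array `(y, x, channel)` or matrix.
#' @param mask integer matrix `(y, x)`, or `NULL`.
#' @param target_shape integer pair `(height, width)`.
#' @return list with `image` and `mask` at the target shape.
#' @export
resample_to <- function(image, mask, target_shape) {
  if (length(target_shape) != 2 || any(target_shape < 1) ||
      any(target_shape != as.integer(target_shape))) {
    stop_acunet("target_shape must be two positive integers")
  }
  target_shape <- as.integer(target_shape)
  was_matrix <- length(dim(image)) == 2
  if (was_matrix) image <- array(image, c(dim(image), 1L))
  nc <- dim(image)[3]
  out <- array(0, c(target_shape, nc))
  for (c in seq_len(nc)) out[, , c] <- bilinear_resize(image[, , c], target_shape)
  m <- NULL
  if (!is.null(mask)) {
    iy <- nn_index(nrow(mask), target_shape[1])
    ix <- nn_index(ncol(mask), target_shape[2])
    m <- mask[iy, ix, drop = FALSE]
    storage.mode(m) <- "integer"
  }
  list(image = if (was_matrix) out[, , 1] else out, mask = m)
}

#' Derive nested BraTS evaluation regions from a label map
#'
#' Maps BraTS-convention labels (1 = necrotic/non-enhancing core, 2 = edema,
#' 4 = enhancing tumor) to the nested evaluation regions: whole tumor
#' WT = \{1, 2, 4\}, tumor core TC = \{1, 4\}, enhancing tumor ET = \{4\}.
#' By construction ET is a subset of TC is a subset of WT.
#'
#' @param labels integer grid (2D or 3D) with values in \{0, 1, 2, 4\}.
#' @return list of logical grids `wt`, `tc`, `et` shaped like `labels`.
#' @export
derive_regions <- function(labels) {
  check_labels(labels)
  list(wt = labels == 1L | labels == 2L | labels == 4L,
       tc = labels == 1L | labels == 4L,
       et = labels == 4L)
}

#' Paired geometric augmentation of a 2D sample
#'
#' Applies the identical geometric transform to image and mask. Flips and
#' right-angle rotations are exact (mask foreground counts preserved);
#' scaling resamples (bilinear image / nearest mask) and re-crops or pads
#' centrally back to the original shape so batch shapes stay fixed.
#'
#' @param sample a [sample2d()].
#' @param op one of `"hflip"`, `"vflip"`, `"rotate90"`, `"scale"`.
#' @param k number of 90-degree counter-clockwise quarter turns (`rotate90`).
#' @param f strictly positive zoom factor (`scale`).
#' @return the transformed `sample2d`.
#' @export
augment_sample <- function(sample, op = c("hflip", "vflip", "rotate90", "scale"),
                           k = 1L, f = 1.0) {
  op <- match.arg(op)
  img <- sample$image
  msk <- sample$mask
  flip_cols <- function(a) a[, rev(seq_len(ncol(a))), , drop = FALSE]
  flip_rows <- function(a) a[rev(seq_len(nrow(a))), , , drop = FALSE]
  if (op == "hflip") {
    img <- flip_cols(img)
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  } else if (op == "vflip") {
    img <- flip_rows(img)
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  } else if (op == "rotate90") {
    k <- as.integer(k) %% 4L
    rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    for (i in seq_len(k)) {
      msk <- rot1(msk)
      img2 <- array(0, c(dim(msk), dim(img)[3]))
      for (c in seq_len(dim(img)[3])) img2[, , c] <- rot1(img[, , c])
      img <- img2
    }
  } else { # scale
    if (!is.finite(f) || f <= 0) stop_acunet("scale factor must be > 0")
    orig <- dim(msk)
    zoomed <- pmax(1L, as.integer(round(orig * f)))
    rs <- resample_to(img, msk, zoomed)
    img <- center_fit(rs$image, orig)
    msk <- center_fit_mask(rs$mask, orig)
  }
  sample2d(img, msk, volume_id = sample$volume_id, slice_index = sample$slice_index)
}

# centre-crop or zero-pad an array (y, x, c) to a target spatial shape
center_fit <- function(a, target) {
  out <- array(0, c(target, dim(a)[3]))
  copy_center(dim(a)[1:2], target, function(src_y, src_x, dst_y, dst_x) {
    out[dst_y, dst_x, ] <<- a[src_y, src_x, , drop = FALSE]
  })
  out
}

center_fit_mask <- function(m, target) {
  out <- matrix(0L, target[1], target[2])
  copy_center(dim(m), target, function(src_y, src_x, dst_y, dst_x) {
    out[dst_y, dst_x] <<- m[src_y, src_x, drop = FALSE]
  })
  out
}

copy_center <- function(src, dst, assign_fun) {
  n <- pmin(src, dst)
  s0 <- (src - n) %/% 2L
  d0 <- (dst - n) %/% 2L
  assign_fun(s0[1] + seq_len(n[1]), s0[2] + seq_len(n[2]),
             d0[1] + seq_len(n[1]), d0[2] + seq_len(n[2]))
}
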