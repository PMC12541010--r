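#' Specification of the synthetic multi-modal phantom generator
#'
#' The generator emulates BraTS-style 2D axial inputs: four co-registered
#' modality channels over a smooth low-frequency bias field with additive
#' Gaussian noise, and (with probability `tumor_probability`) three
#' concentric random ellipses forming nested tumor subregions written into
#' the mask as labels 2 (edema, WT minus TC), 1 (necrotic core, TC minus ET)
#' and 4 (enhancing tumor, ET).
#'
#' `contrast_table` has one row per channel and columns
#' `edema`/`core`/`enhancing`: the mean intensity offset added to a pixel
#' whose finest region is that column. The default makes channel 1
#' (FLAIR-like) bright across the whole tumor — so WT is approximately
#' recoverable by a threshold on channel 1 — and channel 3 (T1CE-like)
#' bright in the enhancing core.
#'
#' @param n_samples number of phantoms.
#' @param shape pixel grid `(height, width)`.
#' @param n_channels number of modality channels.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param bias_amplitude amplitude of the smooth bias field.
#' @param base_level per-channel background intensity.
#' @param wt_radius_range range (pixels) of the whole-tumor ellipse semi-axes.
#' @param tc_fraction_range range of the TC/WT axis shrink factor, in (0, 1].
#' @param et_fraction_range range of the ET/TC axis shrink factor, in (0, 1].
#' @param tumor_probability fraction of samples containing a tumor.
#' @param contrast_table `n_channels x 3` matrix of region intensity offsets.
#' @param spacing voxel spacing (z, y, x) in mm recorded in generated files.
#' @param seed integer master seed; all randomness derives from it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_samples = 100,
                         shape = c(64, 64),
                         n_channels = 4,
                         noise_sigma = 0.05,
                         bias_amplitude = 0.05,
                         base_level = c(0.20, 0.25, 0.20, 0.30),
                         wt_radius_range = c(8, 16),
                         tc_fraction_range = c(0.5, 0.8),
                         et_fraction_range = c(0.4, 0.7),
                         tumor_probability = 1.0,
                         contrast_table = NULL,
                         spacing = c(1, 1, 1),
                         seed = 1L) {
  if (!is_count(n_samples)) stop_acunet("n_samples must be a positive count")
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 8)) stop_acunet("shape must be >= 8x8")
  if (noise_sigma < 0) stop_acunet("noise_sigma must be >= 0")
  if (bias_amplitude < 0) stop_acunet("bias_amplitude must be >= 0")
  chk_frac <- function(r, nm) {
    if (length(r) != 2 || any(r <= 0) || any(r > 1) || r[1] > r[2]) {
      stop_acunet(nm, " must be an increasing range within (0, 1]")
    }
  }
  chk_frac(tc_fraction_range, "tc_fraction_range")
  chk_frac(et_fraction_range, "et_fraction_range")
  if (tumor_probability < 0 || tumor_probability > 1) {
    stop_acunet("tumor_probability must be in [0, 1]")
  }
  if (length(wt_radius_range) != 2 || wt_radius_range[1] <= 0 ||
      wt_radius_range[1] > wt_radius_range[2]) {
    stop_acunet("wt_radius_range must be an increasing positive range")
  }
  if (2 * wt_radius_range[2] + 2 > min(shape)) {
    stop_acunet("tumor geometry cannot fit: 2 * max radius + margin exceeds the grid")
  }
  base_level <- rep_len(base_level, n_channels)
  if (is.null(contrast_table)) {
    tmpl <- rbind(c(0.80, 0.80, 0.80),   # FLAIR-like: bright across WT
                  c(0.10, 0.35, 0.20),   # T1-like
                  c(0.10, 0.25, 0.90),   # T1CE-like: bright in ET
                  c(0.50, 0.25, 0.40))   # T2-like
    contrast_table <- tmpl[rep_len(seq_len(4), n_channels), , drop = FALSE]
  }
  contrast_table <- as.matrix(contrast_table)
  if (!identical(dim(contrast_table), c(as.integer(n_channels), 3L)) &&
      !identical(dim(contrast_table), c(n_channels, 3L))) {
    stop_acunet("contrast_table must be n_channels x 3 (edema, core, enhancing)")
  }
  colnames(contrast_table) <- c("edema", "core", "enhancing")
  structure(list(n_samples = as.integer(n_samples), shape = shape,
                 n_channels = as.integer(n_channels),
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 base_level = base_level,
                 wt_radius_range = wt_radius_range,
                 tc_fraction_range = tc_fraction_range,
                 et_fraction_range = et_fraction_range,
                 tumor_probability = tumor_probability,
                 contrast_table = contrast_table,
                 spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %d samples, %dx%d px, %d channels, seed %d\n",
              x$n_samples, x$shape[1], x$shape[2], x$n_channels, x$seed))
  cat(sprintf("  noise sd %.3g, bias %.3g, tumor probability %.2f\n",
              x$noise_sigma, x$bias_amplitude, x$tumor_probability))
  cat(sprintf("  WT semi-axes %g-%g px, TC fraction %g-%g, ET fraction %g-%g\n",
              x$wt_radius_range[1], x$wt_radius_range[2],
              x$tc_fraction_range[1], x$tc_fraction_range[2],
              x$et_fraction_range[1], x$et_fraction_range[2]))
  invisible(x)
}

# rasterize an ellipse: inside test at pixel centres
ellipse_mask <- function(shape, cy, cx, a, b, theta) {
  y <- seq_len(shape[1]) - cy
  x <- seq_len(shape[2]) - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(y, x, function(yy, xx) (xx * ct + yy * st) / a)
  v <- outer(y, x, function(yy, xx) (-xx * st + yy * ct) / b)
  u^2 + v^2 <= 1
}

# draw one phantom with the current RNG state
draw_phantom <- function(spec, id, index) {
  h <- spec$shape[1]; w <- spec$shape[2]
  mask <- matrix(0L, h, w)
  has_tumor <- runif(1) < spec$tumor_probability
  if (has_tumor) {
    a1 <- runif(1, spec$wt_radius_range[1], spec$wt_radius_range[2])
    b1 <- runif(1, spec$wt_radius_range[1], spec$wt_radius_range[2])
    theta <- runif(1, 0, pi)
    rmax <- max(a1, b1)
    cy <- runif(1, rmax + 1, h - rmax - 1)
    cx <- runif(1, rmax + 1, w - rmax - 1)
    ftc <- runif(1, spec$tc_fraction_range[1], spec$tc_fraction_range[2])
    fet <- runif(1, spec$et_fraction_range[1], spec$et_fraction_range[2])
    wt <- ellipse_mask(spec$shape, cy, cx, a1, b1, theta)
    tc <- ellipse_mask(spec$shape, cy, cx, pmax(1, a1 * ftc), pmax(1, b1 * ftc), theta)
    et <- ellipse_mask(spec$shape, cy, cx, pmax(1, a1 * ftc * fet),
                       pmax(1, b1 * ftc * fet), theta)
    mask[wt] <- 2L
    mask[tc] <- 1L
    mask[et] <- 4L
  }
  img <- array(0, c(h, w, spec$n_channels))
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  for (c in seq_len(spec$n_channels)) {
    fy <- runif(1, 0.5, 1.5); fx <- runif(1, 0.5, 1.5); ph <- runif(1, 0, 2 * pi)
    bias <- spec$bias_amplitude * sin(2 * pi * (fy * yy + fx * xx) + ph)
    ch <- spec$base_level[c] + bias
    ch[mask == 2L] <- ch[mask == 2L] + spec$contrast_table[c, "edema"]
    ch[mask == 1L] <- ch[mask == 1L] + spec$contrast_table[c, "core"]
    ch[mask == 4L] <- ch[mask == 4L] + spec$contrast_table[c, "enhancing"]
    if (spec$noise_sigma > 0) ch <- ch + rnorm(h * w, 0, spec$noise_sigma)
    img[, , c] <- ch
  }
  sample2d(img, mask, volume_id = id, slice_index = index)
}

#' Generate a single phantom sample
#'
#' Deterministic in `(spec, seed)`: the same pair always yields a
#' bit-identical sample.
#'
#' @param spec a [phantom_spec()].
#' @param seed seed for this draw (defaults to `spec$seed`).
#' @param id,index provenance recorded in the sample.
#' @return a [sample2d()].
#' @export
generate_phantom <- function(spec, seed = spec$seed, id = "phantom", index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, draw_phantom(spec, id, index))
}

#' Generate an in-memory phantom dataset
#'
#' Draws `spec$n_samples` phantoms, each from its own sub-seed derived from
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list of [sample2d()] objects.
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  seeds <- derive_seeds(spec$seed, spec$n_samples)
  lapply(seq_len(spec$n_samples), function(i) {
    generate_phantom(spec, seed = seeds[i],
                     id = sprintf("phantom_%03d", i), index = 1L)
  })
}

#' Write a phantom dataset to disk
#'
#' Writes each phantom as a single-slice NIfTI image/label pair, a CSV slice
#' index (volume id, slice index, foreground pixel count) and a JSON
#' manifest in the layout [load_dataset()] consumes.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @return path of the written manifest JSON.
#' @export
generate_phantom_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_acunet("cannot create output directory: ", out_dir)
  samples <- generate_phantoms(spec)
  entries <- vector("list", length(samples))
  idx <- data.frame(volume_id = character(0), slice_index = integer(0),
                    foreground_px = integer(0))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img_path <- sprintf("img_%03d.nii.gz", i)
    lab_path <- sprintf("lab_%03d.nii.gz", i)
    vol <- mm_volume(array(s$image, c(1L, dim(s$image))), spacing = spec$spacing)
    lab <- label_volume(array(s$mask, c(1L, dim(s$mask))), spacing = spec$spacing)
    write_volume(vol, file.path(out_dir, img_path))
    write_volume(lab, file.path(out_dir, lab_path))
    entries[[i]] <- list(id = s$volume_id, image = img_path, label = lab_path)
    idx <- rbind(idx, data.frame(volume_id = s$volume_id, slice_index = 1L,
                                 foreground_px = sum(s$mask > 0L)))
  }
  write.csv(idx, file.path(out_dir, "slices.csv"), row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
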