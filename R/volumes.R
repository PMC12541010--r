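#' Multi-modal MRI volumes and label volumes
#'
#' A `mm_volume` holds a 4D intensity grid indexed `(z, y, x, channel)` with
#' per-axis voxel spacing in mm; a `label_volume` holds a 3D integer grid of
#' BraTS-convention labels. Axial slicing runs along the first spatial axis.
#'
#' @param data numeric array; `(z, y, x, channel)` for intensity volumes,
#'   `(z, y, x)` for label volumes.
#' @param spacing positive numeric vector of length 3, voxel size in mm along
#'   `(z, y, x)`.
#' @param channels optional character vector of modality names, one per
#'   channel (defaults to `FLAIR`, `T1`, `T1CE`, `T2` for 4 channels).
#' @return an object of class `mm_volume` or `label_volume`.
#' @examples
#' v <- mm_volume(array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4)), c(1, 1, 1))
#' dim(v$data)
#' @export
mm_volume <- function(data, spacing = c(1, 1, 1), channels = NULL) {
  if (!is.array(data) || length(dim(data)) != 4) {
    stop_acunet("intensity volume must be a 4D (z, y, x, channel) array")
  }
  if (!all(is.finite(data))) stop_acunet("volume intensities must be finite")
  check_spacing(spacing)
  nc <- dim(data)[4]
  if (is.null(channels)) {
    channels <- if (nc == 4) c("FLAIR", "T1", "T1CE", "T2") else paste0("ch", seq_len(nc))
  }
  if (length(channels) != nc) stop_acunet("one channel name per channel required")
  structure(list(data = data, spacing = as.numeric(spacing), channels = channels),
            class = "mm_volume")
}

#' @rdname mm_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_acunet("label volume must be a 3D (z, y, x) array")
  }
  check_spacing(spacing)
  check_labels(data)
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing)), class = "label_volume")
}

BRATS_LABELS <- c(0L, 1L, 2L, 4L)

check_labels <- function(x) {
  bad <- setdiff(unique(as.integer(x)), BRATS_LABELS)
  if (length(bad) > 0) {
    stop_acunet("invalid label value(s) ", paste(bad, collapse = ", "),
                "; allowed labels are {0, 1, 2, 4}",
                class = "acunet_label_error")
  }
  invisible(TRUE)
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_acunet("spacing must be 3 strictly positive values (z, y, x) in mm")
  }
  invisible(TRUE)
}

#' @export
print.mm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-modal volume: %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  cat(sprintf("Voxel spacing (z, y, x): %s mm\n", paste(x$spacing, collapse = " x ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tab <- table(factor(x$data, levels = BRATS_LABELS))
  cat(sprintf("Label volume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat("Label counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a NIfTI volume or label map
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed). 4D files become
#' [mm_volume()] objects; 3D files are returned as `label_volume` when
#' `kind = "label"` (values validated against the BraTS label set
#' \{0, 1, 2, 4\}) or as a single-channel `mm_volume` when `kind = "image"`.
#' Voxel spacing is taken from the header `pixdim`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"auto"` (4D -> image, 3D -> image), `"image"` or `"label"`.
#' @return an `mm_volume` or `label_volume`.
#' @seealso [write_volume()], [extract_slices()]
#' @export
read_volume <- function(path, kind = c("auto", "image", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_acunet("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dm <- dim(arr)
  attributes(arr) <- NULL
  dim(arr) <- dm
  pd <- RNifti::pixdim(img)
  nd <- length(dim(arr))
  if (nd == 4) {
    if (kind == "label") stop_acunet("label volumes must be 3D: ", path)
    return(mm_volume(arr, spacing = pd[1:3]))
  }
  if (nd != 3) stop_acunet("expected a 3D or 4D NIfTI volume, got ", nd, "D: ", path)
  if (kind == "label") {
    return(label_volume(arr, spacing = pd[1:3]))
  }
  mm_volume(array(arr, c(dim(arr), 1L)), spacing = pd[1:3])
}

#' Write a volume to NIfTI
#'
#' @param vol an `mm_volume` or `label_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "mm_volume")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- c(vol$spacing, 1)
    RNifti::writeNifti(img, path)
  } else if (inherits(vol, "label_volume")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    stop_acunet("vol must be an mm_volume or label_volume")
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a JSON file with one record per volume: `id`, `image` (path
#' to a 4D NIfTI, or a named list of per-modality 3D NIfTI paths) and
#' `label` (path to a 3D label NIfTI). Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest JSON path.
#' @return list with elements `entries` (list of records with resolved
#'   paths) and `dir`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_acunet("manifest not found: ", path)
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(dir, p)
  entries <- lapply(entries, function(e) {
    e$image <- if (is.character(e$image) || length(e$image) == 1) {
      resolve(as.character(e$image))
    } else {
      vapply(e$image, resolve, character(1))
    }
    e$label <- resolve(as.character(e$label))
    e
  })
  list(entries = entries, dir = dir)
}

#' Load all samples referenced by a manifest
#'
#' Reads every volume/label pair in a manifest and decomposes it into 2D
#' axial samples via [extract_slices()].
#'
#' @param path manifest JSON path.
#' @param keep_empty keep slices whose mask is all background?
#' @return list of `sample2d` objects.
#' @export
load_dataset <- function(path, keep_empty = TRUE) {
  man <- read_manifest(path)
  out <- list()
  for (e in man$entries) {
    vol <- if (length(e$image) == 1) {
      read_volume(e$image, kind = "image")
    } else {
      mods <- lapply(e$image, read_volume, kind = "image")
      stack_modalities(mods, names(e$image))
    }
    lab <- read_volume(e$label, kind = "label")
    out <- c(out, extract_slices(vol, lab, keep_empty = keep_empty,
                                 volume_id = e$id %||% basename(e$label)))
  }
  out
}

# combine single-channel volumes into one multi-modal volume
stack_modalities <- function(vols, names = NULL) {
  d <- dim(vols[[1]]$data)[1:3]
  for (v in vols) {
    if (!identical(dim(v$data)[1:3], d)) stop_acunet("modalities differ in shape")
  }
  arr <- array(0, c(d, length(vols)))
  for (i in seq_along(vols)) arr[, , , i] <- vols[[i]]$data[, , , 1]
  mm_volume(arr, spacing = vols[[1]]$spacing, channels = names)
}
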