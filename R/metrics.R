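#' Confusion counts of two binary masks
#'
#' Exhaustive per-pixel tally of true/false positives/negatives.
#'
#' @param pred,gt binary (logical or 0/1) grids of equal shape.
#' @return list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt))) {
    stop_acunet("pred and gt shapes differ")
  }
  if (!is.logical(pred) && !all(pred %in% c(0, 1))) {
    stop_acunet("pred mask must be binary")
  }
  if (!is.logical(gt) && !all(gt %in% c(0, 1))) {
    stop_acunet("gt mask must be binary")
  }
  p <- as.logical(pred)
  g <- as.logical(gt)
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

#' Overlap metrics from confusion counts
#'
#' Dice `2tp/(2tp+fp+fn)`, Jaccard `tp/(tp+fp+fn)`, precision `tp/(tp+fp)`,
#' recall/sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and F1 (the
#' harmonic mean of precision and recall, which equals Dice on binary
#' masks). Conventions for empty masks: if both masks are empty
#' (`tp+fp+fn == 0`) all overlap ratios are 1 (perfect agreement); any other
#' 0/0 ratio is 0, except specificity which is 1 when there are no true
#' negatives or false positives to misclassify.
#'
#' @param counts a list as returned by [confusion_counts()].
#' @return named list of metrics, each in `[0, 1]`.
#' @export
overlap_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop_acunet("counts must be nonnegative")
  ratio <- function(num, den, empty = 0) if (den == 0) empty else num / den
  if (tp + fp + fn == 0) {
    dice <- jaccard <- precision <- recall <- 1
  } else {
    dice <- ratio(2 * tp, 2 * tp + fp + fn)
    jaccard <- ratio(tp, tp + fp + fn)
    precision <- ratio(tp, tp + fp)
    recall <- ratio(tp, tp + fn)
  }
  specificity <- ratio(tn, tn + fp, empty = 1)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  if (tp + fp + fn == 0) f1 <- 1
  list(dice = dice, jaccard = jaccard, precision = precision,
       recall = recall, sensitivity = recall, specificity = specificity,
       f1 = f1)
}

#' Dice coefficient of two binary masks
#'
#' Convenience wrapper: [confusion_counts()] followed by the Dice entry of
#' [overlap_metrics()].
#'
#' @inheritParams confusion_counts
#' @return scalar Dice in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt) {
  overlap_metrics(confusion_counts(pred, gt))$dice
}

# boundary pixels: foreground with at least one background 4-neighbour
# (outside the image counts as background). Returns an n x 2 matrix of
# (row, col) indices.
boundary_pixels <- function(mask) {
  m <- as.logical(mask)
  dim(m) <- dim(mask)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  inner <- pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)]
  which(m & !inner, arr.ind = TRUE)
}

# all nearest-neighbour distances from points a to set b (mm)
directed_distances <- function(a, b, spacing) {
  if (nrow(a) == 0) return(numeric(0))
  ay <- a[, 1] * spacing[1]; ax <- a[, 2] * spacing[2]
  by <- b[, 1] * spacing[1]; bx <- b[, 2] * spacing[2]
  d2 <- outer(ay, by, "-")^2 + outer(ax, bx, "-")^2
  sqrt(apply(d2, 1, min))
}

surface_distance_sets <- function(pred, gt, spacing) {
  if (!identical(dim(pred), dim(gt))) stop_acunet("pred and gt shapes differ")
  pe <- !any(as.logical(pred))
  ge <- !any(as.logical(gt))
  if (pe && ge) return(list(status = "both_empty"))
  if (pe || ge) return(list(status = "undefined"))
  bp <- boundary_pixels(pred)
  bg <- boundary_pixels(gt)
  list(status = "ok",
       d_pred_gt = directed_distances(bp, bg, spacing),
       d_gt_pred = directed_distances(bg, bp, spacing))
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' Boundary pixels (foreground with a background 4-neighbour) are extracted
#' from both masks; HD95 is the maximum of the two directed 95th-percentile
#' nearest-boundary distances, in mm (Euclidean, scaled by `spacing`).
#' Percentiles use linear interpolation. Both masks empty gives 0; exactly
#' one empty gives `NA` with attribute `undefined = TRUE` (excluded from
#' aggregate means).
#'
#' @param pred,gt binary grids of equal shape.
#' @param spacing per-axis pixel size in mm, `(y, x)`.
#' @return HD95 in mm, or flagged `NA`.
#' @export
hd95 <- function(pred, gt, spacing = c(1, 1)) {
  s <- surface_distance_sets(pred, gt, spacing)
  if (s$status == "both_empty") return(0)
  if (s$status == "undefined") return(structure(NA_real_, undefined = TRUE))
  max(quantile(s$d_pred_gt, 0.95, names = FALSE, type = 7),
      quantile(s$d_gt_pred, 0.95, names = FALSE, type = 7))
}

#' Average symmetric surface distance (ASSD)
#'
#' Mean of all boundary-point-to-nearest-boundary distances taken in both
#' directions, in mm. Empty-mask conventions as in [hd95()].
#'
#' @inheritParams hd95
#' @return ASSD in mm, or flagged `NA`.
#' @export
assd <- function(pred, gt, spacing = c(1, 1)) {
  s <- surface_distance_sets(pred, gt, spacing)
  if (s$status == "both_empty") return(0)
  if (s$status == "undefined") return(structure(NA_real_, undefined = TRUE))
  (sum(s$d_pred_gt) + sum(s$d_gt_pred)) /
    (length(s$d_pred_gt) + length(s$d_gt_pred))
}

METRIC_COLUMNS <- c("dice", "jaccard", "sensitivity", "specificity",
                    "precision", "f1", "hd95_mm", "assd_mm")

#' Region-wise evaluation report
#'
#' Derives the nested WT/TC/ET regions from predicted and ground-truth label
#' maps ([derive_regions()]) and computes, per region, all overlap metrics
#' plus HD95 and ASSD, with an `Average` row of arithmetic means over the
#' three regions. Undefined surface distances (exactly one empty mask) are
#' excluded from the averages; the number excluded is recorded in the
#' attribute `n_undefined`.
#'
#' @param pred_labels,gt_labels integer grids with values in \{0, 1, 2, 4\}.
#' @param spacing per-axis pixel size in mm `(y, x)`.
#' @return a `metric_report`: data.frame with rows WT, TC, ET, Average.
#' @export
evaluate_regions <- function(pred_labels, gt_labels, spacing = c(1, 1)) {
  rp <- derive_regions(pred_labels)
  rg <- derive_regions(gt_labels)
  rows <- lapply(c(wt = "wt", tc = "tc", et = "et"), function(r) {
    om <- overlap_metrics(confusion_counts(rp[[r]], rg[[r]]))
    c(dice = om$dice, jaccard = om$jaccard, sensitivity = om$sensitivity,
      specificity = om$specificity, precision = om$precision, f1 = om$f1,
      hd95_mm = as.numeric(hd95(rp[[r]], rg[[r]], spacing)),
      assd_mm = as.numeric(assd(rp[[r]], rg[[r]], spacing)))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- c("WT", "TC", "ET")
  n_undef <- sum(is.na(tab$hd95_mm))
  avg <- colMeans(tab, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  tab <- rbind(tab, Average = avg)
  structure(tab, class = c("metric_report", "data.frame"),
            n_undefined = n_undef)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Region-wise segmentation metrics\n")
  print.data.frame(round(as.data.frame(x), 4))
  nu <- attr(x, "n_undefined")
  if (!is.null(nu) && nu > 0) {
    cat(sprintf("(%d undefined surface distance(s) excluded from averages)\n", nu))
  }
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report a `metric_report`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  df <- cbind(region = rownames(report), as.data.frame(report))
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}

# mean region dice of a model over a sample list (both-empty convention 1)
mean_region_dice <- function(model, samples) {
  acc <- c(wt = 0, tc = 0, et = 0)
  for (s in samples) {
    pred <- predict.acunet_model(model, s)[[1]]
    rp <- derive_regions(pred)
    rg <- derive_regions(s$mask)
    for (r in names(acc)) {
      acc[[r]] <- acc[[r]] + dice_coefficient(rp[[r]], rg[[r]])
    }
  }
  acc / length(samples)
}
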