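#' Seeded k-fold split
#'
#' Partitions `1:n` into `k` folds of near-equal size (differing by at most
#' one) by a seeded permutation.
#'
#' @param n number of samples.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed permutation seed.
#' @return integer vector of fold ids (1..k), one per sample index.
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (!is_count(n)) stop_acunet("n must be a positive count")
  if (!is_count(k) || k < 2 || k > n) stop_acunet("k must satisfy 2 <= k <= n")
  perm <- with_seed(seed, sample(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  fold
}

#' k-fold cross-validation
#'
#' For each fold, trains a fresh model on the remaining folds and evaluates
#' mean WT/TC/ET dice on the held-out fold; the `Average` row is the
#' arithmetic mean over folds.
#'
#' @param samples list of [sample2d()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; its seed also drives the fold split.
#' @param k number of folds.
#' @param verbose print progress?
#' @return object of class `cv_result`: list with `table` (fold x dice
#'   data.frame including the Average row), `folds` (per-fold dice vectors)
#'   and `assignment`.
#' @export
cross_validate <- function(samples, model_cfg = model_config(),
                           train_cfg = train_config(), k = 5, verbose = FALSE) {
  fold <- kfold_split(length(samples), k, seed = train_cfg$seed)
  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- samples[fold != i]
    va <- samples[fold == i]
    fit <- acunet_train(tr, model = model_cfg, train = train_cfg,
                        val_samples = va, verbose = FALSE)
    per_fold[[i]] <- evaluate_fit(fit, va)
    if (verbose) {
      message(sprintf("fold %d/%d dice wt/tc/et = %.3f/%.3f/%.3f", i, k,
                      per_fold[[i]][["wt"]], per_fold[[i]][["tc"]],
                      per_fold[[i]][["et"]]))
    }
  }
  tab <- as.data.frame(do.call(rbind, per_fold))
  colnames(tab) <- c("dice_wt", "dice_tc", "dice_et")
  rownames(tab) <- paste0("fold", seq_len(k))
  tab <- rbind(tab, Average = colMeans(tab))
  structure(list(table = tab, folds = per_fold, assignment = fold, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  print(round(x$table, 4))
  invisible(x)
}

#' Ablation harness over attention variants
#'
#' Trains each requested variant under identical conditions — same seed,
#' same train/holdout split, same preprocessing and loss — and tabulates
#' held-out WT/TC/ET dice per variant.
#'
#' @param samples list of [sample2d()].
#' @param variants character vector of [model_config()] variants (>= 2).
#' @param model_cfg base [model_config()]; its `variant` field is replaced.
#' @param train_cfg shared [train_config()].
#' @param holdout_fraction fraction of samples held out for the comparison.
#' @param verbose print progress?
#' @return object of class `ablation_table`: data.frame with one row per
#'   variant and columns `dice_wt`, `dice_tc`, `dice_et`, `mean_dice`.
#' @export
run_ablation <- function(samples, variants = c("baseline", "full"),
                         model_cfg = model_config(), train_cfg = train_config(),
                         holdout_fraction = 0.2, verbose = FALSE) {
  if (length(variants) < 2) stop_acunet("need at least 2 variants to ablate")
  bad <- setdiff(variants, c("baseline", "channel_only", "spatial_only",
                             "decoder_only", "full"))
  if (length(bad) > 0) stop_acunet("unknown variant(s): ", paste(bad, collapse = ", "))
  n_hold <- max(1L, floor(length(samples) * holdout_fraction))
  hold_idx <- with_seed(train_cfg$seed, sample(length(samples), n_hold))
  hold <- samples[hold_idx]
  train_set <- samples[-hold_idx]
  rows <- lapply(variants, function(v) {
    cfg <- model_cfg
    cfg$variant <- v
    fit <- acunet_train(train_set, model = cfg, train = train_cfg, verbose = FALSE)
    d <- evaluate_fit(fit, hold)
    if (verbose) {
      message(sprintf("variant %-13s dice wt/tc/et = %.3f/%.3f/%.3f", v,
                      d[["wt"]], d[["tc"]], d[["et"]]))
    }
    c(dice_wt = d[["wt"]], dice_tc = d[["tc"]], dice_et = d[["et"]],
      mean_dice = mean(d))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- variants
  structure(tab, class = c("ablation_table", "data.frame"))
}

#' @export
print.ablation_table <- function(x, ...) {
  cat("Ablation study (held-out dice per region)\n")
  print.data.frame(round(as.data.frame(x), 4))
  invisible(x)
}

#' Write an ablation table to CSV
#'
#' @param tab an `ablation_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ablation_table <- function(tab, path) {
  df <- cbind(variant = rownames(tab), as.data.frame(tab))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
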