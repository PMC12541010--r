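#' Training configuration
#'
#' Defaults are sized for phantom-scale runs: plain SGD with momentum 0.9,
#' learning rate 0.05 and mini-batches of 8.
#'
#' @param epochs number of passes over the training split.
#' @param batch_size mini-batch size.
#' @param learning_rate SGD step size (> 0).
#' @param momentum momentum coefficient in `[0, 1)`; 0 disables the buffer.
#' @param weights a [loss_weights()] for the combined Dice/cross-entropy
#'   objective.
#' @param seed seed driving the train/validation split, shuffling and
#'   augmentation.
#' @param augment apply random flips/right-angle rotations to training
#'   batches?
#' @param patience early-stop patience: epochs without validation-dice
#'   improvement before stopping (default: never).
#' @param val_fraction fraction held out for validation when no explicit
#'   validation set is given.
#' @param normalize per-slice intensity standardization applied to inputs:
#'   `"zscore"`, `"minmax"` or `"none"`.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 8, learning_rate = 0.05,
                         momentum = 0.9, weights = loss_weights(), seed = 1L,
                         augment = FALSE, patience = Inf, val_fraction = 0.2,
                         normalize = c("zscore", "minmax", "none")) {
  normalize <- match.arg(normalize)
  if (!is_count(epochs)) stop_acunet("epochs must be >= 1")
  if (!is_count(batch_size)) stop_acunet("batch_size must be >= 1")
  if (!is.finite(learning_rate) || learning_rate <= 0) {
    stop_acunet("learning_rate must be > 0")
  }
  if (momentum < 0 || momentum >= 1) stop_acunet("momentum must be in [0, 1)")
  stopifnot(inherits(weights, "loss_weights"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weights = weights, seed = as.integer(seed),
                 augment = isTRUE(augment), patience = patience,
                 val_fraction = val_fraction, normalize = normalize),
            class = "train_config")
}

# elementwise recursion over two parameter trees (NULL slots skipped)
map2_params <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  for (i in seq_along(a)) {
    if (!is.null(a[[i]])) a[[i]] <- map2_params(a[[i]], b[[i]], f)
  }
  a
}

map_params <- function(a, f) {
  if (is.numeric(a)) return(f(a))
  for (i in seq_along(a)) if (!is.null(a[[i]])) a[[i]] <- map_params(a[[i]], f)
  a
}

#' One SGD update
#'
#' `theta <- theta - lr * v` with velocity `v <- momentum * v + grad`
#' (plain gradient descent when `momentum = 0`). Parameters and gradients
#' are arbitrary nested lists of numeric arrays with identical structure.
#'
#' @param params,grads nested parameter and gradient lists.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param state velocity buffer from the previous call (or `NULL`).
#' @return list with updated `params` and `state`.
#' @export
sgd_step <- function(params, grads, lr, momentum = 0, state = NULL) {
  if (momentum > 0) {
    if (is.null(state)) state <- map_params(params, function(x) x * 0)
    state <- map2_params(state, grads, function(v, g) momentum * v + g)
    params <- map2_params(params, state, function(p, v) p - lr * v)
  } else {
    params <- map2_params(params, grads, function(p, g) p - lr * g)
  }
  list(params = params, state = state)
}

prep_image <- function(img, mode) {
  if (mode == "none") img else normalize_intensity(img, mode)
}

assemble_batch <- function(samples, idx, normalize) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  m <- array(0L, c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    s <- samples[[idx[j]]]
    x[, , , j] <- prep_image(s$image, normalize)
    m[, , j] <- s$mask
  }
  list(x = x, mask = m)
}

random_flip_rot <- function(s) {
  if (runif(1) < 0.5) s <- augment_sample(s, "hflip")
  if (runif(1) < 0.5) s <- augment_sample(s, "vflip")
  k <- sample(0:3, 1)
  if (k > 0) s <- augment_sample(s, "rotate90", k = k)
  s
}

#' Fit an attention U-Net
#'
#' Trains a model by mini-batch SGD on the combined Dice / cross-entropy
#' objective. The run is fully determined by `(model$seed, train$seed)` and
#' the dataset: the split, shuffling and augmentation draws all derive from
#' `train$seed`. The returned fit keeps the weights of the epoch with the
#' best mean validation region dice.
#'
#' @param samples list of [sample2d()] with identical shapes.
#' @param model a [model_config()] (built and initialized here) or an
#'   existing `acunet_model` to warm-start from.
#' @param train a [train_config()].
#' @param val_samples optional explicit validation set; otherwise
#'   `train$val_fraction` of `samples` is held out.
#' @param verbose print one line per epoch?
#' @return an object of class `acunet_fit` with elements `model` (best
#'   weights), `history` (per-epoch data.frame), `train_config`, and the
#'   validation indices.
#' @seealso [predict.acunet_fit()], [cross_validate()], [run_ablation()]
#' @export
acunet_train <- function(samples, model = model_config(), train = train_config(),
                         val_samples = NULL, verbose = FALSE) {
  if (length(samples) == 0) stop_acunet("empty dataset")
  stopifnot(inherits(train, "train_config"))
  if (inherits(model, "model_config")) model <- build_model(model)
  stopifnot(inherits(model, "acunet_model"))

  val_idx <- integer(0)
  if (is.null(val_samples)) {
    n_val <- max(1L, floor(length(samples) * train$val_fraction))
    if (n_val >= length(samples)) stop_acunet("dataset too small for a validation split")
    val_idx <- with_seed(train$seed, sample(length(samples), n_val))
    val_samples <- samples[val_idx]
    train_samples <- samples[-val_idx]
  } else {
    train_samples <- samples
  }
  val_prepped <- lapply(val_samples, function(s) {
    sample2d(prep_image(s$image, train$normalize), s$mask, s$volume_id, s$slice_index)
  })

  seeds <- derive_seeds(train$seed, train$epochs)
  state <- NULL
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_dice_wt = numeric(0), val_dice_tc = numeric(0),
                     val_dice_et = numeric(0))
  best <- list(score = -Inf, params = model$params, epoch = 0L)
  stall <- 0L
  for (ep in seq_len(train$epochs)) {
    shuffled <- with_seed(seeds[ep], {
      es <- if (train$augment) lapply(train_samples, random_flip_rot) else train_samples
      list(samples = es, order = sample(length(es)))
    })
    ep_samples <- shuffled$samples
    order_idx <- shuffled$order
    batches <- split(order_idx, ceiling(seq_along(order_idx) / train$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      ba <- assemble_batch(ep_samples, bi, train$normalize)
      fw <- forward_net(model, ba$x, keep_cache = TRUE)
      tl <- training_loss(fw$probs, onehot_labels(ba$mask), train$weights)
      if (!is.finite(tl$loss)) {
        stop_acunet("NaN/Inf loss at epoch ", ep, "; reduce the learning rate",
                    class = "acunet_divergence_error")
      }
      gz <- softmax_channels_bw(tl$gP, fw$probs)
      grads <- backward_net(model, fw$cache, gz)
      upd <- sgd_step(model$params, grads, train$learning_rate, train$momentum, state)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + tl$loss * length(bi)
    }
    ep_loss <- ep_loss / length(order_idx)
    vd <- mean_region_dice(model, val_prepped)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_dice_wt = vd[["wt"]],
                                   val_dice_tc = vd[["tc"]],
                                   val_dice_et = vd[["et"]]))
    score <- mean(vd)
    if (verbose) {
      message(sprintf("epoch %d/%d loss=%.4f val dice wt/tc/et=%.3f/%.3f/%.3f",
                      ep, train$epochs, ep_loss, vd[["wt"]], vd[["tc"]], vd[["et"]]))
    }
    if (score > best$score) {
      best <- list(score = score, params = model$params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= train$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = hist, train_config = train,
                 best_epoch = best$epoch, best_score = best$score,
                 val_idx = val_idx),
            class = "acunet_fit")
}

#' @export
print.acunet_fit <- function(x, ...) {
  cat("Fitted attention U-Net\n")
  print(x$model$config)
  cat(sprintf("  epochs run: %d (best epoch %d, mean val dice %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_score))
  invisible(x)
}

#' @export
summary.acunet_fit <- function(object, ...) {
  print(object)
  cat("\nPer-epoch history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict segmentations from a fitted model
#'
#' Applies the fit's intensity normalization, runs the network and returns
#' argmax label maps (or class probabilities).
#'
#' @param object an `acunet_fit`.
#' @param samples list of [sample2d()] (or a single one).
#' @param type `"labels"` or `"probs"`.
#' @param ... unused.
#' @return list of label matrices or probability arrays.
#' @export
predict.acunet_fit <- function(object, samples, type = c("labels", "probs"), ...) {
  type <- match.arg(type)
  if (inherits(samples, "sample2d")) samples <- list(samples)
  prepped <- lapply(samples, function(s) {
    sample2d(prep_image(s$image, object$train_config$normalize), s$mask,
             s$volume_id, s$slice_index)
  })
  predict.acunet_model(object$model, prepped, type = type)
}

#' Evaluate a fitted model on samples
#'
#' @param fit an `acunet_fit`.
#' @param samples list of [sample2d()].
#' @return named vector of mean WT/TC/ET dice over the samples.
#' @export
evaluate_fit <- function(fit, samples) {
  prepped <- lapply(samples, function(s) {
    sample2d(prep_image(s$image, fit$train_config$normalize), s$mask,
             s$volume_id, s$slice_index)
  })
  mean_region_dice(fit$model, prepped)
}

#' Plot training history
#'
#' Training loss and per-region validation dice against epoch.
#'
#' @param x an `acunet_fit`.
#' @param ... unused.
#' @export
plot.acunet_fit <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch", ylab = "training loss",
       main = "Combined Dice + CE loss", pch = 16)
  plot(h$epoch, h$val_dice_wt, type = "b", col = "firebrick", ylim = c(0, 1),
       xlab = "epoch", ylab = "validation dice", main = "Validation dice", pch = 16)
  lines(h$epoch, h$val_dice_tc, type = "b", col = "steelblue", pch = 16)
  lines(h$epoch, h$val_dice_et, type = "b", col = "darkgreen", pch = 16)
  legend("bottomright", c("WT", "TC", "ET"), bty = "n",
         col = c("firebrick", "steelblue", "darkgreen"), lty = 1, pch = 16)
  invisible(x)
}

config_fingerprint <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(js) * seq_len(nchar(js))) %% 2147483647
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the weights, the
#' architecture config (as JSON) and a fingerprint validated on load.
#'
#' @param fit an `acunet_fit` (or bare `acunet_model`).
#' @param path output path.
#' @return `path` (save) / the restored object (load).
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "acunet_fit")) fit$model else fit
  obj <- list(config = unclass(model$config),
              config_json = as.character(jsonlite::toJSON(unclass(model$config),
                                                          auto_unbox = TRUE)),
              fingerprint = config_fingerprint(model$config),
              params = model$params,
              train_config = if (inherits(fit, "acunet_fit")) unclass(fit$train_config),
              history = if (inherits(fit, "acunet_fit")) fit$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_acunet("checkpoint not found: ", path)
  obj <- readRDS(path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  if (config_fingerprint(cfg) != obj$fingerprint) {
    stop_acunet("checkpoint fingerprint mismatch: config was altered")
  }
  model <- build_model(cfg)
  model$params <- obj$params
  if (!is.null(obj$train_config)) {
    tc <- obj$train_config
    tc$weights <- do.call(loss_weights, tc$weights)
    fit <- structure(list(model = model,
                          history = obj$history,
                          train_config = do.call(train_config, tc),
                          best_epoch = NA_integer_, best_score = NA_real_,
                          val_idx = integer(0)),
                     class = "acunet_fit")
    return(fit)
  }
  model
}
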