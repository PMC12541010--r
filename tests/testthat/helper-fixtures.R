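# Shared fixtures and independent brute-force oracles used across test files.

# small phantom spec that keeps unit tests fast
tiny_phantom_spec <- function(n = 6, seed = 1, ...) {
  phantom_spec(n_samples = n, shape = c(48, 48), wt_radius_range = c(5, 9),
               seed = seed, ...)
}

micro_model_config <- function(variant = "full", gate_mode = "concat_sigmoid",
                               seed = 5) {
  model_config(depth = 2, base_width = 2, variant = variant,
               gate_mode = gate_mode, spatial_kernel = 3, seed = seed)
}

fast_train_config <- function(epochs = 2, seed = 1, ...) {
  train_config(epochs = epochs, batch_size = 4, seed = seed, ...)
}

random_binary_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# a random filled disc, guaranteed nonempty
random_disc_mask <- function(h, w) {
  r <- runif(1, 1.5, min(h, w) / 3)
  cy <- runif(1, r + 1, h - r)
  cx <- runif(1, r + 1, w - r)
  outer(seq_len(h), seq_len(w), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2) * 1L
}

# -- oracles (independent of package internals) ------------------------------

brute_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] != 0
      g <- gt[i, j] != 0
      if (p && g) tp <- tp + 1L
      else if (p && !g) fp <- fp + 1L
      else if (!p && g) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# boundary by explicit 4-neighbour inspection (outside counts as background)
brute_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 0) next
      nb <- c(if (i > 1) mask[i - 1, j] else 0,
              if (i < h) mask[i + 1, j] else 0,
              if (j > 1) mask[i, j - 1] else 0,
              if (j < w) mask[i, j + 1] else 0)
      if (any(nb == 0)) pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

# exhaustive all-pairs directed boundary distances
brute_surface_distances <- function(a_mask, b_mask, spacing) {
  a <- brute_boundary(a_mask)
  b <- brute_boundary(b_mask)
  d <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      dy <- (a[i, 1] - b[j, 1]) * spacing[1]
      dx <- (a[i, 2] - b[j, 2]) * spacing[2]
      best <- min(best, sqrt(dy^2 + dx^2))
    }
    d[i] <- best
  }
  d
}

brute_hd95 <- function(pred, gt, spacing = c(1, 1)) {
  dab <- brute_surface_distances(pred, gt, spacing)
  dba <- brute_surface_distances(gt, pred, spacing)
  max(quantile(dab, 0.95, names = FALSE, type = 7),
      quantile(dba, 0.95, names = FALSE, type = 7))
}

brute_assd <- function(pred, gt, spacing = c(1, 1)) {
  dab <- brute_surface_distances(pred, gt, spacing)
  dba <- brute_surface_distances(gt, pred, spacing)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

# -- parameter-tree helpers for gradient checks ------------------------------

flatten_params <- function(p, prefix = "") {
  if (is.numeric(p)) return(stats::setNames(list(p), prefix))
  out <- list()
  for (i in seq_along(p)) {
    nm <- if (!is.null(names(p)) && names(p)[i] != "") names(p)[i] else i
    if (!is.null(p[[i]])) {
      out <- c(out, flatten_params(p[[i]], paste0(prefix, "/", nm)))
    }
  }
  out
}

perturb_leaf <- function(params, path, i, delta) {
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  expr <- "params"
  for (pt in parts) {
    expr <- if (grepl("^[0-9]+$", pt)) {
      paste0(expr, "[[", pt, "]]")
    } else {
      paste0(expr, "[['", pt, "']]")
    }
  }
  eval(parse(text = paste0(expr, "[", i, "] <- ", expr, "[", i, "] + ", delta)))
  params
}

# central-difference check of the combined-loss gradient through a model;
# returns the worst elementwise relative error over sampled coordinates
gradient_check <- function(model, x, mask, weights = loss_weights(),
                           n_per_leaf = 4, h = 1e-5) {
  ns <- asNamespace("acunet")
  G <- ns$onehot_labels(mask)
  loss_of <- function(params) {
    mm <- model
    mm$params <- params
    ns$training_loss(ns$forward_net(mm, x)$probs, G, weights)$loss
  }
  fw <- ns$forward_net(model, x, keep_cache = TRUE)
  tl <- ns$training_loss(fw$probs, G, weights)
  grads <- ns$backward_net(model, fw$cache, ns$softmax_channels_bw(tl$gP, fw$probs))
  fp <- flatten_params(model$params)
  fg <- flatten_params(grads)
  stopifnot(identical(names(fp), names(fg)))
  worst <- 0
  for (nm in names(fp)) {
    idxs <- if (length(fp[[nm]]) > n_per_leaf) {
      sample(length(fp[[nm]]), n_per_leaf)
    } else {
      seq_along(fp[[nm]])
    }
    for (i in idxs) {
      fd <- (loss_of(perturb_leaf(model$params, nm, i, h)) -
               loss_of(perturb_leaf(model$params, nm, i, -h))) / (2 * h)
      bp <- fg[[nm]][i]
      worst <- max(worst, abs(fd - bp) / max(1e-6, abs(fd), abs(bp)))
    }
  }
  worst
}

read_file_bytes <- function(path) readBin(path, "raw", file.size(path))
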