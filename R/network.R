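#' Architecture configuration
#'
#' Hyperparameters of the attention U-Net and its ablation variants.
#' `variant` selects where attention is applied: `"baseline"` (plain U-Net,
#' no attention), `"channel_only"` / `"spatial_only"` (that single branch at
#' every encoder and decoder level), `"decoder_only"` (dual attention on
#' decoder features only) and `"full"` (dual attention at every encoder and
#' decoder level plus attention-gated skip connections). `gate_mode` picks
#' the skip-gate formulation: `"concat_sigmoid"` (per-position sigmoid on a
#' 1x1 conv over the channel concatenation of encoder and decoder features)
#' or `"qkv_softmax"` (scaled dot-product attention over flattened spatial
#' positions).
#'
#' @param in_channels input modality channels.
#' @param n_classes output classes (background + 3 tumor labels).
#' @param depth number of encoder levels (>= 2); channel widths double per
#'   level from `base_width`.
#' @param base_width channels at the first level.
#' @param variant ablation variant, see above.
#' @param gate_mode skip-gate formulation (used by `variant = "full"`).
#' @param channel_reduction bottleneck ratio r of the channel-attention MLP.
#' @param spatial_kernel odd conv kernel size of the spatial-attention branch.
#' @param seed weight-initialization seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(in_channels = 4, n_classes = 4, depth = 3,
                         base_width = 8,
                         variant = c("full", "baseline", "channel_only",
                                     "spatial_only", "decoder_only"),
                         gate_mode = c("concat_sigmoid", "qkv_softmax"),
                         channel_reduction = 8, spatial_kernel = 7,
                         seed = 1L) {
  variant <- match.arg(variant)
  gate_mode <- match.arg(gate_mode)
  if (!is_count(depth) || depth < 2) stop_acunet("depth must be >= 2")
  if (!is_count(base_width)) stop_acunet("base_width must be >= 1")
  if (!is_count(channel_reduction)) stop_acunet("channel_reduction must be >= 1")
  if (!is_count(spatial_kernel) || spatial_kernel %% 2 == 0) {
    stop_acunet("spatial_kernel must be a positive odd integer")
  }
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 depth = as.integer(depth), base_width = as.integer(base_width),
                 variant = variant, gate_mode = gate_mode,
                 channel_reduction = as.integer(channel_reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  widths <- x$base_width * 2^(seq_len(x$depth) - 1)
  cat(sprintf("acunet model config: variant '%s', gate '%s'\n", x$variant, x$gate_mode))
  cat(sprintf("  %d -> [%s] -> %d classes, depth %d, r = %d, spatial kernel %dx%d, seed %d\n",
              x$in_channels, paste(widths, collapse = ", "), x$n_classes,
              x$depth, x$channel_reduction, x$spatial_kernel, x$spatial_kernel, x$seed))
  invisible(x)
}

# where each variant places attention
variant_plan <- function(cfg) {
  switch(cfg$variant,
         baseline     = list(enc = "none", dec = "none", gate = "none"),
         channel_only = list(enc = "channel", dec = "channel", gate = "none"),
         spatial_only = list(enc = "spatial", dec = "spatial", gate = "none"),
         decoder_only = list(enc = "none", dec = "dual", gate = "none"),
         full         = list(enc = "dual", dec = "dual", gate = cfg$gate_mode))
}

he_conv <- function(kh, kw, ci, co) {
  array(rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))), c(kh, kw, ci, co))
}

he_mat <- function(rows, cols) {
  matrix(rnorm(rows * cols, 0, sqrt(2 / cols)), rows, cols)
}

block_params <- function(ci, co) {
  list(W1 = he_conv(3, 3, ci, co), b1 = numeric(co),
       W2 = he_conv(3, 3, co, co), b2 = numeric(co))
}

att_params <- function(type, C, cfg) {
  if (type == "none") return(NULL)
  ch <- function() {
    cr <- max(1L, C %/% cfg$channel_reduction)
    list(W1 = he_mat(cr, C), b1 = numeric(cr),
         W2 = he_mat(C, cr), b2 = numeric(C))
  }
  sp <- function() {
    k <- cfg$spatial_kernel
    list(W = he_conv(k, k, 2, 1), b = numeric(1))
  }
  switch(type,
         channel = ch(),
         spatial = sp(),
         dual = list(sp = sp(), ch = ch(),
                     Wf = he_conv(1, 1, C, C), bf = numeric(C)))
}

gate_params <- function(mode, ce, cd) {
  if (mode == "none") return(NULL)
  p <- list(Wg = he_conv(1, 1, ce + cd, 1), bg = numeric(1))
  if (mode == "qkv_softmax") {
    dk <- ce
    p$Wq <- he_mat(dk, cd)
    p$Wk <- he_mat(dk, ce)
  }
  p
}

# positions above which the quadratic-cost qkv gate falls back to the
# concat-sigmoid gate at that level
QKV_MAX_POSITIONS <- 1024L

#' Build an attention U-Net
#'
#' Instantiates the network of a [model_config()] with seeded He-normal
#' weight initialization. Two builds from the same config (including seed)
#' produce identical weights.
#'
#' @param cfg a [model_config()].
#' @return object of class `acunet_model` with elements `config` and
#'   `params` (nested named list of weight arrays).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  plan <- variant_plan(cfg)
  widths <- cfg$base_width * 2^(seq_len(cfg$depth) - 1)
  params <- with_seed(cfg$seed, {
    p <- list(enc = vector("list", cfg$depth),
              enc_att = vector("list", cfg$depth),
              dec = vector("list", cfg$depth - 1),
              dec_att = vector("list", cfg$depth - 1),
              gate = vector("list", cfg$depth - 1))
    for (i in seq_len(cfg$depth)) {
      ci <- if (i == 1) cfg$in_channels else widths[i - 1]
      p$enc[[i]] <- block_params(ci, widths[i])
      # single-bracket assignment keeps NULL holes without shrinking the list
      p$enc_att[i] <- list(att_params(plan$enc, widths[i], cfg))
    }
    for (i in seq_len(cfg$depth - 1)) {
      p$dec[[i]] <- c(list(Wt = he_conv(2, 2, widths[i + 1], widths[i]),
                           bt = numeric(widths[i])),
                      block_params(2 * widths[i], widths[i]))
      p$dec_att[i] <- list(att_params(plan$dec, widths[i], cfg))
      p$gate[i] <- list(gate_params(plan$gate, widths[i], widths[i]))
    }
    p$head <- list(Wo = he_conv(1, 1, widths[1], cfg$n_classes),
                   bo = numeric(cfg$n_classes))
    p
  })
  structure(list(config = cfg, params = params, plan = plan),
            class = "acunet_model")
}

#' @export
print.acunet_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model an `acunet_model` (or a bare nested parameter list).
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "acunet_model")) model$params else model
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) {
      n <<- n + length(x)
    } else if (is.list(x)) {
      for (e in x) if (!is.null(e)) walk(e)
    }
  }
  walk(p)
  n
}

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  hp <- (m - d[1] %% m) %% m
  wp <- (m - d[2] %% m) %% m
  if (hp == 0 && wp == 0) return(list(x = x, pad = c(0L, 0L)))
  out <- array(0, c(d[1] + hp, d[2] + wp, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = out, pad = c(hp, wp))
}

fw_att_dispatch <- function(type, x, p) {
  switch(type,
         none = list(y = x),
         channel = fw_channel_att(x, p),
         spatial = fw_spatial_att(x, p),
         dual = fw_dual_att(x, p))
}

bw_att_dispatch <- function(type, gy, p, cache) {
  switch(type,
         none = list(gx = gy, gp = NULL),
         channel = bw_channel_att(gy, p, cache),
         spatial = bw_spatial_att(gy, p, cache),
         dual = bw_dual_att(gy, p, cache))
}

# which gate runs at a given skip level (qkv falls back on large maps)
gate_mode_at <- function(plan, positions) {
  if (plan$gate == "qkv_softmax" && positions > QKV_MAX_POSITIONS) {
    return("concat_sigmoid")
  }
  plan$gate
}

# Full forward pass. x: (H, W, C, N). Returns per-pixel class probabilities
# and, when keep_cache, every intermediate needed by backward_net().
forward_net <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  plan <- model$plan
  p <- model$params
  if (dim(x)[3] != cfg$in_channels) {
    stop_acunet("input has ", dim(x)[3], " channels; model expects ", cfg$in_channels)
  }
  orig <- dim(x)[1:2]
  padded <- pad_to_multiple(x, 2^(cfg$depth - 1))
  x <- padded$x
  cache <- list(orig = orig, pad = padded$pad, x_dim = dim(x))
  cur <- x
  enc_feats <- vector("list", cfg$depth)
  cache$enc <- vector("list", cfg$depth)
  cache$att_e <- vector("list", cfg$depth)
  cache$pool <- vector("list", cfg$depth - 1)
  for (i in seq_len(cfg$depth)) {
    cb <- fw_block(cur, p$enc[[i]])
    ca <- fw_att_dispatch(plan$enc, cb$y, p$enc_att[[i]])
    enc_feats[[i]] <- ca$y
    if (keep_cache) {
      cache$enc[[i]] <- cb
      cache$att_e[[i]] <- ca
    }
    if (i < cfg$depth) {
      pl <- fw_pool(ca$y)
      if (keep_cache) cache$pool[[i]] <- list(arg = pl$arg, in_dim = dim(ca$y))
      cur <- pl$y
    } else {
      cur <- ca$y
    }
  }
  cache$dec <- vector("list", cfg$depth - 1)
  for (i in rev(seq_len(cfg$depth - 1))) {
    dp <- p$dec[[i]]
    up <- fw_convt(cur, dp$Wt, dp$bt)
    gmode <- gate_mode_at(plan, prod(dim(up)[1:2]))
    cg <- if (gmode == "none") {
      list(y = enc_feats[[i]])
    } else if (gmode == "concat_sigmoid") {
      fw_gate_cs(enc_feats[[i]], up, p$gate[[i]])
    } else {
      fw_gate_qkv(enc_feats[[i]], up, p$gate[[i]])
    }
    cat_in <- concat_channels(up, cg$y)
    cb <- fw_block(cat_in, dp)
    ca <- fw_att_dispatch(plan$dec, cb$y, p$dec_att[[i]])
    if (keep_cache) {
      cache$dec[[i]] <- list(x_in = cur, up = up, gmode = gmode, gate = cg,
                             cat_in = cat_in, block = cb, att = ca)
    }
    cur <- ca$y
  }
  logits <- fw_conv(cur, p$head$Wo, p$head$bo)
  probs <- softmax_channels(logits)
  if (any(padded$pad > 0)) {
    probs <- probs[seq_len(orig[1]), seq_len(orig[2]), , , drop = FALSE]
  }
  if (keep_cache) cache$pre_head <- cur
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# Backward pass from gradient wrt logits (pre-softmax, already combined with
# the softmax Jacobian by the loss). Returns nested gradients mirroring
# model$params.
backward_net <- function(model, cache, gz) {
  cfg <- model$config
  plan <- model$plan
  p <- model$params
  if (any(cache$pad > 0)) {
    full <- array(0, c(cache$x_dim[1], cache$x_dim[2], dim(gz)[3], dim(gz)[4]))
    full[seq_len(cache$orig[1]), seq_len(cache$orig[2]), , ] <- gz
    gz <- full
  }
  g <- list(enc = vector("list", cfg$depth),
            enc_att = vector("list", cfg$depth),
            dec = vector("list", cfg$depth - 1),
            dec_att = vector("list", cfg$depth - 1),
            gate = vector("list", cfg$depth - 1))
  bh <- bw_conv(cache$pre_head, p$head$Wo, gz)
  g$head <- list(Wo = bh$gw, bo = bh$gb)
  gcur <- bh$gx
  genc_extra <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth - 1)) {
    dc <- cache$dec[[i]]
    ba <- bw_att_dispatch(plan$dec, gcur, p$dec_att[[i]], dc$att)
    g$dec_att[i] <- list(ba$gp)
    bb <- bw_block(ba$gx, p$dec[[i]], dc$block)
    cu <- dim(dc$up)[3]
    gup <- bb$gx[, , seq_len(cu), , drop = FALSE]
    gskip <- bb$gx[, , cu + seq_len(dim(bb$gx)[3] - cu), , drop = FALSE]
    if (dc$gmode == "none") {
      genc_extra[[i]] <- gskip
    } else {
      bg <- if (dc$gmode == "concat_sigmoid") {
        bw_gate_cs(gskip, p$gate[[i]], dc$gate)
      } else {
        bw_gate_qkv(gskip, p$gate[[i]], dc$gate)
      }
      genc_extra[[i]] <- bg$genc
      gup <- gup + bg$gdec
      # a qkv-mode gate also carries concat-fallback weights (and vice versa
      # at levels where the fallback ran): zero-fill so the gradient tree
      # mirrors the parameter tree exactly
      gp <- bg$gp
      for (nm in names(p$gate[[i]])) {
        if (is.null(gp[[nm]])) gp[[nm]] <- p$gate[[i]][[nm]] * 0
      }
      g$gate[i] <- list(gp[names(p$gate[[i]])])
    }
    bt <- bw_convt(dc$x_in, p$dec[[i]]$Wt, gup)
    g$dec[[i]] <- c(list(Wt = bt$gw, bt = bt$gb), bb$gp)
    gcur <- bt$gx
  }
  for (i in rev(seq_len(cfg$depth))) {
    if (i < cfg$depth) {
      gat <- bw_pool(gcur, cache$pool[[i]],
                     cache$pool[[i]]$in_dim[1], cache$pool[[i]]$in_dim[2])
      gat <- gat + genc_extra[[i]]
    } else {
      gat <- gcur
    }
    ba <- bw_att_dispatch(plan$enc, gat, p$enc_att[[i]], cache$att_e[[i]])
    g$enc_att[i] <- list(ba$gp)
    bb <- bw_block(ba$gx, p$enc[[i]], cache$enc[[i]])
    g$enc[[i]] <- bb$gp
    gcur <- bb$gx
  }
  g
}

#' Run the network on one or more samples
#'
#' @param model an `acunet_model`.
#' @param images a `(y, x, channel)` array, a `(y, x, channel, n)` batch, or
#'   a [sample2d()].
#' @return per-pixel class probabilities `(y, x, n_classes, n)`; softmax over
#'   classes at every pixel.
#' @export
forward <- function(model, images) {
  if (inherits(images, "sample2d")) images <- images$image
  if (length(dim(images)) == 3) images <- array(images, c(dim(images), 1L))
  forward_net(model, images)$probs
}

# class index (1..K) -> BraTS label
CLASS_LABELS <- c(0L, 1L, 2L, 4L)

probs_to_labels <- function(probs) {
  d <- dim(probs)
  out <- array(0L, c(d[1], d[2], d[4]))
  for (n in seq_len(d[4])) {
    pm <- matrix(probs[, , 1, n], d[1], d[2])
    am <- matrix(1L, d[1], d[2])
    for (k in 2:d[3]) {
      pk <- matrix(probs[, , k, n], d[1], d[2])
      upd <- pk > pm
      pm[upd] <- pk[upd]
      am[upd] <- k
    }
    out[, , n] <- CLASS_LABELS[am]
  }
  out
}

#' Predict label maps for samples
#'
#' @param object an `acunet_model`.
#' @param samples a list of [sample2d()] (or a single one).
#' @param type `"labels"` for argmax BraTS label maps, `"probs"` for class
#'   probability arrays.
#' @param ... unused.
#' @return list (one element per sample) of label matrices or probability
#'   arrays.
#' @export
predict.acunet_model <- function(object, samples, type = c("labels", "probs"), ...) {
  type <- match.arg(type)
  if (inherits(samples, "sample2d")) samples <- list(samples)
  lapply(samples, function(s) {
    pr <- forward(object, s)
    if (type == "probs") {
      array(pr, dim(pr)[1:3])
    } else {
      probs_to_labels(pr)[, , 1]
    }
  })
}
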