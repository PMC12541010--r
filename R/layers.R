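# Layer primitives on (H, W, C, N) arrays. Every fw_* returns a list with
# the output `y` plus whatever the matching bw_* needs; bw_* consumes the
# upstream gradient and returns gradients for inputs and parameters.

sigmoid <- function(z) 1 / (1 + exp(-z))

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## -- convolution ------------------------------------------------------------

fw_conv <- function(x, W, b) cpp_conv2d_fw(x, W, b)

bw_conv <- function(x, W, gy) cpp_conv2d_bw(x, W, gy)

## -- conv block: two conv(k)+ReLU pairs, shape-preserving --------------------

fw_block <- function(x, p) {
  a1 <- fw_conv(x, p$W1, p$b1)
  a1 <- pmax(a1, 0)
  a2 <- fw_conv(a1, p$W2, p$b2)
  a2 <- pmax(a2, 0)
  list(y = a2, x = x, a1 = a1, a2 = a2)
}

bw_block <- function(gy, p, cache) {
  g2 <- gy * (cache$a2 > 0)
  bw2 <- bw_conv(cache$a1, p$W2, g2)
  g1 <- bw2$gx * (cache$a1 > 0)
  bw1 <- bw_conv(cache$x, p$W1, g1)
  list(gx = bw1$gx,
       gp = list(W1 = bw1$gw, b1 = bw1$gb, W2 = bw2$gw, b2 = bw2$gb))
}

## -- channel attention: GAP -> bottleneck MLP -> sigmoid ---------------------

fw_channel_att <- function(x, p) {
  d <- dim(x)
  hw <- d[1] * d[2]
  g <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])
  z1 <- p$W1 %*% g + p$b1
  h1 <- pmax(z1, 0)
  s <- sigmoid(p$W2 %*% h1 + p$b2)
  sb <- array(rep(as.vector(s), each = hw), d)
  list(y = x * sb, x = x, g = g, h1 = h1, s = s, sb = sb)
}

bw_channel_att <- function(gy, p, cache) {
  d <- dim(cache$x)
  hw <- d[1] * d[2]
  gs <- matrix(colSums(matrix(gy * cache$x, hw, d[3] * d[4])), d[3], d[4])
  gz2 <- gs * cache$s * (1 - cache$s)
  gW2 <- gz2 %*% t(cache$h1)
  gb2 <- rowSums(gz2)
  gh1 <- t(p$W2) %*% gz2
  gz1 <- gh1 * (cache$h1 > 0)
  gW1 <- gz1 %*% t(cache$g)
  gb1 <- rowSums(gz1)
  gg <- t(p$W1) %*% gz1
  gx <- gy * cache$sb + array(rep(as.vector(gg / hw), each = hw), d)
  list(gx = gx, gp = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       weights = cache$s)
}

## -- spatial attention: channel max/avg pool -> conv -> sigmoid --------------

fw_spatial_att <- function(x, p) {
  d <- dim(x)
  C <- d[3]
  mx <- x[, , 1, , drop = FALSE]
  amax <- array(1L, c(d[1], d[2], 1, d[4]))
  if (C > 1) {
    for (c in 2:C) {
      xc <- x[, , c, , drop = FALSE]
      upd <- xc > mx
      mx[upd] <- xc[upd]
      amax[upd] <- c
    }
  }
  av <- array(0, c(d[1], d[2], 1, d[4]))
  for (c in seq_len(C)) av <- av + x[, , c, , drop = FALSE]
  av <- av / C
  pooled <- concat_channels(mx, av)
  z <- fw_conv(pooled, p$W, p$b)
  s <- sigmoid(z)
  y <- x
  for (c in seq_len(C)) y[, , c, ] <- x[, , c, ] * s[, , 1, ]
  list(y = y, x = x, amax = amax, pooled = pooled, s = s)
}

bw_spatial_att <- function(gy, p, cache) {
  x <- cache$x
  d <- dim(x)
  C <- d[3]
  s2 <- cache$s[, , 1, ]
  gs <- array(0, c(d[1], d[2], 1, d[4]))
  for (c in seq_len(C)) gs[, , 1, ] <- gs[, , 1, ] + gy[, , c, ] * x[, , c, ]
  gz <- gs * cache$s * (1 - cache$s)
  bwc <- bw_conv(cache$pooled, p$W, gz)
  gm <- bwc$gx[, , 1, , drop = FALSE]
  gav <- bwc$gx[, , 2, , drop = FALSE]
  gx <- array(0, d)
  for (c in seq_len(C)) {
    gx[, , c, ] <- gy[, , c, ] * s2 + gav[, , 1, ] / C +
      (cache$amax[, , 1, ] == c) * gm[, , 1, ]
  }
  list(gx = gx, gp = list(W = bwc$gw, b = bwc$gb), weights = cache$s)
}

## -- dual attention: parallel branches, mean fusion, 1x1 conv ----------------

fw_dual_att <- function(x, p) {
  cs <- fw_spatial_att(x, p$sp)
  cc <- fw_channel_att(x, p$ch)
  h <- (cs$y + cc$y) / 2
  y <- fw_conv(h, p$Wf, p$bf)
  list(y = y, sp = cs, ch = cc, h = h)
}

bw_dual_att <- function(gy, p, cache) {
  bwf <- bw_conv(cache$h, p$Wf, gy)
  gh <- bwf$gx / 2
  bs <- bw_spatial_att(gh, p$sp, cache$sp)
  bc <- bw_channel_att(gh, p$ch, cache$ch)
  list(gx = bs$gx + bc$gx,
       gp = list(sp = bs$gp, ch = bc$gp, Wf = bwf$gw, bf = bwf$gb))
}

## -- attention gates on skip connections -------------------------------------

# concat-sigmoid gate: alpha = sigmoid(1x1 conv on [enc, dec]); y = alpha * enc
fw_gate_cs <- function(enc, dec, p) {
  cat <- concat_channels(enc, dec)
  z <- fw_conv(cat, p$Wg, p$bg)
  a <- sigmoid(z)
  Ce <- dim(enc)[3]
  y <- enc
  for (c in seq_len(Ce)) y[, , c, ] <- enc[, , c, ] * a[, , 1, ]
  list(y = y, enc = enc, cat = cat, a = a)
}

bw_gate_cs <- function(gy, p, cache) {
  enc <- cache$enc
  Ce <- dim(enc)[3]
  d <- dim(cache$a)
  ga <- array(0, d)
  genc <- enc
  for (c in seq_len(Ce)) {
    ga[, , 1, ] <- ga[, , 1, ] + gy[, , c, ] * enc[, , c, ]
    genc[, , c, ] <- gy[, , c, ] * cache$a[, , 1, ]
  }
  gz <- ga * cache$a * (1 - cache$a)
  bwc <- bw_conv(cache$cat, p$Wg, gz)
  Cd <- dim(cache$cat)[3] - Ce
  genc <- genc + bwc$gx[, , seq_len(Ce), , drop = FALSE]
  gdec <- bwc$gx[, , Ce + seq_len(Cd), , drop = FALSE]
  list(genc = genc, gdec = gdec, gp = list(Wg = bwc$gw, bg = bwc$gb))
}

# scaled dot-product gate: Q = Wq dec, K = Wk enc over flattened positions;
# alpha = softmax(Q'K / sqrt(dk)) reweights encoder positions.
fw_gate_qkv <- function(enc, dec, p) {
  d <- dim(enc)
  P <- d[1] * d[2]
  N <- d[4]
  dk <- nrow(p$Wk)
  y <- enc
  As <- vector("list", N)
  Xes <- vector("list", N)
  Xds <- vector("list", N)
  for (n in seq_len(N)) {
    Xe <- t(matrix(enc[, , , n], P, d[3]))
    Xd <- t(matrix(dec[, , , n], P, dim(dec)[3]))
    K <- p$Wk %*% Xe
    Q <- p$Wq %*% Xd
    S <- crossprod(Q, K) / sqrt(dk)
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    Yn <- Xe %*% t(A)
    y[, , , n] <- array(t(Yn), c(d[1], d[2], d[3]))
    As[[n]] <- A
    Xes[[n]] <- Xe
    Xds[[n]] <- Xd
  }
  list(y = y, A = As, Xe = Xes, Xd = Xds, enc_dim = d, dec_dim = dim(dec))
}

bw_gate_qkv <- function(gy, p, cache) {
  d <- cache$enc_dim
  P <- d[1] * d[2]
  N <- d[4]
  dk <- nrow(p$Wk)
  genc <- array(0, d)
  gdec <- array(0, cache$dec_dim)
  gWq <- p$Wq * 0
  gWk <- p$Wk * 0
  for (n in seq_len(N)) {
    A <- cache$A[[n]]
    Xe <- cache$Xe[[n]]
    Xd <- cache$Xd[[n]]
    gY <- t(matrix(gy[, , , n], P, d[3]))
    gXe <- gY %*% A
    gA <- crossprod(gY, Xe)
    gS <- A * (gA - rowSums(gA * A))
    K <- p$Wk %*% Xe
    Q <- p$Wq %*% Xd
    gQ <- K %*% t(gS) / sqrt(dk)
    gK <- Q %*% gS / sqrt(dk)
    gWq <- gWq + gQ %*% t(Xd)
    gWk <- gWk + gK %*% t(Xe)
    gXe <- gXe + t(p$Wk) %*% gK
    gXd <- t(p$Wq) %*% gQ
    genc[, , , n] <- array(t(gXe), d[1:3])
    gdec[, , , n] <- array(t(gXd), cache$dec_dim[1:3])
  }
  list(genc = genc, gdec = gdec, gp = list(Wq = gWq, Wk = gWk))
}

## -- pooling / transposed convolution ---------------------------------------

fw_pool <- function(x) cpp_maxpool2_fw(x)

bw_pool <- function(gy, cache, H, W) cpp_maxpool2_bw(gy, cache$arg, H, W)

fw_convt <- function(x, W, b) cpp_convt2_fw(x, W, b)

bw_convt <- function(x, W, gy) cpp_convt2_bw(x, W, gy)

## -- softmax over the class channel ------------------------------------------

softmax_channels <- function(z) {
  K <- dim(z)[3]
  m <- z[, , 1, , drop = FALSE]
  if (K > 1) for (k in 2:K) m <- pmax(m, z[, , k, , drop = FALSE])
  e <- z
  s <- array(0, dim(m))
  for (k in seq_len(K)) {
    e[, , k, ] <- exp(z[, , k, ] - m[, , 1, ])
    s[, , 1, ] <- s[, , 1, ] + e[, , k, ]
  }
  for (k in seq_len(K)) e[, , k, ] <- e[, , k, ] / s[, , 1, ]
  e
}

# gradient wrt logits given gradient wrt softmax probabilities
softmax_channels_bw <- function(gp, probs) {
  K <- dim(probs)[3]
  dot <- gp[, , 1, ] * probs[, , 1, ]
  if (K > 1) for (k in 2:K) dot <- dot + gp[, , k, ] * probs[, , k, ]
  gz <- probs
  for (k in seq_len(K)) gz[, , k, ] <- probs[, , k, ] * (gp[, , k, ] - dot)
  gz
}
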