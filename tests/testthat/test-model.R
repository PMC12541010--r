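ns <- asNamespace("acunet")

test_that("conv blocks apply ReLU(conv(x) + b) with shape preserved", {
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  p <- list(W1 = array(0, c(3, 3, 3, 5)), b1 = numeric(5),
            W2 = array(0, c(3, 3, 5, 5)), b2 = numeric(5))
  out <- ns$fw_block(x, p)
  expect_equal(out$y, array(0, c(6, 6, 5, 2)))

  # identity 1x1-style kernel with a large negative bias: ReLU clamps to 0
  p$W1[2, 2, , ] <- 1
  p$b1 <- rep(-1e6, 5)
  expect_equal(ns$fw_block(x, p)$y, array(0, c(6, 6, 5, 2)))

  set.seed(1)
  p2 <- list(W1 = array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)), b1 = rnorm(4),
             W2 = array(rnorm(3 * 3 * 4 * 4), c(3, 3, 4, 4)), b2 = rnorm(4))
  y <- ns$fw_block(x, p2)$y
  expect_true(all(y >= 0))
  expect_equal(dim(y), c(6L, 6L, 4L, 2L))
})

test_that("spatial attention: zero weights give 0.5, bright spots win", {
  set.seed(2)
  x <- array(abs(rnorm(4 * 4 * 3 * 1)), c(4, 4, 3, 1))
  p0 <- list(W = array(0, c(3, 3, 2, 1)), b = 0)
  out <- ns$fw_spatial_att(x, p0)
  expect_equal(out$s, array(0.5, c(4, 4, 1, 1)))
  expect_equal(out$y, 0.5 * x)

  # one spatial location 10x brighter in all channels; a handcrafted
  # positive 1x1 kernel must put the attention maximum there.
  xb <- array(1, c(4, 4, 3, 1))
  xb[2, 3, , 1] <- 10
  k <- array(0, c(3, 3, 2, 1))
  k[2, 2, , 1] <- 1  # centre tap on [max; mean] pooled maps
  ab <- ns$fw_spatial_att(xb, list(W = k, b = 0))$s[, , 1, 1]
  # oracle: direct evaluation of pool -> conv -> sigmoid at centre taps
  pooled_sum <- apply(xb[, , , 1], c(1, 2), max) + apply(xb[, , , 1], c(1, 2), mean)
  expect_equal(ab, 1 / (1 + exp(-pooled_sum)))
  expect_equal(which.max(ab), which.max(pooled_sum))
  expect_equal(arrayInd(which.max(ab), c(4, 4)), matrix(c(2L, 3L), 1))

  rnd <- ns$fw_spatial_att(array(rnorm(32), c(4, 4, 2, 1)),
                           list(W = array(rnorm(18), c(3, 3, 2, 1)), b = 0.3))
  expect_true(all(rnd$s > 0 & rnd$s < 1))
})

test_that("channel attention: GAP, bottleneck MLP and sigmoid behave", {
  x <- array(0, c(3, 3, 4, 1))
  for (c in 1:4) x[, , c, 1] <- c * 1.5
  p0 <- list(W1 = matrix(0, 2, 4), b1 = numeric(2),
             W2 = matrix(0, 4, 2), b2 = numeric(4))
  out <- ns$fw_channel_att(x, p0)
  expect_equal(as.numeric(out$g), (1:4) * 1.5)  # GAP of constant channels
  expect_equal(as.numeric(out$s), rep(0.5, 4))
  expect_equal(out$y, 0.5 * x)

  set.seed(3)
  pr <- list(W1 = matrix(rnorm(8), 2, 4), b1 = rnorm(2),
             W2 = matrix(rnorm(8), 4, 2), b2 = rnorm(4))
  s <- ns$fw_channel_att(array(rnorm(36 * 2), c(3, 3, 4, 2)), pr)$s
  expect_true(all(s > 0 & s < 1))
})

test_that("dual attention fuses branches and preserves shape", {
  C <- 3
  x <- array(rnorm(5 * 4 * C * 2), c(5, 4, C, 2))
  idW <- array(0, c(1, 1, C, C))
  for (c in seq_len(C)) idW[1, 1, c, c] <- 1
  p <- list(sp = list(W = array(0, c(3, 3, 2, 1)), b = 0),
            ch = list(W1 = matrix(0, 1, C), b1 = 0,
                      W2 = matrix(0, C, 1), b2 = numeric(C)),
            Wf = idW, bf = numeric(C))
  out <- ns$fw_dual_att(x, p)
  expect_equal(out$y, 0.5 * x)  # both branches 0.5x, identity fusion
  expect_equal(ns$fw_dual_att(x * 0, p)$y, x * 0)
  set.seed(4)
  p$Wf <- array(rnorm(C * C), c(1, 1, C, C))
  expect_equal(dim(ns$fw_dual_att(x, p)$y), dim(x))
})

test_that("attention gates match their closed forms", {
  enc <- array(rnorm(4 * 4 * 3 * 1), c(4, 4, 3, 1))
  dec <- array(rnorm(4 * 4 * 3 * 1), c(4, 4, 3, 1))
  p0 <- list(Wg = array(0, c(1, 1, 6, 1)), bg = 0)
  g <- ns$fw_gate_cs(enc, dec, p0)
  expect_equal(g$a, array(0.5, c(4, 4, 1, 1)))
  expect_equal(g$y, 0.5 * enc)

  # zero projections: every softmax row is uniform 1/n
  pq0 <- list(Wq = matrix(0, 3, 3), Wk = matrix(0, 3, 3))
  gq <- ns$fw_gate_qkv(enc, dec, pq0)
  expect_equal(gq$A[[1]], matrix(1 / 16, 16, 16))

  # two-position toy with hand-set Q, K and d = 1
  enc2 <- array(c(1, -1, 0.5, 2, 0, 1), c(1, 2, 3, 1))  # positions (1,1),(1,2)
  dec2 <- array(c(2, 1, -1, 0, 1, 1), c(1, 2, 3, 1))
  Wq <- matrix(c(1, 0, 1), 1, 3)
  Wk <- matrix(c(0, 1, 1), 1, 3)
  gt <- ns$fw_gate_qkv(enc2, dec2, list(Wq = Wq, Wk = Wk))
  Xe <- t(matrix(enc2[, , , 1], 2, 3))
  Xd <- t(matrix(dec2[, , , 1], 2, 3))
  q <- as.numeric(Wq %*% Xd)
  k <- as.numeric(Wk %*% Xe)
  expected_A <- t(vapply(q, function(qi) {
    e <- exp(qi * k)
    e / sum(e)
  }, numeric(2)))
  expect_equal(gt$A[[1]], expected_A, tolerance = 1e-12)
  expect_equal(as.numeric(gt$y), as.numeric(t(Xe %*% t(expected_A))))

  set.seed(5)
  prand <- list(Wq = matrix(rnorm(9), 3, 3), Wk = matrix(rnorm(9), 3, 3))
  A <- ns$fw_gate_qkv(enc, dec, prand)$A[[1]]
  expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-12)
})

test_that("model building is seeded, variant-aware and parameter-counted", {
  cfg <- micro_model_config()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  base <- build_model(micro_model_config(variant = "baseline"))
  expect_true(all(vapply(base$params$enc_att, is.null, logical(1))))
  expect_true(all(vapply(base$params$dec_att, is.null, logical(1))))
  expect_true(all(vapply(base$params$gate, is.null, logical(1))))

  counts <- vapply(c("baseline", "channel_only", "spatial_only",
                     "decoder_only", "full"),
                   function(v) count_parameters(build_model(micro_model_config(variant = v))),
                   numeric(1))
  expect_true(all(counts[-1] > counts["baseline"]))
  expect_gt(counts["full"], max(counts[c("channel_only", "spatial_only")]))

  # variant nesting as sets of occupied module slots
  occupied <- function(v) {
    p <- build_model(micro_model_config(variant = v))$params
    slots <- character(0)
    for (nm in c("enc_att", "dec_att", "gate")) {
      idx <- which(!vapply(p[[nm]], is.null, logical(1)))
      if (length(idx)) slots <- c(slots, paste0(nm, idx))
    }
    slots
  }
  expect_true(all(occupied("baseline") %in% occupied("channel_only")))
  expect_true(all(occupied("channel_only") %in% occupied("full")))
  expect_true(all(occupied("decoder_only") %in% occupied("full")))

  # hand count: single 1x1 conv, 1 -> 1 channel, with bias
  expect_equal(count_parameters(list(W = array(1, c(1, 1, 1, 1)), b = 0)), 2)
  expect_equal(count_parameters(m1), count_parameters(m2))
})

test_that("forward pass is shape-preserving, normalized and deterministic", {
  m <- build_model(model_config(depth = 3, base_width = 4, seed = 2))
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  pr <- forward(m, x)
  expect_equal(dim(pr), c(64L, 64L, 4L, 1L))
  sums <- apply(pr, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, forward(m, x))

  # non-divisible spatial dims are padded then cropped back
  m2 <- build_model(micro_model_config())
  x2 <- array(rnorm(10 * 12 * 4), c(10, 12, 4))
  pr2 <- forward(m2, x2)
  expect_equal(dim(pr2)[1:2], c(10L, 12L))
  sums2 <- apply(pr2, c(1, 2, 4), sum)
  expect_true(all(abs(sums2 - 1) < 1e-6))

  expect_error(forward(m, array(0, c(16, 16, 3))), "channels")
})

test_that("qkv gating inside a full model stays row-normalized and bounded", {
  m <- build_model(model_config(depth = 2, base_width = 2, seed = 3,
                                variant = "full", gate_mode = "qkv_softmax",
                                spatial_kernel = 3))
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 1))
  fw <- ns$forward_net(m, x, keep_cache = TRUE)
  A <- fw$cache$dec[[1]]$gate$A[[1]]
  expect_equal(rowSums(A), rep(1, 256), tolerance = 1e-9)
  expect_true(all(A > 0))

  # attention weights from sigmoid branches live strictly inside (0, 1)
  s_sp <- fw$cache$att_e[[1]]$sp$s
  s_ch <- fw$cache$att_e[[1]]$ch$s
  expect_true(all(s_sp > 0 & s_sp < 1))
  expect_true(all(s_ch > 0 & s_ch < 1))
})
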