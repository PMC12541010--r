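test_that("SGD updates follow theta <- theta - lr * grad", {
  p <- list(w = matrix(as.numeric(1:4), 2, 2), b = c(0.5, -0.5))
  g <- list(w = matrix(1, 2, 2), b = c(1, 1))
  same <- sgd_step(p, g, lr = 0)
  expect_identical(same$params, p)

  one <- sgd_step(list(theta = 1), list(theta = 0.25), lr = 1)
  expect_equal(one$params$theta, 0.75)

  # minimizing theta^2 contracts geometrically: (1 - 2*lr)^t * theta0
  theta <- list(x = 4)
  st <- NULL
  for (t in 1:50) {
    up <- sgd_step(theta, list(x = 2 * theta$x), lr = 0.1, momentum = 0, state = st)
    theta <- up$params
    st <- up$state
  }
  expect_lt(abs(theta$x), 1e-3)
  expect_equal(theta$x, (1 - 0.2)^50 * 4, tolerance = 1e-9)

  # momentum accumulates a velocity buffer
  m1 <- sgd_step(list(x = 1), list(x = 1), lr = 0.1, momentum = 0.9)
  m2 <- sgd_step(m1$params, list(x = 1), lr = 0.1, momentum = 0.9, state = m1$state)
  expect_equal(m2$params$x, 1 - 0.1 * 1 - 0.1 * (0.9 + 1))
})

test_that("k-fold splits partition the indices into near-equal folds", {
  f <- kfold_split(10, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_length(f, 10)
  expect_setequal(unique(f), 1:5)
  expect_identical(f, kfold_split(10, 5, seed = 3))
  expect_false(identical(f, kfold_split(10, 5, seed = 4)))

  f2 <- kfold_split(11, 3, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(kfold_split(10, 1), "k must")
  expect_error(kfold_split(10, 11), "k must")
})

test_that("training is deterministic and reduces the loss on phantoms", {
  spec <- tiny_phantom_spec(n = 10, seed = 19)
  ss <- generate_phantoms(spec)
  mcfg <- micro_model_config(seed = 2)
  tcfg <- fast_train_config(epochs = 2, seed = 7)

  fit1 <- acunet_train(ss, model = mcfg, train = tcfg)
  fit2 <- acunet_train(ss, model = mcfg, train = tcfg)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history, fit2$history)
  expect_equal(nrow(fit1$history), 2)

  # loss after training is below the untrained model's loss on the same data
  ns <- asNamespace("acunet")
  batch <- ns$assemble_batch(ss, seq_along(ss), "zscore")
  G <- ns$onehot_labels(batch$mask)
  w <- tcfg$weights
  untrained <- build_model(mcfg)
  l0 <- ns$training_loss(ns$forward_net(untrained, batch$x)$probs, G, w)$loss
  l1 <- ns$training_loss(ns$forward_net(fit1$model, batch$x)$probs, G, w)$loss
  expect_lt(l1, l0)
  expect_lt(fit1$history$train_loss[2], fit1$history$train_loss[1])

  expect_error(acunet_train(list(), model = mcfg, train = tcfg), "empty")
})

test_that("cross-validation averages fold metrics exactly", {
  spec <- tiny_phantom_spec(n = 8, seed = 23)
  ss <- generate_phantoms(spec)
  cv <- cross_validate(ss, model_cfg = micro_model_config(seed = 1),
                       train_cfg = fast_train_config(epochs = 1, seed = 5), k = 2)
  expect_equal(nrow(cv$table), 3)
  # every sample validated exactly once
  expect_setequal(unique(cv$assignment), 1:2)
  expect_length(cv$assignment, 8)
  fold_mat <- do.call(rbind, cv$folds)
  expect_equal(unname(as.matrix(cv$table)["Average", ]),
               unname(colMeans(fold_mat)), tolerance = 1e-12)
})

test_that("checkpoints round-trip weights and reject tampered configs", {
  d <- withr::local_tempdir()
  spec <- tiny_phantom_spec(n = 5, seed = 29)
  ss <- generate_phantoms(spec)
  fit <- acunet_train(ss, model = micro_model_config(seed = 3),
                      train = fast_train_config(epochs = 1, seed = 2))
  p <- file.path(d, "ck.rds")
  save_checkpoint(fit, p)
  back <- load_checkpoint(p)
  expect_identical(back$model$params, fit$model$params)
  pred1 <- predict(fit, ss[[1]])[[1]]
  pred2 <- predict(back, ss[[1]])[[1]]
  expect_identical(pred1, pred2)

  obj <- readRDS(p)
  obj$config$base_width <- 16L
  saveRDS(obj, p)
  expect_error(load_checkpoint(p), "fingerprint")
})
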