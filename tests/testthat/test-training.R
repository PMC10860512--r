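test_that("dice loss obeys its limiting identities", {
  a <- array(rbinom(64, 1, 0.4), c(8, 8))
  expect_lt(dice_loss(a, a, smooth = 1e-9), 1e-8)
  b <- array(0, c(8, 8)); b[1:2, 1:2] <- 1
  d <- array(0, c(8, 8)); d[5:6, 5:6] <- 1
  expect_gt(dice_loss(b, d, smooth = 1e-9), 1 - 1e-8)
  expect_error(dice_loss(b, d[1:4, ]), "mismatch")
})

test_that("dice loss matches a hand computation at half coverage", {
  # N pixels, target covers N/2, prediction 0.5 everywhere, smooth -> 0:
  # overlap = 0.5*|T|, sums = 0.5*N + N/2, Dice = 0.5, loss = 0.5
  N <- 16 * 16
  t <- array(0, c(16, 16)); t[, 1:8] <- 1
  p <- array(0.5, c(16, 16))
  expect_equal(dice_loss(p, t, smooth = 1e-12), 0.5, tolerance = 1e-9)
})

test_that("dice loss is symmetric for binary arguments and bounded", {
  set.seed(1)
  for (i in 1:100) {
    p <- array(runif(64), c(8, 8, 1, 1))
    t <- array(rbinom(64, 1, runif(1, 0.05, 0.8)), c(8, 8, 1, 1))
    l <- dice_loss(p, t)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  b1 <- array(rbinom(64, 1, 0.3), c(8, 8))
  b2 <- array(rbinom(64, 1, 0.3), c(8, 8))
  expect_equal(dice_loss(b1, b2), dice_loss(b2, b1))
})

test_that("the gradient of the dice loss matches finite differences", {
  set.seed(2)
  p <- array(runif(32, 0.1, 0.9), c(4, 4, 1, 2))
  t <- array(rbinom(32, 1, 0.4), c(4, 4, 1, 2))
  g <- gtvseg:::dice_loss_grad(p, t, smooth = 1)
  h <- 1e-6
  for (i in sample(32, 6)) {
    p2 <- p; p2[i] <- p2[i] + h
    p3 <- p; p3[i] <- p3[i] - h
    gnum <- (dice_loss(p2, t) - dice_loss(p3, t)) / (2 * h)
    expect_equal(g[i], gnum, tolerance = 1e-5)
  }
})

test_that("subject splits are exact, disjoint and seeded", {
  co <- generate_cohort(tiny_spec(), 20, seed = 1L)
  sp <- split_subjects(co, 0.1, seed = 3L)
  expect_length(sp$train, 18); expect_length(sp$val, 2)
  ids <- function(x) vapply(x, `[[`, "", "id")
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$val)), ids(co))
  sp2 <- split_subjects(co, 0.1, seed = 3L)
  expect_identical(ids(sp2$val), ids(sp$val))
  # at least one validation subject even at tiny fractions
  expect_length(split_subjects(co[1:4], 0.1, seed = 1L)$val, 1)
  expect_error(split_subjects(co[1], 0.1, 1L), "too small")
})

test_that("a zero learning rate leaves the weights untouched", {
  co <- generate_cohort(tiny_spec(), 4, seed = 5L)
  m0 <- build_model(tiny_net(), seed = 4)
  out <- train(m0, co, tiny_train_cfg(epochs_max = 2L, learning_rate = 0))
  expect_identical(out$model$params, m0$params)
  # shuffling recomposes batches, so batch-norm statistics (and hence the
  # reported loss) can move in the 4th decimal even with frozen weights
  expect_equal(out$history$train_loss[1], out$history$train_loss[2],
               tolerance = 5e-3)
})

test_that("training is deterministic and reduces the loss", {
  co <- generate_cohort(tiny_spec(), 5, seed = 6L)
  cfg <- tiny_train_cfg(epochs_max = 4L, seed = 2L)
  m0 <- build_model(tiny_net(), seed = 4)
  a <- train(m0, co, cfg)
  b <- train(m0, co, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_lt(dplyr::last(a$history$train_loss), a$history$train_loss[1])
  expect_true(all(is.finite(a$history$val_loss)))
})

test_that("fine-tuning with a zero epoch budget is the identity", {
  co <- generate_cohort(tiny_spec(), 4, seed = 7L)
  m <- build_model(tiny_net(), seed = 4)
  out <- fine_tune(m, co, tiny_train_cfg(epochs_max = 0L))
  expect_identical(out$model$params, m$params)
  expect_identical(nrow(out$history), 0L)
})

test_that("volume prediction restacks slices and respects the threshold", {
  s <- generate_subject(tiny_spec(), 9L)
  v <- window_normalize(s$volume)
  m <- build_model(tiny_net(), seed = 4)
  pred <- predict_volume(m, v)
  expect_identical(dim(pred), dim(v$data))
  expect_true(all(pred %in% c(0L, 1L)))
  # sigmoid outputs are < 1, so an impossible threshold empties the mask
  expect_equal(sum(predict_volume(m, v, threshold = 1 + 1e-9)), 0)
  wrong <- gtv_volume(array(0.5, c(16, 16, 4)), c(1, 1, 1), "normalized")
  expect_error(predict_volume(m, wrong), "input size")
  expect_error(predict_volume(m, s$volume), "normalized")
})
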