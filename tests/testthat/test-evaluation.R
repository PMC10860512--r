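test_that("confusion counts match the exhaustive per-voxel oracle", {
  set.seed(1)
  for (i in 1:50) {
    p <- random_mask(c(8, 8), runif(1, 0.1, 0.6))
    r <- random_mask(c(8, 8), runif(1, 0.1, 0.6))
    cc <- confusion(p, r)
    oc <- oracle_confusion(p, r)
    expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")], oc)
    expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 64L)
  }
  expect_error(confusion(random_mask(c(4, 4)), random_mask(c(4, 5))),
               "mismatch")
})

test_that("metric arithmetic follows the standard definitions", {
  m1 <- array(0L, c(10, 10, 10)); m1[1:10] <- 1L
  expect_equal(dsc(confusion(m1, m1)), 1)
  expect_equal(precision(confusion(m1, m1)), 1)
  expect_equal(recall(confusion(m1, m1)), 1)

  c1 <- structure(list(tp = 2, fp = 2, fn = 2, tn = 10),
                  class = "gtv_confusion")
  expect_equal(dsc(c1), 0.5)
  expect_equal(precision(c1), 0.5)
  expect_equal(recall(c1), 0.5)

  c2 <- structure(list(tp = 3, fp = 1, fn = 2, tn = 10),
                  class = "gtv_confusion")
  expect_equal(dsc(c2), 6 / 9)
  expect_equal(precision(c2), 0.75)
  expect_equal(recall(c2), 0.6)
})

test_that("degenerate mask pairs follow the documented conventions", {
  e <- array(0L, c(5, 5)); f <- array(0L, c(5, 5)); f[1:3] <- 1L
  both <- confusion(e, e)
  expect_equal(c(dsc(both), precision(both), recall(both)), c(1, 1, 1))
  pe <- confusion(e, f)   # empty prediction, non-empty reference
  expect_equal(dsc(pe), 0)
  expect_equal(recall(pe), 0)
  expect_true(is.na(precision(pe)))
  re <- confusion(f, e)   # non-empty prediction, empty reference
  expect_equal(dsc(re), 0)
  expect_equal(precision(re), 0)
  expect_true(is.na(recall(re)))
})

test_that("dsc is the harmonic mean of precision and recall", {
  set.seed(2)
  for (i in 1:50) {
    cc <- confusion(random_mask(c(6, 6), 0.4), random_mask(c(6, 6), 0.4))
    p <- precision(cc); r <- recall(cc)
    if (!is.na(p) && !is.na(r) && p + r > 0)
      expect_equal(dsc(cc), 2 * p * r / (p + r))
  }
})

test_that("pairwise observer agreement enumerates unordered pairs", {
  masks5 <- lapply(1:5, function(i) random_mask(c(6, 6), 0.4))
  pw <- pairwise_observer_dsc(masks5, "s")
  expect_identical(nrow(pw), 10L)

  same <- lapply(1:4, function(i) masks5[[1]])
  expect_true(all(pairwise_observer_dsc(same)$dsc == 1))

  masks3 <- lapply(1:3, function(i) random_mask(c(5, 5), 0.5))
  pw3 <- pairwise_observer_dsc(masks3, "s")
  expect_identical(nrow(pw3), 3L)
  for (row in seq_len(3)) {
    i <- as.integer(sub("obs", "", pw3$predictor[row]))
    j <- as.integer(sub("obs", "", pw3$reference[row]))
    expect_equal(pw3$dsc[row], dsc(confusion(masks3[[i]], masks3[[j]])))
    expect_equal(pw3$dsc[row], dsc(confusion(masks3[[j]], masks3[[i]])))
  }
  expect_error(pairwise_observer_dsc(masks3[1]), "two")
})

test_that("model-vs-observer records one comparison per observer", {
  masks <- lapply(1:5, function(i) random_mask(c(6, 6), 0.4))
  pred <- masks[[3]]
  mv <- model_vs_observers(pred, masks, "s", "model1")
  expect_identical(nrow(mv), 5L)
  expect_equal(mv$dsc[3], 1)
  for (k in 1:5) {
    cc <- confusion(pred, masks[[k]])
    expect_equal(mv$dsc[k], dsc(cc))
    expect_equal(mv$precision[k], precision(cc))
    expect_equal(mv$recall[k], recall(cc))
  }
})

test_that("consensus regions agree with brute-force vote counting", {
  all_same <- lapply(1:5, function(i) random_mask(c(6, 6), 0.5))
  for (i in 2:5) all_same[[i]] <- all_same[[1]]
  cr <- consensus_regions(all_same)
  for (k in 1:5)
    expect_identical(consensus_region(cr, k),
                     array(as.integer(all_same[[1]] != 0), c(6, 6)))

  a <- array(0L, c(4, 4)); a[1:4] <- 1L
  b <- array(0L, c(4, 4)); b[13:16] <- 1L
  cr2 <- consensus_regions(list(a, b))
  expect_equal(sum(consensus_region(cr2, 2)), 0)
  expect_identical(consensus_region(cr2, 1),
                   array(as.integer((a + b) > 0), c(4, 4)))

  set.seed(3)
  masks <- lapply(1:5, function(i) random_mask(c(8, 8), 0.4))
  cr3 <- consensus_regions(masks)
  for (k in 1:5)
    expect_identical(consensus_region(cr3, k),
                     oracle_consensus_region(masks, k))
  for (k in 1:4)  # nesting
    expect_true(all(consensus_region(cr3, k)[
      consensus_region(cr3, k + 1) == 1L] == 1L))
})

test_that("consensus recall is complete coverage or a nested gradient", {
  set.seed(4)
  masks <- lapply(1:5, function(i) random_mask(c(8, 8), 0.5))
  cr <- consensus_regions(masks)
  full <- consensus_region(cr, 1)
  rec_full <- consensus_recall(full, cr)
  expect_true(all(rec_full$recall == 1, na.rm = TRUE))

  core <- consensus_region(cr, 5)
  rec_core <- consensus_recall(core, cr)  # levels K..1
  expect_equal(rec_core$recall[rec_core$level == 5], 1)
  expect_true(all(diff(rec_core$recall) <= 1e-12))  # rows K..1: non-increasing

  pred <- random_mask(c(8, 8), 0.5)
  rec <- consensus_recall(pred, cr, "s", "m")
  for (k in 1:5) {
    reg <- oracle_consensus_region(masks, k)
    expect_equal(rec$recall[rec$level == k],
                 sum(pred & reg) / sum(reg))
  }
})

test_that("volume metrics equal metrics from summed per-slice counts", {
  set.seed(5)
  p <- random_mask(c(6, 6, 4), 0.4); r <- random_mask(c(6, 6, 4), 0.4)
  cc <- confusion(p, r)
  sums <- list(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (s in 1:4) {
    sc <- confusion(p[, , s], r[, , s])
    for (nm in names(sums)) sums[[nm]] <- sums[[nm]] + sc[[nm]]
  }
  expect_identical(unclass(cc)[names(sums)], sums)
  expect_equal(dsc(cc), dsc(structure(sums, class = "gtv_confusion")))
})
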