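test_that("confusion accumulation is exact and additive", {
  sch <- class_scheme("A")
  truth <- seg_mask(matrix(c(rep(1L, 12), rep(0L, 13)), 5, 5), sch)
  pred0 <- seg_mask(matrix(0L, 5, 5), sch)

  acc <- accumulate_confusion(confusion_accumulator(sch), pred0, truth)
  td <- tidy(acc)
  expect_equal(td$tp[td$class == "class_norm"], 0)
  expect_equal(td$fn[td$class == "class_norm"], 12)

  # identical masks give zero errors everywhere
  acc2 <- accumulate_confusion(confusion_accumulator(sch), truth, truth)
  expect_true(all(tidy(acc2)$fp == 0) && all(tidy(acc2)$fn == 0))
  expect_equal(mean_iou(acc2), 1.0)

  # accumulating two images equals one accumulator fed both
  m1 <- random_scheme_c_mask(8, 8); t1 <- random_scheme_c_mask(8, 8)
  m2 <- random_scheme_c_mask(8, 8); t2 <- random_scheme_c_mask(8, 8)
  both <- accumulate_confusion(
    accumulate_confusion(confusion_accumulator("C"), m1, t1), m2, t2)
  concat <- accumulate_confusion(
    confusion_accumulator("C"),
    seg_mask(cbind(m1$labels, m2$labels), "C"),
    seg_mask(cbind(t1$labels, t2$labels), "C"))
  expect_equal(both$counts[c("tp", "fp", "fn")],
               concat$counts[c("tp", "fp", "fn")])

  expect_error(accumulate_confusion(confusion_accumulator("B"), m1, t1),
               "scheme")
  expect_error(
    accumulate_confusion(confusion_accumulator("C"), m1,
                         random_scheme_c_mask(4, 4)), "grids")
})

test_that("mean IoU reproduces the hand-worked 4x4 example", {
  sch <- class_scheme("A")
  truth <- seg_mask(matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4), sch)
  pred <- truth
  pred$labels[1:2, 3] <- 1L    # two background pixels mislabeled plant
  acc <- accumulate_confusion(confusion_accumulator(sch), pred, truth)
  expect_equal(mean_iou(acc), 0.775)
  td <- tidy(acc)
  expect_equal(td$iou[td$class == "class_norm"], 8 / 10)
  expect_equal(td$iou[td$class == "background"], 6 / 8)
})

test_that("mean IoU edge cases: disjoint, symmetric, absent classes", {
  sch <- class_scheme("A")
  left <- seg_mask(matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4), sch)
  right <- seg_mask(matrix(c(rep(0L, 8), rep(1L, 8)), 4, 4), sch)
  acc <- accumulate_confusion(confusion_accumulator(sch), left, right)
  expect_equal(mean_iou(acc), 0)   # both classes fully disjoint

  # symmetry under swapping prediction and truth
  m1 <- random_scheme_c_mask(); m2 <- random_scheme_c_mask()
  a12 <- accumulate_confusion(confusion_accumulator("C"), m1, m2)
  a21 <- accumulate_confusion(confusion_accumulator("C"), m2, m1)
  expect_equal(mean_iou(a12), mean_iou(a21))

  # absent classes are excluded from the mean, empty pair errors
  bg <- seg_mask(matrix(0L, 4, 4), "C")
  accbg <- accumulate_confusion(confusion_accumulator("C"), bg, bg)
  expect_equal(mean_iou(accbg), 1.0)   # only background scored
  expect_error(mean_iou(confusion_accumulator("C")), "undefined")
})

test_that("mean IoU matches the brute-force set oracle on random pairs", {
  set.seed(99)
  for (i in 1:40) {
    pred <- random_scheme_c_mask()
    truth <- random_scheme_c_mask()
    acc <- accumulate_confusion(confusion_accumulator("C"), pred, truth)
    expect_equal(mean_iou(acc), oracle_mean_iou(pred, truth),
                 tolerance = 1e-14)
  }
})

test_that("label noise never improves a perfect prediction", {
  set.seed(17)
  truth <- random_scheme_c_mask(20, 20)
  perfect <- accumulate_confusion(confusion_accumulator("C"), truth, truth)
  prev_iou <- mean_iou(perfect)
  for (frac in c(0.05, 0.2, 0.5)) {
    noisy <- truth
    idx <- sample(length(noisy$labels), round(frac * length(noisy$labels)))
    noisy$labels[idx] <- (noisy$labels[idx] + 1L) %% 4L
    acc <- accumulate_confusion(confusion_accumulator("C"), noisy, truth)
    expect_lte(mean_iou(acc), prev_iou + 1e-12)
  }
})

test_that("area agreement returns exact R^2 for affine relations", {
  x <- c(10, 22, 35, 41, 57)
  expect_equal(glance(area_agreement(x, x))$r.squared, 1.0)
  expect_equal(glance(area_agreement(x, 2 * x + 5))$r.squared, 1.0)
  ag <- area_agreement(x, 2 * x + 5)
  expect_equal(glance(ag)$slope, 2)
  expect_equal(glance(ag)$intercept, 5)
  expect_error(area_agreement(c(1, 2), c(1, 2)), "at least 3")
  expect_error(area_agreement(c(3, 3, 3), c(1, 2, 3)), "variance")
  expect_s3_class(autoplot(ag), "ggplot")
  expect_equal(tidy(ag)$term, c("(Intercept)", "x"))
})
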