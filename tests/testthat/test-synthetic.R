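test_that("scene parameters validate their inputs", {
  expect_error(scene_params(state_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(scene_params(leaf_length = -3), "positive")
  expect_error(scene_params(background = "lawn"))
})

test_that("generation is deterministic and leaves the RNG untouched", {
  p <- scene_params(width = 96L, height = 96L, seed = 5L)
  s1 <- generate_rosette(p)
  s2 <- generate_rosette(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth$labels, s2$truth$labels)

  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_rosette(p)); after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate scenes behave as specified", {
  empty <- generate_rosette(scene_params(width = 64L, height = 64L,
                                         leaf_count = 0L, seed = 2L))
  expect_true(all(empty$truth$labels == 0L))

  green <- generate_rosette(scene_params(width = 96L, height = 96L,
                                         state_probs = c(1, 0, 0),
                                         leaf_count = 8L, seed = 3L))
  expect_setequal(unique(as.vector(green$truth$labels)), c(0L, 1L))
})

test_that("class counts match the rendered mask and leaves are clipped", {
  sc <- small_scene(seed = 21)
  tally <- table(factor(sc$truth$labels, levels = 0:3))
  counts <- setNames(sc$class_counts$pixels, sc$class_counts$class)
  expect_equal(unname(counts["background"]), unname(c(tally["0"])))
  expect_equal(unname(counts["class_norm"]), unname(c(tally["1"])))
  expect_equal(unname(counts["plant_region"]),
               unname(c(tally["1"] + tally["2"])))

  # oversized leaves are clipped to the frame, not an error
  big <- generate_rosette(scene_params(width = 48L, height = 48L,
                                       leaf_length = 200, leaf_width = 60,
                                       seed = 4L))
  expect_equal(dim(big$truth$labels), c(48L, 48L))
})

test_that("state mix over many scenes follows the sampling probabilities", {
  p <- c(0.5, 0.3, 0.2)
  n_scenes <- 60
  leaf_count <- 8L
  tot <- c(0, 0, 0)
  for (i in seq_len(n_scenes)) {
    sc <- generate_rosette(scene_params(width = 96L, height = 96L,
                                        leaf_count = leaf_count,
                                        state_probs = p, seed = 7000L + i))
    tot <- tot + vapply(1:3, function(l) sum(sc$truth$labels == l),
                        numeric(1))
  }
  frac <- tot / sum(tot)
  n_leaves <- n_scenes * leaf_count
  # pixel fractions track leaf-level binomial sampling
  for (k in 1:3) {
    se <- sqrt(p[k] * (1 - p[k]) / n_leaves)
    expect_lt(abs(frac[k] - p[k]), 3 * se + 0.02)
  }
})

test_that("channel means converge to the configured state colors", {
  for (spread in c(0, 4)) {
    sc <- generate_rosette(scene_params(width = 128L, height = 128L,
                                        state_probs = c(1, 0, 0),
                                        color_spread = spread, seed = 9L))
    cm <- channel_means(sc$image, sc$truth, "class_norm")
    truth_col <- sc$state_colors["class_norm", ]
    tol <- if (spread == 0) 1e-9 else 6
    expect_equal(unname(unlist(cm)), unname(truth_col), tolerance = tol)
  }
})

test_that("time series recovers an imposed senescence trend", {
  base <- scene_params(width = 96L, height = 96L, leaf_count = 8L,
                       seed = 31L)
  ages <- 1:6
  ts <- generate_time_series(base, ages,
                             senescence_ramp(1, 6, 0.02, 0.6),
                             replicates = 4)
  expect_equal(nrow(ts), 24)
  rho <- cor(ts$age, ts$frac_senesc, method = "spearman")
  expect_gt(rho, 0.7)

  # constant mapping gives a statistically flat series
  flat <- generate_time_series(base, ages,
                               function(a) c(0.6, 0.2, 0.2),
                               replicates = 4)
  expect_gt(cor.test(flat$age, flat$frac_senesc,
                     method = "spearman", exact = FALSE)$p.value, 0.01)

  # reproducibility and input validation
  ts2 <- generate_time_series(base, ages,
                              senescence_ramp(1, 6, 0.02, 0.6),
                              replicates = 4)
  expect_identical(ts$frac_senesc, ts2$frac_senesc)
  expect_error(generate_time_series(base, c(3, 2, 1), function(a) c(1, 0, 0)),
               "increasing")
  expect_error(generate_time_series(base, ages, function(a) c(2, 0, 0)),
               "probability")
  expect_s3_class(plot_class_fractions(ts), "ggplot")
})

test_that("simulate_dataset writes a coherent benchmark folder", {
  dir <- withr::local_tempdir()
  truth <- simulate_dataset(dir, n = 3, seed = 12, preset = "mixed",
                            width = 96L, height = 96L)
  expect_equal(nrow(truth), 3)
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.png$")
  masks <- list.files(file.path(dir, "masks"), pattern = "\\.png$")
  expect_equal(length(imgs), 3)
  expect_equal(imgs, masks)
  # written mask tallies agree with truth.csv
  m1 <- load_mask(file.path(dir, "masks", masks[1]), "C")
  expect_equal(sum(m1$labels == 1L), truth$pixels_norm[1])
  expect_true(file.exists(file.path(dir, "truth.csv")))
})
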