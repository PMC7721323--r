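#' Parameters of a synthetic rosette scene
#'
#' Bundles everything that determines one generated top-view scene: a
#' single rosette of elliptical leaves placed radially around the image
#' center, each leaf in one of three color states (green, anthocyanin-rich,
#' senescent), over a configurable background. The seed fully determines
#' the scene.
#'
#' @param width,height Image size in pixels.
#' @param leaf_count Number of leaves (0 gives a pure-background scene).
#' @param leaf_length,leaf_width Mean leaf dimensions in pixels (each leaf
#'   draws its own length/width from a normal with these means and
#'   `leaf_dim_sd`).
#' @param leaf_dim_sd Standard deviation of leaf dimensions, pixels.
#' @param angle_jitter Standard deviation of the angular jitter (radians)
#'   added to the regular spacing `2*pi*l/leaf_count`.
#' @param state_probs Probabilities `(p_norm, p_antho, p_senesc)` of the
#'   three leaf states; must sum to 1.
#' @param state_colors 3x3 matrix of mean RGB per state (rows norm, antho,
#'   senesc). Defaults: green (45,110,40), purple (95,40,85), brown-yellow
#'   (150,120,60).
#' @param color_spread Per-channel SD around the state mean (per leaf, plus
#'   smaller per-pixel grain); 0 gives exactly the state colors.
#' @param background One of `"solid"`, `"blue_mesh"`, `"soil"`,
#'   `"soil_with_algae"`.
#' @param illumination Global intensity scale factor (clipped to 0-255).
#' @param seed Integer seed.
#' @return A `scene_params` list.
#' @export
scene_params <- function(width = 256L, height = 256L, leaf_count = 10L,
                         leaf_length = 70, leaf_width = 26,
                         leaf_dim_sd = 8, angle_jitter = 0.12,
                         state_probs = c(0.7, 0.2, 0.1),
                         state_colors = default_state_colors(),
                         color_spread = 15, background = "soil",
                         illumination = 1, seed = 1L) {
  stopifnot(length(state_probs) == 3L, all(state_probs >= 0))
  if (abs(sum(state_probs) - 1) > 1e-8) {
    stop("`state_probs` must sum to 1", call. = FALSE)
  }
  if (leaf_length <= 0 || leaf_width <= 0) {
    stop("leaf dimensions must be positive", call. = FALSE)
  }
  background <- match.arg(background,
                          c("solid", "blue_mesh", "soil", "soil_with_algae"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 leaf_count = as.integer(leaf_count),
                 leaf_length = leaf_length, leaf_width = leaf_width,
                 leaf_dim_sd = leaf_dim_sd, angle_jitter = angle_jitter,
                 state_probs = state_probs, state_colors = state_colors,
                 color_spread = color_spread, background = background,
                 illumination = illumination, seed = as.integer(seed)),
            class = "scene_params")
}

#' Default mean RGB of the three leaf states
#' @return 3x3 matrix, rows `class_norm`, `class_antho`, `class_senesc`.
#' @export
default_state_colors <- function() {
  m <- rbind(class_norm = c(45, 110, 40),
             class_antho = c(95, 40, 85),
             class_senesc = c(150, 120, 60))
  colnames(m) <- c("r", "g", "b")
  m
}

# Deterministic per-scene seed from (base seed, scene index); stays well
# below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483629) + 1L
}

render_background <- function(params) {
  h <- params$height; w <- params$width
  img <- array(0, c(h, w, 3L))
  switch(params$background,
    solid = {
      base <- c(70, 70, 75)
      for (ch in 1:3) img[, , ch] <- base[ch]
    },
    blue_mesh = {
      base <- c(50, 50, 55); blue <- c(60, 90, 170)
      for (ch in 1:3) img[, , ch] <- base[ch]
      rows <- which(seq_len(h) %% 16L %in% c(0L, 1L))
      cols <- which(seq_len(w) %% 16L %in% c(0L, 1L))
      for (ch in 1:3) {
        img[rows, , ch] <- blue[ch]
        img[, cols, ch] <- blue[ch]
      }
    },
    soil = ,
    soil_with_algae = {
      base <- c(110, 85, 60)
      for (ch in 1:3) {
        img[, , ch] <- base[ch] + matrix(stats::rnorm(h * w, sd = 12), h, w)
      }
      if (params$background == "soil_with_algae") {
        n_dots <- max(1L, round(0.002 * h * w))
        cy <- sample.int(h, n_dots, replace = TRUE)
        cx <- sample.int(w, n_dots, replace = TRUE)
        algae <- c(50, 120, 55)
        for (d in seq_len(n_dots)) {
          rr <- pmax(1L, pmin(h, cy[d] + (-1:1)))
          cc <- pmax(1L, pmin(w, cx[d] + (-1:1)))
          for (ch in 1:3) {
            img[rr, cc, ch] <- algae[ch] + stats::rnorm(1, sd = 8)
          }
        }
      }
    })
  pmin(pmax(img, 0), 255)
}

# Pixel set of a rotated ellipse, clipped to the grid. Returns linear
# indices into an h x w matrix.
ellipse_pixels <- function(h, w, cy, cx, a, b, theta) {
  rmax <- ceiling(max(a, b))
  rows <- max(1L, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  if (length(rows) == 0L || length(cols) == 0L) return(integer(0))
  ry <- rep(rows, times = length(cols)) - cy
  rx <- rep(cols, each = length(rows)) - cx
  u <- rx * cos(theta) + ry * sin(theta)
  v <- -rx * sin(theta) + ry * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * h + rr
}

#' Generate one synthetic rosette scene
#'
#' Places `leaf_count` elliptical leaves radially around the image center
#' (angle `2*pi*l/leaf_count` plus jitter), assigns each leaf a color
#' state by `state_probs`, and renders image and ground-truth mask from the
#' same geometry, leaves drawn back to front so the mask matches visible
#' pixels exactly. Leaves extending beyond the frame are clipped.
#'
#' @param params A [scene_params()].
#' @return An object of class `synthetic_scene`: list with `image`
#'   (`h x w x 3`, 0-255), `truth` (scheme-C [seg_mask()]),
#'   `class_counts` (tibble, per-class pixel tallies incl. `plant_region`),
#'   `state_colors` (the configured per-state means) and `params`.
#' @examples
#' sc <- generate_rosette(scene_params(width = 96, height = 96, seed = 7))
#' sc$class_counts
#' @export
generate_rosette <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(params$seed)

  h <- params$height; w <- params$width
  img <- render_background(params)
  labels <- matrix(0L, h, w)
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  n <- params$leaf_count
  if (n > 0L) {
    states <- sample.int(3L, n, replace = TRUE, prob = params$state_probs)
    for (l in seq_len(n)) {
      theta <- 2 * pi * (l - 1) / n +
        stats::rnorm(1, sd = params$angle_jitter)
      len <- max(6, stats::rnorm(1, params$leaf_length, params$leaf_dim_sd))
      wid <- max(4, stats::rnorm(1, params$leaf_width, params$leaf_dim_sd / 2))
      d <- len / 2 + 4
      cy <- cy0 + d * sin(theta); cx <- cx0 + d * cos(theta)
      idx <- ellipse_pixels(h, w, cy, cx, len / 2, wid / 2, theta)
      if (length(idx) == 0L) next
      base <- params$state_colors[states[l], ] +
        stats::rnorm(3, sd = params$color_spread)
      grain <- params$color_spread / 5
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- base[ch] +
          if (grain > 0) stats::rnorm(length(idx), sd = grain) else 0
        img[, , ch] <- plane
      }
      labels[idx] <- states[l]
    }
  }
  img <- pmin(pmax(img * params$illumination, 0), 255)
  truth <- seg_mask(labels, "C")
  structure(list(image = img, truth = truth,
                 class_counts = mask_class_counts(truth),
                 state_colors = params$state_colors, params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene ", x$params$height, "x", x$params$width,
      ", ", x$params$leaf_count, " leaves, background ",
      x$params$background, ">\n", sep = "")
  print(x$class_counts)
  invisible(x)
}

#' Linear senescence ramp over an age range
#'
#' Builds an age-to-state-probability mapping in which the senescent share
#' rises linearly from `p_start` to `p_end` across `[age_min, age_max]`,
#' the anthocyanin share is a fixed fraction of the remainder, and green
#' tissue takes the rest — a simple stand-in for the leaf-state dynamics of
#' an aging rosette.
#'
#' @param age_min,age_max Age range the ramp spans.
#' @param p_start,p_end Senescent probability at the range ends.
#' @param antho_share Anthocyanin fraction of the non-senescent remainder.
#' @return Function `f(age)` returning `c(p_norm, p_antho, p_senesc)`.
#' @export
senescence_ramp <- function(age_min, age_max, p_start = 0.02, p_end = 0.6,
                            antho_share = 0.25) {
  force(age_min); force(age_max)
  function(age) {
    t <- (age - age_min) / (age_max - age_min)
    ps <- p_start + (p_end - p_start) * min(max(t, 0), 1)
    rest <- 1 - ps
    c(rest * (1 - antho_share), rest * antho_share, ps)
  }
}

#' Generate a time series of aging rosette scenes
#'
#' Produces `length(ages) * replicates` scenes in which leaf count grows
#' with age and the state mix follows `rate_fun(age)`, enabling
#' trend-recovery checks on the measured senescent pixel fraction. Each
#' scene gets its own RNG stream derived from `(base$seed, scene index)`,
#' so the series is reproducible independently of generation order.
#'
#' @param base A [scene_params()] template; its `leaf_count` is the count
#'   at the midpoint of the age range.
#' @param ages Strictly increasing numeric vector of ages.
#' @param rate_fun Function mapping age to a valid probability triple
#'   `c(p_norm, p_antho, p_senesc)`, e.g. from [senescence_ramp()].
#' @param replicates Scenes per age.
#' @return Tibble with one row per scene: `age`, `replicate`, `scene`
#'   (list-column of `synthetic_scene`), per-class pixel counts, and
#'   `frac_norm`, `frac_antho`, `frac_senesc` — each class's share of the
#'   non-background (plant + senescent) pixels.
#' @export
generate_time_series <- function(base, ages, rate_fun, replicates = 1L) {
  stopifnot(inherits(base, "scene_params"))
  if (length(ages) < 2L || any(diff(ages) <= 0)) {
    stop("`ages` must be strictly increasing", call. = FALSE)
  }
  n_ages <- length(ages)
  counts <- pmax(3L, round(seq(base$leaf_count * 0.6, base$leaf_count * 1.4,
                               length.out = n_ages)))
  grid <- tidyr::expand_grid(age_idx = seq_len(n_ages),
                             replicate = seq_len(replicates))
  rows <- purrr::pmap(grid, function(age_idx, replicate) {
    age <- ages[age_idx]
    probs <- rate_fun(age)
    if (length(probs) != 3L || any(probs < 0) || abs(sum(probs) - 1) > 1e-6) {
      stop("rate_fun(", age, ") is not a valid probability triple",
           call. = FALSE)
    }
    idx <- (age_idx - 1L) * replicates + replicate
    p <- base
    p$leaf_count <- counts[age_idx]
    p$state_probs <- probs
    p$seed <- derive_seed(base$seed, idx)
    sc <- generate_rosette(p)
    tally <- stats::setNames(sc$class_counts$pixels, sc$class_counts$class)
    plant_px <- sum(tally[c("class_norm", "class_antho", "class_senesc")])
    frac <- if (plant_px > 0) {
      tally[c("class_norm", "class_antho", "class_senesc")] / plant_px
    } else {
      c(NA_real_, NA_real_, NA_real_)
    }
    tibble::tibble(age = age, replicate = replicate, scene = list(sc),
                   pixels_norm = unname(tally["class_norm"]),
                   pixels_antho = unname(tally["class_antho"]),
                   pixels_senesc = unname(tally["class_senesc"]),
                   frac_norm = unname(frac[1]), frac_antho = unname(frac[2]),
                   frac_senesc = unname(frac[3]))
  })
  dplyr::bind_rows(rows)
}

#' Plot leaf-state fractions over age
#'
#' Summarizes a [generate_time_series()] tibble as the mean share of plant
#' pixels in each leaf state per age, with a normal-approximation 95%
#' confidence ribbon across replicates.
#'
#' @param ts Tibble from [generate_time_series()].
#' @return A ggplot.
#' @export
plot_class_fractions <- function(ts) {
  long <- tidyr::pivot_longer(
    ts[, c("age", "frac_norm", "frac_antho", "frac_senesc")],
    cols = -"age", names_to = "state", values_to = "fraction",
    names_prefix = "frac_")
  summ <- long |>
    dplyr::group_by(.data$age, .data$state) |>
    dplyr::summarise(
      mean = mean(.data$fraction, na.rm = TRUE),
      se = stats::sd(.data$fraction, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$fraction))),
      .groups = "drop")
  pal <- c(norm = "#2e7d32", antho = "#ad1457", senesc = "#c8a23c")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$age, y = .data$mean,
                                     color = .data$state,
                                     fill = .data$state)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                      ymax = .data$mean + 1.96 * .data$se),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "age", y = "share of plant pixels",
                  color = "leaf state", fill = "leaf state") +
    ggplot2::theme_minimal()
}

#' Write a synthetic data set to disk
#'
#' Renders `n` scenes into `outdir/images/*.png` and `outdir/masks/*.png`
#' (ground truth, scheme C) with a `truth.csv` of per-scene class pixel
#' counts — a self-contained benchmark folder for the pipeline.
#'
#' @param outdir Output directory (created if needed).
#' @param n Number of scenes.
#' @param seed Base seed; scene `i` uses a stream derived from `(seed, i)`.
#' @param preset One of `"green"` (all-green rosettes), `"mixed"`
#'   (70/20/10 state mix), `"senescing"` (35/20/45), `"timeseries"`
#'   (ages with a rising senescence ramp).
#' @param width,height Scene size in pixels.
#' @param background Background kind, see [scene_params()].
#' @return Tibble describing the written scenes (also saved as
#'   `truth.csv`), invisibly.
#' @export
simulate_dataset <- function(outdir, n = 20L, seed = 1L, preset = "mixed",
                             width = 256L, height = 256L,
                             background = "soil") {
  preset <- match.arg(preset,
                      c("green", "mixed", "senescing", "timeseries"))
  dir.create(file.path(outdir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  base <- scene_params(width = width, height = height, seed = seed,
                       background = background)
  if (preset == "timeseries") {
    ages <- seq_len(max(2L, min(10L, n)))
    reps <- max(1L, ceiling(n / length(ages)))
    ts <- generate_time_series(base, ages,
                               senescence_ramp(min(ages), max(ages)),
                               replicates = reps)
    ts <- ts[seq_len(min(n, nrow(ts))), ]
    scenes <- ts$scene
    meta <- ts[, c("age", "replicate")]
  } else {
    probs <- switch(preset,
                    green = c(1, 0, 0),
                    mixed = c(0.7, 0.2, 0.1),
                    senescing = c(0.35, 0.2, 0.45))
    scenes <- purrr::map(seq_len(n), function(i) {
      p <- base
      p$state_probs <- probs
      p$seed <- derive_seed(seed, i)
      generate_rosette(p)
    })
    meta <- tibble::tibble(age = NA_real_,
                           replicate = seq_along(scenes))
  }
  rows <- purrr::imap(scenes, function(sc, i) {
    id <- sprintf("scene_%04d", i)
    write_rgb_image(sc$image, file.path(outdir, "images",
                                        paste0(id, ".png")))
    write_mask(sc$truth, file.path(outdir, "masks", paste0(id, ".png")))
    tally <- stats::setNames(sc$class_counts$pixels, sc$class_counts$class)
    tibble::tibble(image_id = id, age = meta$age[i],
                   pixels_background = unname(tally["background"]),
                   pixels_norm = unname(tally["class_norm"]),
                   pixels_antho = unname(tally["class_antho"]),
                   pixels_senesc = unname(tally["class_senesc"]))
  })
  truth <- dplyr::bind_rows(rows)
  readr::write_csv(truth, file.path(outdir, "truth.csv"))
  invisible(truth)
}
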