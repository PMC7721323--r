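#' Create an empty confusion accumulator
#'
#' Accumulates pixel-level true-positive, false-positive and false-negative
#' counts per class over any number of image pairs, pooling pixels across
#' images before the intersection-over-union is formed.
#'
#' @param scheme A [class_scheme()] or scheme name.
#' @return An object of class `confusion_acc`.
#' @seealso [accumulate_confusion()], [mean_iou()]
#' @export
confusion_accumulator <- function(scheme) {
  scheme <- as_class_scheme(scheme)
  structure(list(
    counts = tibble::tibble(class = scheme$classes, tp = 0, fp = 0, fn = 0),
    scheme = scheme, n_images = 0L), class = "confusion_acc")
}

#' Accumulate one predicted/ground-truth mask pair
#'
#' @param acc A [confusion_accumulator()].
#' @param pred,truth [seg_mask()]s of identical shape under the
#'   accumulator's scheme.
#' @return The updated `confusion_acc`. Accumulation order is irrelevant:
#'   counts are plain sums over pixels.
#' @export
accumulate_confusion <- function(acc, pred, truth) {
  stopifnot(inherits(acc, "confusion_acc"), inherits(pred, "seg_mask"),
            inherits(truth, "seg_mask"))
  if (pred$scheme$name != acc$scheme$name ||
      truth$scheme$name != acc$scheme$name) {
    stop("mask scheme does not match accumulator scheme ", acc$scheme$name,
         call. = FALSE)
  }
  if (!identical(dim(pred$labels), dim(truth$labels))) {
    stop("prediction and truth grids differ", call. = FALSE)
  }
  for (i in seq_along(acc$scheme$classes)) {
    lab <- unname(acc$scheme$labels[i])
    p <- pred$labels == lab
    t <- truth$labels == lab
    acc$counts$tp[i] <- acc$counts$tp[i] + sum(p & t)
    acc$counts$fp[i] <- acc$counts$fp[i] + sum(p & !t)
    acc$counts$fn[i] <- acc$counts$fn[i] + sum(!p & t)
  }
  acc$n_images <- acc$n_images + 1L
  acc
}

#' Mean intersection over union
#'
#' For each class (background included) the IoU is
#' `TP / (TP + FP + FN)` on the pooled pixel counts; the mean is taken over
#' classes that occur at all (`TP + FP + FN > 0`), so absent classes do not
#' contribute 0/0 terms.
#'
#' @param acc A [confusion_accumulator()] with at least one accumulated
#'   pair.
#' @return Scalar mIoU in `[0, 1]`.
#' @examples
#' sch <- class_scheme("A")
#' truth <- seg_mask(matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4), sch)
#' pred <- truth; pred$labels[1:2, 3] <- 1L
#' acc <- accumulate_confusion(confusion_accumulator(sch), pred, truth)
#' mean_iou(acc)  # (8/10 + 6/8) / 2 = 0.775
#' @export
mean_iou <- function(acc) {
  stopifnot(inherits(acc, "confusion_acc"))
  denom <- with(acc$counts, tp + fp + fn)
  if (all(denom == 0)) {
    stop("mean IoU undefined: no class has any pixel in prediction or truth",
         call. = FALSE)
  }
  iou <- acc$counts$tp[denom > 0] / denom[denom > 0]
  mean(iou)
}

#' @export
print.confusion_acc <- function(x, ...) {
  cat("<confusion_acc scheme ", x$scheme$name, ", ", x$n_images,
      " image(s)>\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy per-class IoU from a confusion accumulator
#'
#' @param x A `confusion_acc`.
#' @param ... Unused.
#' @return Tibble with columns `class`, `tp`, `fp`, `fn`, `iou` (NA for
#'   classes absent from both prediction and truth).
#' @method tidy confusion_acc
#' @export
tidy.confusion_acc <- function(x, ...) {
  dplyr::mutate(x$counts,
                iou = ifelse(.data$tp + .data$fp + .data$fn > 0,
                             .data$tp / (.data$tp + .data$fp + .data$fn),
                             NA_real_))
}

#' One-row summary of a confusion accumulator
#'
#' @param x A `confusion_acc`.
#' @param ... Unused.
#' @return Tibble with `mean_iou`, `n_images`, `n_classes_scored`.
#' @method glance confusion_acc
#' @export
glance.confusion_acc <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(mean_iou = mean_iou(x), n_images = x$n_images,
                 n_classes_scored = sum(!is.na(td$iou)))
}

#' Agreement between two per-image plant-area measurements
#'
#' Fits an ordinary least-squares line `y ~ x` on untransformed pixel areas
#' and reports its coefficient of determination, the standard way of
#' comparing rosette-area series produced under different segmentation
#' vocabularies.
#'
#' @param areas_x,areas_y Numeric vectors of per-image areas, equal length
#'   of at least 3. `areas_x` must not be constant.
#' @return An object of class `area_agreement` wrapping the paired data and
#'   the `lm` fit; use [glance.area_agreement()] for `r.squared`,
#'   [autoplot.area_agreement()] for the scatterplot.
#' @export
area_agreement <- function(areas_x, areas_y) {
  if (length(areas_x) != length(areas_y)) {
    stop("area vectors must have equal length", call. = FALSE)
  }
  if (length(areas_x) < 3L) stop("need at least 3 images", call. = FALSE)
  if (stats::var(areas_x) == 0) {
    stop("zero variance in `areas_x`: regression undefined", call. = FALSE)
  }
  data <- tibble::tibble(x = as.numeric(areas_x), y = as.numeric(areas_y))
  fit <- stats::lm(y ~ x, data = data)
  # summary() warns on numerically perfect fits; exact agreement is a
  # legitimate outcome here (coarsening conserves areas)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(data = data, fit = fit, r_squared = r2),
            class = "area_agreement")
}

#' @export
print.area_agreement <- function(x, ...) {
  cat("<area_agreement> n = ", nrow(x$data),
      ", R^2 = ", format(x$r_squared, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy coefficients of an area-agreement fit
#' @param x An `area_agreement`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy area_agreement
#' @export
tidy.area_agreement <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2])
}

#' One-row summary of an area-agreement fit
#' @param x An `area_agreement`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `slope`, `intercept`, `n`.
#' @method glance area_agreement
#' @export
glance.area_agreement <- function(x, ...) {
  cf <- stats::coef(x$fit)
  tibble::tibble(r.squared = x$r_squared, slope = unname(cf[2]),
                 intercept = unname(cf[1]), n = nrow(x$data))
}

#' Scatterplot of an area-agreement comparison
#'
#' @param object An `area_agreement`.
#' @param ... Unused.
#' @return A ggplot: paired areas, OLS line, R^2 annotation.
#' @method autoplot area_agreement
#' @export
autoplot.area_agreement <- function(object, ...) {
  lab <- paste0("R² = ", format(object$r_squared, digits = 4))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "steelblue", linewidth = 0.6) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "plant area (px), measurement 1",
                  y = "plant area (px), measurement 2") +
    ggplot2::theme_minimal()
}

#' Evaluate predicted masks against ground truth on disk
#'
#' Pairs predicted and ground-truth mask files by file stem, accumulates
#' pixel confusion counts and reports per-class and mean IoU.
#'
#' @param pred_dir,truth_dir Directories of single-channel PNG masks.
#' @param scheme A [class_scheme()] or scheme name.
#' @return List with `per_class_iou` (named list), `mean_iou`, `n_images`,
#'   plus the underlying `confusion_acc` as attribute `"accumulator"`.
#' @export
evaluate_masks <- function(pred_dir, truth_dir, scheme = "C") {
  scheme <- as_class_scheme(scheme)
  preds <- sort(list.files(pred_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(preds) == 0L) stop("no PNG masks in ", pred_dir, call. = FALSE)
  acc <- confusion_accumulator(scheme)
  for (p in preds) {
    stem <- tools::file_path_sans_ext(basename(p))
    tpath <- file.path(truth_dir, paste0(stem, ".png"))
    if (!file.exists(tpath)) {
      stop("no ground-truth mask for image '", stem, "' in ", truth_dir,
           call. = FALSE)
    }
    acc <- accumulate_confusion(acc, load_mask(p, scheme),
                                load_mask(tpath, scheme))
  }
  td <- tidy(acc)
  out <- list(per_class_iou = as.list(stats::setNames(td$iou, td$class)),
              mean_iou = mean_iou(acc), n_images = acc$n_images)
  attr(out, "accumulator") <- acc
  out
}
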