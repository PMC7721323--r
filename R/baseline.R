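#' Convert an RGB image to CIELAB
#'
#' Standard sRGB to CIELAB conversion under the D65 white point. The a*
#' axis separates green (negative) from magenta/red (positive), which is
#' what makes Lab thresholding a useful classical plant/background
#' segmenter — and what makes it fail on anthocyanin-rich (purple) tissue.
#'
#' @param image RGB array `h x w x 3`, intensities in `[0, 255]`.
#' @return List of three matrices `l_star` (0-100), `a_star`, `b_star`.
#' @examples
#' img <- array(128, c(2, 2, 3))
#' rgb_to_lab(img)$a_star
#' @export
rgb_to_lab <- function(image) {
  check_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  srgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3])) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  list(l_star = matrix(lab[, 1], h, w),
       a_star = matrix(lab[, 2], h, w),
       b_star = matrix(lab[, 3], h, w))
}

#' Classical color-threshold segmentation (one-class baseline)
#'
#' Labels a pixel as rosette tissue when its a* value is at most `a_max`
#' (sufficiently green) and its lightness L* is at least `l_min` (not
#' shadow). The raw threshold mask is then cleaned up by keeping the
#' largest 8-connected foreground component and filling its holes, the
#' usual post-processing of classical color pipelines. This comparator
#' segments healthy green rosettes well but, by construction, loses
#' anthocyanin-rich (purple, a* > 0) and senescent tissue — the failure
#' mode that motivates leaf-state-aware segmentation.
#'
#' @param image RGB array `h x w x 3`, intensities in `[0, 255]`.
#' @param a_max Upper threshold on a* (default -8): lower = stricter green.
#' @param l_min Lower threshold on L* (default 15) to reject near-black.
#' @param postprocess Keep largest component and fill holes (default TRUE).
#' @return A scheme-A [seg_mask()].
#' @export
threshold_segment <- function(image, a_max = -8, l_min = 15,
                              postprocess = TRUE) {
  lab <- rgb_to_lab(image)
  fg <- lab$a_star <= a_max & lab$l_star >= l_min
  if (postprocess && any(fg)) {
    comp <- label_components(fg)
    sizes <- tabulate(comp[comp > 0L])
    fg <- comp == which.max(sizes)
    fg <- fill_holes(fg)
  }
  seg_mask(matrix(as.integer(fg), nrow(fg), ncol(fg)), "A")
}

resize_plane <- function(m, new_h, new_w, nearest = FALSE) {
  if (nrow(m) == new_h && ncol(m) == new_w) return(m)
  filt <- if (nearest) "none" else "bilinear"
  out <- EBImage::resize(m, w = new_h, h = new_w, filter = filt)
  matrix(as.numeric(out), new_h, new_w)
}

resize_rgb <- function(image, new_h, new_w) {
  out <- array(0, c(new_h, new_w, 3L))
  for (ch in 1:3) {
    out[, , ch] <- resize_plane(image[, , ch], new_h, new_w)
  }
  pmin(pmax(out, 0), 255)
}

#' Multi-scale inference over a pluggable pixel classifier
#'
#' Runs a per-pixel classifier at several image scales and averages the
#' class score maps at native resolution before taking the per-pixel
#' argmax — the standard trick that stabilizes semantic segmentation
#' against scale-dependent artifacts (e.g. algae speckle picked up at one
#' scale only), at proportional computational cost.
#'
#' @param classifier Function `f(image)` returning a score array
#'   `h x w x n_classes` (nonnegative, summing to 1 over classes for each
#'   pixel) with classes in the label order of `scheme`.
#' @param image RGB array `h x w x 3`.
#' @param scales Numeric vector of positive scale factors (default
#'   `c(0.5, 0.75, 1, 1.25, 1.5, 1.75)`). The image is resized by each
#'   factor (bilinear), classified, and the scores are resized back.
#' @param scheme [class_scheme()] of the classifier's output classes.
#' @return A [seg_mask()] under `scheme` from the argmax of the averaged
#'   scores (ties broken toward the lower label).
#' @export
multiscale_predict <- function(classifier, image,
                               scales = c(0.5, 0.75, 1, 1.25, 1.5, 1.75),
                               scheme = class_scheme("C")) {
  check_rgb_image(image)
  scheme <- as_class_scheme(scheme)
  if (length(scales) == 0L) stop("`scales` must be nonempty", call. = FALSE)
  if (any(scales <= 0)) stop("scale factors must be positive", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  k <- length(scheme$classes)
  acc <- array(0, c(h, w, k))
  for (s in scales) {
    hs <- max(1L, as.integer(round(h * s)))
    ws <- max(1L, as.integer(round(w * s)))
    scores <- classifier(resize_rgb(image, hs, ws))
    if (!identical(dim(scores)[3], k) && dim(scores)[3] != k) {
      stop("classifier returned ", dim(scores)[3], " classes, expected ", k,
           call. = FALSE)
    }
    for (j in seq_len(k)) {
      acc[, , j] <- acc[, , j] + resize_plane(scores[, , j], h, w)
    }
  }
  acc <- acc / length(scales)
  # renormalize per pixel (bilinear resampling preserves nonnegativity but
  # not exact unit sums)
  tot <- acc[, , 1]
  for (j in seq_len(k)[-1]) tot <- tot + acc[, , j]
  tot[tot == 0] <- 1
  labels <- matrix(0L, h, w)
  best <- acc[, , 1] / tot
  for (j in seq_len(k)[-1]) {
    sj <- acc[, , j] / tot
    gain <- sj > best
    labels[gain] <- j - 1L
    best[gain] <- sj[gain]
  }
  seg_mask(labels, scheme)
}
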