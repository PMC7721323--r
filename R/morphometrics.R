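#' Morphometric traits of one mask class
#'
#' Computes the eleven region-shape traits for all pixels of a class
#' (or of the `plant_region` compound) treated as a single region, even when
#' the pixels form several disconnected patches — the unit of phenotyping is
#' one plant per image, so whole-rosette descriptors such as the convex hull
#' span all leaves of the class.
#'
#' The traits are:
#' \describe{
#'   \item{area}{pixel count of the class.}
#'   \item{filled_area}{pixel count after filling enclosed holes
#'     (4-connected background).}
#'   \item{convex_area}{number of pixel centers inside or on the convex hull
#'     of the class's pixel centers.}
#'   \item{equivalent_diameter}{diameter of the circle with the same area,
#'     `sqrt(4 * area / pi)`.}
#'   \item{major_axis_length, minor_axis_length}{axes of the ellipse with
#'     the same normalized second central moments as the pixel set:
#'     `4 * sqrt(lambda)` for each eigenvalue `lambda` of the
#'     moment matrix divided by area.}
#'   \item{perimeter}{weighted contour-step length of the region boundary
#'     (straight step 1, diagonal `sqrt(2)`).}
#'   \item{eccentricity}{`sqrt(1 - lambda2/lambda1)`, 0 for degenerate
#'     (point-like) regions.}
#'   \item{extent}{area divided by bounding-box area.}
#'   \item{solidity}{area divided by convex area.}
#'   \item{aspect_ratio}{major over minor axis length (missing when the
#'     minor axis is 0).}
#' }
#'
#' An absent class yields `area = 0` with every other trait missing (`NA`),
#' distinguishing "no such tissue" from degenerate geometry.
#'
#' @param mask A [seg_mask()].
#' @param class_name Class of the mask's scheme, or `"plant_region"`.
#' @return A one-row tibble with the 11 trait columns above.
#' @examples
#' m <- matrix(0L, 30, 30); m[11:20, 6:25] <- 1L
#' compute_morphometrics(seg_mask(m, "A"), "class_norm")
#' @export
compute_morphometrics <- function(mask, class_name) {
  fg <- class_pixels(mask, class_name)
  n <- sum(fg)
  if (n == 0L) {
    return(tibble::tibble(
      area = 0, filled_area = NA_real_, convex_area = NA_real_,
      equivalent_diameter = NA_real_, major_axis_length = NA_real_,
      minor_axis_length = NA_real_, perimeter = NA_real_,
      eccentricity = NA_real_, extent = NA_real_, solidity = NA_real_,
      aspect_ratio = NA_real_))
  }
  pts <- which(fg, arr.ind = TRUE)
  bb <- region_bbox(fg)
  bbox_area <- (bb[2] - bb[1] + 1) * (bb[4] - bb[3] + 1)

  # ellipse with identical normalized second central moments
  r <- pts[, 1]; cc <- pts[, 2]
  mu_rr <- sum((r - mean(r))^2) / n
  mu_cc <- sum((cc - mean(cc))^2) / n
  mu_rc <- sum((r - mean(r)) * (cc - mean(cc))) / n
  tr2 <- (mu_rr + mu_cc) / 2
  det_term <- sqrt(((mu_rr - mu_cc) / 2)^2 + mu_rc^2)
  l1 <- tr2 + det_term
  l2 <- max(tr2 - det_term, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0

  hull_area <- convex_hull_area(fg)
  tibble::tibble(
    area = as.numeric(n),
    filled_area = as.numeric(sum(fill_holes(fg))),
    convex_area = as.numeric(hull_area),
    equivalent_diameter = sqrt(4 * n / pi),
    major_axis_length = major,
    minor_axis_length = minor,
    perimeter = region_perimeter(fg),
    eccentricity = ecc,
    extent = n / bbox_area,
    solidity = n / hull_area,
    aspect_ratio = if (minor > 0) major / minor else NA_real_)
}

#' Names of the morphometric trait columns
#' @return Character vector of length 11 in emission order.
#' @export
morphometric_trait_names <- function() {
  c("area", "filled_area", "convex_area", "equivalent_diameter",
    "major_axis_length", "minor_axis_length", "perimeter", "eccentricity",
    "extent", "solidity", "aspect_ratio")
}
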