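#' Mean channel intensities over one mask class
#'
#' Arithmetic mean of the red, green and blue channel of the original image
#' over exactly the pixels of a class (or of `plant_region`). An empty class
#' yields missing values.
#'
#' @param image RGB array `h x w x 3`, intensities in `[0, 255]`.
#' @param mask A [seg_mask()] on the same grid.
#' @param class_name Class of the mask's scheme, or `"plant_region"`.
#' @return One-row tibble with columns `n_red`, `n_green`, `n_blue`.
#' @export
channel_means <- function(image, mask, class_name) {
  check_rgb_image(image)
  check_same_grid(image, mask)
  fg <- class_pixels(mask, class_name)
  if (!any(fg)) {
    return(tibble::tibble(n_red = NA_real_, n_green = NA_real_,
                          n_blue = NA_real_))
  }
  tibble::tibble(n_red = mean(image[, , 1][fg]),
                 n_green = mean(image[, , 2][fg]),
                 n_blue = mean(image[, , 3][fg]))
}

#' Chroma indices from channel means
#'
#' Computes the five chroma indices from per-region channel means (the means
#' are taken first, then the indices — not per-pixel indices averaged):
#'
#' \deqn{chroma\_base = (N_{blue} + N_{red}) / N_{green}}
#' \deqn{chroma\_difference = (N_{blue} + N_{red})/2 - N_{green}}
#' \deqn{chroma\_ratio = N_{green} / ((N_{blue} + N_{red})/2)}
#' \deqn{blue\_green\_ratio = N_{blue} / N_{green}}
#' \deqn{green\_strength = N_{green} / (N_{red} + N_{green} + N_{blue})}
#'
#' The chroma ratio falls as red/blue intensity rises relative to green, so
#' it is inversely related to anthocyanin accumulation; green strength is
#' the green share of total intensity. Any index whose denominator is zero
#' is emitted as missing rather than infinite, and missing channel means
#' (empty region) propagate to all five indices. Note the algebraic tie
#' `chroma_ratio * chroma_base = 2` whenever both are defined.
#'
#' @param means One-row tibble or named list with `n_red`, `n_green`,
#'   `n_blue`, as returned by [channel_means()].
#' @return One-row tibble with columns `chroma_base`, `chroma_difference`,
#'   `chroma_ratio`, `blue_green_ratio`, `green_strength`.
#' @examples
#' chroma_indices(list(n_red = 64, n_green = 128, n_blue = 64))
#' @export
chroma_indices <- function(means) {
  r <- as.numeric(means$n_red)
  g <- as.numeric(means$n_green)
  b <- as.numeric(means$n_blue)
  safe_div <- function(num, den) {
    ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
  }
  tibble::tibble(
    chroma_base = safe_div(b + r, g),
    chroma_difference = (b + r) / 2 - g,
    chroma_ratio = safe_div(g, (b + r) / 2),
    blue_green_ratio = safe_div(b, g),
    green_strength = safe_div(g, r + g + b))
}

#' Names of the color trait columns
#' @return Character vector of length 8 in emission order.
#' @export
color_trait_names <- function() {
  c("n_red", "n_green", "n_blue", "chroma_base", "chroma_difference",
    "chroma_ratio", "blue_green_ratio", "green_strength")
}
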