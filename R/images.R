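#' Read an 8-bit RGB image
#'
#' Reads a PNG or JPEG file into a height x width x 3 numeric array with
#' intensities on the 0-255 scale. Grayscale input is replicated to three
#' channels; an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return Numeric array `h x w x 3`, values in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "': ", path, call. = FALSE)
  )
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3L) {
    stop("expected 1, 3 or 4 channels, got ", dim(px)[3], ": ", path,
         call. = FALSE)
  }
  px * 255
}

#' Write an 8-bit RGB image as PNG
#'
#' @param image Numeric array `h x w x 3`, values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(pmin(pmax(image, 0), 255) / 255, target = path)
  invisible(path)
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be a h x w x 3 array", call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

check_same_grid <- function(image, mask) {
  di <- dim(image)[1:2]
  dm <- dim(mask$labels)
  if (!identical(di, dm)) {
    stop("image grid ", paste(di, collapse = "x"),
         " does not match mask grid ", paste(dm, collapse = "x"),
         call. = FALSE)
  }
  invisible(NULL)
}
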