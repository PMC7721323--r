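#' Segmentation class schemes
#'
#' A class scheme is one of the three label vocabularies used for top-view
#' rosette segmentation masks:
#'
#' * `"A"` — one vegetative class: `background`, `class_norm` (the whole
#'   living rosette; senescent tissue is treated as background).
#' * `"B"` — two classes: `background`, `class_norm` (non-senescent),
#'   `class_senesc` (senescent/dead tissue).
#' * `"C"` — three leaf states: `background`, `class_norm` (green),
#'   `class_antho` (anthocyanin-rich), `class_senesc`.
#'
#' Integer labels are assigned consecutively from 0 in the listed order, so
#' `background` is always 0, `class_norm` is always 1, `class_antho` is 2
#' (scheme C only) and `class_senesc` is the highest label of its scheme.
#' The compound class `plant_region` is the union of `class_norm` and
#' `class_antho` where the latter exists, i.e. living (non-senescent) tissue.
#'
#' @param name Scheme name: `"A"`, `"B"` or `"C"`.
#' @return An object of class `class_scheme`: a list with elements `name`,
#'   `classes` (ordered character vector including `background`) and
#'   `labels` (named integer vector mapping class name to label).
#' @examples
#' class_scheme("C")
#' class_scheme("A")$labels
#' @export
class_scheme <- function(name = c("C", "B", "A")) {
  name <- match.arg(toupper(name), c("C", "B", "A"))
  classes <- switch(name,
    A = c("background", "class_norm"),
    B = c("background", "class_norm", "class_senesc"),
    C = c("background", "class_norm", "class_antho", "class_senesc")
  )
  labels <- stats::setNames(seq_along(classes) - 1L, classes)
  structure(list(name = name, classes = classes, labels = labels),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme ", x$name, "> ",
      paste0(x$classes, "=", x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_class_scheme <- function(scheme) {
  if (inherits(scheme, "class_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) return(class_scheme(scheme))
  stop("`scheme` must be a class_scheme or one of \"A\", \"B\", \"C\"",
       call. = FALSE)
}

#' Non-background classes of a scheme
#'
#' @param scheme A [class_scheme()] or scheme name.
#' @return Character vector of the scheme's vegetative + senescent classes
#'   (everything except `background`).
#' @export
scheme_classes <- function(scheme) {
  scheme <- as_class_scheme(scheme)
  setdiff(scheme$classes, "background")
}

#' Construct a segmentation mask
#'
#' Wraps an integer label matrix together with its [class_scheme()],
#' validating that every label belongs to the scheme's vocabulary (labels
#' are mutually exclusive per pixel by construction: one integer per pixel).
#' Pixels are indexed 0-based in concept, row-major with origin at the
#' top-left, i.e. plain R matrix order.
#'
#' @param labels Integer matrix (height x width) of class labels.
#' @param scheme A [class_scheme()] or scheme name.
#' @return An object of class `seg_mask`: list with `labels` (integer
#'   matrix) and `scheme`.
#' @examples
#' m <- matrix(0L, 4, 4); m[2:3, 2:3] <- 1L
#' seg_mask(m, "A")
#' @export
seg_mask <- function(labels, scheme) {
  scheme <- as_class_scheme(scheme)
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(scheme$labels))
  if (length(bad) > 0L) {
    stop("label value(s) ", paste(sort(bad), collapse = ", "),
         " not in scheme ", scheme$name,
         " (valid: ", paste(scheme$labels, collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(labels = labels, scheme = scheme), class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$scheme$labels,
                      labels = x$scheme$classes))
  cat("<seg_mask ", nrow(x$labels), "x", ncol(x$labels),
      ", scheme ", x$scheme$name, ">\n", sep = "")
  print(tab)
  invisible(x)
}

#' @export
dim.seg_mask <- function(x) dim(x$labels)

#' Read a segmentation mask from a PNG file
#'
#' Masks are stored as single-channel 8-bit PNG files whose pixel values are
#' the integer class labels of the scheme (background = 0). Multi-channel
#' files and out-of-vocabulary labels are rejected.
#'
#' @param path Path to a single-channel PNG file.
#' @param scheme A [class_scheme()] or scheme name.
#' @return A [seg_mask()].
#' @seealso [write_mask()]
#' @export
load_mask <- function(path, scheme) {
  scheme <- as_class_scheme(scheme)
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L) {
      stop("mask must be single-channel, got ", dim(px)[3],
           " channels: ", path, call. = FALSE)
    }
    px <- px[, , 1L]
  }
  labels <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  tryCatch(seg_mask(labels, scheme),
           error = function(e) stop("invalid mask ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a segmentation mask to a PNG file
#'
#' @param mask A [seg_mask()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  png::writePNG(mask$labels / 255, target = path)
  invisible(path)
}

#' Coarsen a mask to a less detailed class scheme
#'
#' Merges classes according to the scheme hierarchy: going C to B the
#' anthocyanin class is folded into `class_norm`; going to A the senescent
#' class additionally becomes `background`, since the one-class vocabulary
#' covers only non-senescent rosette tissue. Pixel counts are conserved by
#' the merge: every source pixel maps to exactly one target label.
#' Refinement (e.g. A to C) is not defined and raises an error.
#'
#' @param mask A [seg_mask()].
#' @param target Target [class_scheme()] or scheme name; must be strictly
#'   coarser than the mask's scheme (C->B, C->A or B->A).
#' @return A [seg_mask()] under `target`.
#' @examples
#' m <- matrix(0L, 4, 5); m[1, 1:3] <- 1L; m[2, 1:2] <- 2L; m[3, 1] <- 3L
#' cm <- seg_mask(m, "C")
#' table(coarsen_mask(cm, "B")$labels)
#' @export
coarsen_mask <- function(mask, target) {
  stopifnot(inherits(mask, "seg_mask"))
  target <- as_class_scheme(target)
  src <- mask$scheme
  rank <- c(A = 1L, B = 2L, C = 3L)
  if (rank[[target$name]] >= rank[[src$name]]) {
    stop("unsupported direction: can only coarsen (C->B, C->A, B->A), got ",
         src$name, "->", target$name, call. = FALSE)
  }
  # class-name level merge map, then translated to integer labels
  map <- vapply(src$classes, function(cl) {
    if (cl %in% target$classes) return(cl)
    if (cl == "class_antho") return("class_norm")   # antho folds into norm
    if (cl == "class_senesc") return("background")  # scheme A drops senescence
    cl
  }, character(1))
  lut <- unname(target$labels[map[match(as.vector(mask$labels),
                                        unname(src$labels))]])
  seg_mask(matrix(as.integer(lut), nrow(mask$labels), ncol(mask$labels)),
           target)
}

#' Per-class pixel counts of a mask
#'
#' @param mask A [seg_mask()].
#' @return A tibble with columns `class` and `pixels`, one row per scheme
#'   class (including `background`), plus a `plant_region` row.
#' @export
mask_class_counts <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sch <- mask$scheme
  counts <- vapply(sch$classes,
                   function(cl) sum(mask$labels == sch$labels[[cl]]),
                   integer(1))
  pr <- sum(counts[intersect(c("class_norm", "class_antho"), sch$classes)])
  tibble::tibble(class = c(sch$classes, "plant_region"),
                 pixels = c(unname(counts), pr))
}

#' Logical pixel membership of a class (or the plant_region compound)
#'
#' @param mask A [seg_mask()].
#' @param class_name A class of the mask's scheme, or `"plant_region"`
#'   (union of `class_norm` and `class_antho` where present).
#' @return Logical matrix, `TRUE` where the pixel belongs to the class.
#' @export
class_pixels <- function(mask, class_name) {
  stopifnot(inherits(mask, "seg_mask"))
  sch <- mask$scheme
  if (class_name == "plant_region") {
    members <- intersect(c("class_norm", "class_antho"), sch$classes)
    return(matrix(mask$labels %in% unname(sch$labels[members]),
                  nrow(mask$labels), ncol(mask$labels)))
  }
  if (!class_name %in% sch$classes) {
    stop("unknown class '", class_name, "' for scheme ", sch$name,
         call. = FALSE)
  }
  mask$labels == sch$labels[[class_name]]
}
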