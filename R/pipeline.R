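#' Trait column names of a results table
#'
#' One block of 19 traits (11 morphometric + 3 channel means + 5 chroma
#' indices) per non-background class plus the `plant_region` compound,
#' followed by the two whole-image traits — 78 columns for scheme C, 59 for
#' B, 40 for A (excluding the `image_id` identifier).
#'
#' @param scheme A [class_scheme()] or scheme name.
#' @return Character vector of column names in emission order.
#' @export
trait_column_names <- function(scheme) {
  scheme <- as_class_scheme(scheme)
  blocks <- c(scheme_classes(scheme), "plant_region")
  traits <- c(morphometric_trait_names(), color_trait_names())
  c(as.vector(vapply(blocks, function(b) paste(b, traits, sep = "_"),
                     character(length(traits)))),
    "total_area", "background_area")
}

#' Extract the full trait record of one image
#'
#' Computes, for every non-background class of the mask's scheme and for
#' the `plant_region` compound, the 11 morphometric and 8 color traits,
#' plus the whole-image `total_area` (all non-background pixels) and
#' `background_area`. Absent classes yield `area = 0` and missing values
#' for the remaining traits of their block.
#'
#' @param image RGB array `h x w x 3`, intensities in `[0, 255]`.
#' @param mask A [seg_mask()] on the same grid.
#' @param image_id Identifier for the record (file stem in pipeline runs).
#' @return A one-row tibble: `image_id` followed by the
#'   [trait_column_names()] of the scheme.
#' @examples
#' sc <- generate_rosette(scene_params(width = 96, height = 96, seed = 3))
#' rec <- process_image(sc$image, sc$truth, "demo")
#' ncol(rec) - 1  # 78 trait columns for scheme C
#' @export
process_image <- function(image, mask, image_id = NA_character_) {
  check_rgb_image(image)
  check_same_grid(image, mask)
  blocks <- c(scheme_classes(mask$scheme), "plant_region")
  parts <- purrr::map(blocks, function(cl) {
    block <- dplyr::bind_cols(
      compute_morphometrics(mask, cl),
      {
        cm <- channel_means(image, mask, cl)
        dplyr::bind_cols(cm, chroma_indices(cm))
      })
    stats::setNames(block, paste(cl, names(block), sep = "_"))
  })
  total <- sum(mask$labels != 0L)
  dplyr::bind_cols(
    tibble::tibble(image_id = image_id),
    purrr::list_cbind(parts),
    tibble::tibble(total_area = as.numeric(total),
                   background_area = as.numeric(length(mask$labels) - total)))
}

#' Split image paths into equally sized batches
#'
#' Scatter step of the scatter-gather pipeline: paths are put in
#' deterministic lexicographic order and split into `ceiling(n/batch_size)`
#' consecutive batches, all of size `batch_size` except possibly the last.
#'
#' @param paths Character vector of input image paths (nonempty).
#' @param batch_size Positive integer.
#' @return A tibble of class `batch_plan` with columns `path` and `batch`;
#'   attribute `batch_size` records the requested size.
#' @examples
#' scatter(sprintf("img%03d.png", 1:7), batch_size = 3)
#' @export
scatter <- function(paths, batch_size) {
  if (length(paths) == 0L) stop("no input images", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  paths <- sort(paths)
  plan <- tibble::tibble(
    path = paths,
    batch = ((seq_along(paths) - 1L) %/% as.integer(batch_size)) + 1L)
  attr(plan, "batch_size") <- as.integer(batch_size)
  class(plan) <- c("batch_plan", class(plan))
  plan
}

#' Merge per-batch trait tables into the final results table
#'
#' Gather step: binds the per-batch tibbles, restores the original
#' (lexicographic) input order regardless of batch completion order, and
#' rejects duplicate image identifiers.
#'
#' @param batch_results List of tibbles as produced by [process_image()].
#' @param image_ids Optional character vector giving the original input
#'   order; defaults to sorting by `image_id`.
#' @return One tibble, one row per input image.
#' @export
gather <- function(batch_results, image_ids = NULL) {
  out <- dplyr::bind_rows(batch_results)
  dup <- out$image_id[duplicated(out$image_id)]
  if (length(dup) > 0L) {
    stop("duplicate image_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(image_ids)) {
    out <- dplyr::arrange(out, .data$image_id)
  } else {
    out <- out[match(image_ids, out$image_id), ]
  }
  tibble::as_tibble(out)
}

diagnostic_palette <- function() {
  rbind(class_norm = c(0, 200, 0),
        class_antho = c(255, 0, 255),
        class_senesc = c(255, 215, 0))
}

draw_polyline <- function(img, ys, xs, color = c(255, 255, 255)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  m <- length(ys)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    steps <- max(abs(ys[j] - ys[i]), abs(xs[j] - xs[i])) + 1L
    ry <- round(seq(ys[i], ys[j], length.out = steps))
    rx <- round(seq(xs[i], xs[j], length.out = steps))
    keep <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
    idx <- (rx[keep] - 1L) * h + ry[keep]
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[idx] <- color[ch]; img[, , ch] <- plane
    }
  }
  img
}

#' Render the diagnostic image set for one segmentation
#'
#' Produces the four standard quality-control panels: (1) the original
#' image with class colors alpha-blended on top, (2) the color-coded mask
#' alone, (3) the background-subtracted crop of the `plant_region` (living
#' tissue on black, cut to its bounding box; a fully black frame when the
#' plant region is empty), and (4) the original image with the
#' `plant_region` convex hull outlined. The palette is fixed: green tissue
#' green, anthocyanin-rich magenta, senescent gold.
#'
#' @param image RGB array `h x w x 3`.
#' @param mask A [seg_mask()] on the same grid.
#' @param outdir Directory to write into (created if needed).
#' @param image_id File stem for the four PNGs
#'   (`<id>_overlay/mask/crop/hull.png`).
#' @param alpha Overlay opacity of the class colors.
#' @return Named character vector of the four written paths, invisibly.
#' @export
render_diagnostics <- function(image, mask, outdir, image_id,
                               alpha = 0.5) {
  check_rgb_image(image)
  check_same_grid(image, mask)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pal <- diagnostic_palette()
  h <- dim(image)[1]; w <- dim(image)[2]

  overlay <- image
  mask_img <- array(0, c(h, w, 3L))
  for (cl in intersect(rownames(pal), mask$scheme$classes)) {
    px <- class_pixels(mask, cl)
    if (!any(px)) next
    for (ch in 1:3) {
      plane <- overlay[, , ch]
      plane[px] <- (1 - alpha) * plane[px] + alpha * pal[cl, ch]
      overlay[, , ch] <- plane
      mplane <- mask_img[, , ch]; mplane[px] <- pal[cl, ch]
      mask_img[, , ch] <- mplane
    }
  }

  pr <- class_pixels(mask, "plant_region")
  if (any(pr)) {
    bb <- region_bbox(pr)
    crop <- array(0, c(bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L, 3L))
    sub <- pr[bb[1]:bb[2], bb[3]:bb[4]]
    for (ch in 1:3) {
      plane <- image[bb[1]:bb[2], bb[3]:bb[4], ch]
      plane[!sub] <- 0
      crop[, , ch] <- plane
    }
  } else {
    crop <- array(0, c(h, w, 3L))
  }

  hull_img <- image
  if (sum(pr) >= 3L) {
    pts <- which(pr, arr.ind = TRUE)
    hv <- grDevices::chull(pts[, 2], pts[, 1])
    hull_img <- draw_polyline(hull_img, pts[hv, 1], pts[hv, 2])
  }

  paths <- c(overlay = file.path(outdir, paste0(image_id, "_overlay.png")),
             mask = file.path(outdir, paste0(image_id, "_mask.png")),
             crop = file.path(outdir, paste0(image_id, "_crop.png")),
             hull = file.path(outdir, paste0(image_id, "_hull.png")))
  write_rgb_image(overlay, paths[["overlay"]])
  write_rgb_image(mask_img, paths[["mask"]])
  write_rgb_image(crop, paths[["crop"]])
  write_rgb_image(hull_img, paths[["hull"]])
  invisible(paths)
}

#' One-hot pixel classifier from the Lab threshold baseline
#'
#' Wraps [threshold_segment()] (without post-processing) as a score-map
#' classifier usable with [multiscale_predict()]: each pixel scores 1 for
#' its thresholded class (background or rosette) and 0 for the other.
#'
#' @param a_max,l_min Thresholds, see [threshold_segment()].
#' @return Function `f(image)` returning an `h x w x 2` score array.
#' @export
lab_threshold_classifier <- function(a_max = -8, l_min = 15) {
  function(image) {
    m <- threshold_segment(image, a_max = a_max, l_min = l_min,
                           postprocess = FALSE)
    fg <- m$labels == 1L
    scores <- array(0, c(dim(fg), 2L))
    scores[, , 1][!fg] <- 1
    scores[, , 2][fg] <- 1
    scores
  }
}

#' Run the scatter-gather phenotyping pipeline over an image folder
#'
#' Lists the input images, scatters them into batches, obtains one
#' segmentation mask per image (either user-provided mask files paired by
#' file stem, or the Lab color-threshold baseline), extracts the full trait
#' record per image, and gathers everything into a single results table.
#' Optionally renders diagnostic panels and evaluates the masks against a
#' ground-truth folder. The run is fully deterministic: the same inputs and
#' configuration give a byte-identical `results.csv`, and the batch size
#' changes scheduling only, never a value.
#'
#' @param images_dir Folder of PNG/JPEG images, one plant per image.
#' @param scheme Mask vocabulary, `"A"`, `"B"` or `"C"` (forced to `"A"`
#'   when the Lab-threshold segmenter is used, which is one-class).
#' @param segmenter `"external-mask"` (read `masks_dir/<stem>.png`) or
#'   `"lab-threshold"` (run [threshold_segment()]).
#' @param masks_dir Folder of mask PNGs; required for `"external-mask"`.
#'   Every image must have a mask with the same file stem.
#' @param batch_size Images per batch (default 10).
#' @param outdir Optional output folder: `results.csv`, `diagnostics/`,
#'   `evaluation.json` are written here when given.
#' @param diagnostics Render the four diagnostic panels per image.
#' @param evaluate_dir Optional folder of ground-truth masks; when given,
#'   predictions are scored by mean IoU.
#' @param multiscale Use multi-scale score averaging for the baseline
#'   segmenter.
#' @param scales Scale factors for `multiscale`.
#' @param a_max,l_min Thresholds of the baseline segmenter.
#' @param strict Error at the end if any image failed (default TRUE);
#'   otherwise failed images are reported in `$failures` and skipped.
#' @return List with `results` (tibble), `plan` (the [scatter()] batch
#'   plan), `failures` (tibble of image_id/error), and `evaluation` (list
#'   with per-class IoU, mean IoU and image count, or NULL).
#' @export
run_pipeline <- function(images_dir,
                         scheme = "C",
                         segmenter = c("external-mask", "lab-threshold"),
                         masks_dir = NULL,
                         batch_size = 10L,
                         outdir = NULL,
                         diagnostics = FALSE,
                         evaluate_dir = NULL,
                         multiscale = FALSE,
                         scales = c(0.5, 0.75, 1, 1.25, 1.5, 1.75),
                         a_max = -8, l_min = 15,
                         strict = TRUE) {
  segmenter <- match.arg(segmenter)
  scheme <- as_class_scheme(scheme)
  if (segmenter == "lab-threshold" && scheme$name != "A") {
    message("lab-threshold is a one-class segmenter; using scheme A")
    scheme <- class_scheme("A")
  }
  if (segmenter == "external-mask" && is.null(masks_dir)) {
    stop("`masks_dir` is required with segmenter = \"external-mask\"",
         call. = FALSE)
  }
  paths <- list.files(images_dir, pattern = "\\.(png|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  plan <- scatter(paths, batch_size)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  }

  acc <- if (!is.null(evaluate_dir)) confusion_accumulator(scheme)
  failures <- list()
  batch_tables <- purrr::map(split(plan$path, plan$batch), function(batch) {
    t0 <- Sys.time()
    rows <- purrr::map(batch, function(p) {
      stem <- tools::file_path_sans_ext(basename(p))
      tryCatch({
        img <- read_rgb_image(p)
        mask <- if (segmenter == "external-mask") {
          mpath <- file.path(masks_dir, paste0(stem, ".png"))
          if (!file.exists(mpath)) {
            stop("no mask for image '", stem, "' in ", masks_dir,
                 call. = FALSE)
          }
          load_mask(mpath, scheme)
        } else if (multiscale) {
          multiscale_predict(lab_threshold_classifier(a_max, l_min), img,
                             scales = scales, scheme = scheme)
        } else {
          threshold_segment(img, a_max = a_max, l_min = l_min)
        }
        if (!is.null(evaluate_dir)) {
          tpath <- file.path(evaluate_dir, paste0(stem, ".png"))
          if (!file.exists(tpath)) {
            stop("no ground-truth mask for '", stem, "' in ", evaluate_dir,
                 call. = FALSE)
          }
          truth <- load_mask(tpath, class_scheme("C"))
          if (scheme$name != "C") truth <- coarsen_mask(truth, scheme)
          acc <<- accumulate_confusion(acc, mask, truth)
        }
        if (diagnostics && !is.null(outdir)) {
          render_diagnostics(img, mask, file.path(outdir, "diagnostics"),
                             stem)
        }
        process_image(img, mask, image_id = stem)
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          tibble::tibble(image_id = stem, error = conditionMessage(e))
        NULL
      })
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("batch of %d image(s) done in %.2fs (%d failed)",
                    length(batch), dt, sum(vapply(rows, is.null,
                                                  logical(1)))))
    dplyr::bind_rows(rows)
  })

  ids <- tools::file_path_sans_ext(basename(plan$path))
  ok_ids <- ids[!ids %in% purrr::map_chr(failures, "image_id")]
  results <- gather(batch_tables, image_ids = ok_ids)

  evaluation <- NULL
  if (!is.null(evaluate_dir) && acc$n_images > 0L) {
    td <- tidy(acc)
    evaluation <- list(
      per_class_iou = as.list(stats::setNames(td$iou, td$class)),
      mean_iou = mean_iou(acc), n_images = acc$n_images)
  }

  if (!is.null(outdir)) {
    readr::write_csv(results, file.path(outdir, "results.csv"), na = "")
    if (!is.null(evaluation)) {
      jsonlite::write_json(evaluation, file.path(outdir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  failures <- dplyr::bind_rows(failures)
  if (strict && nrow(failures) > 0L) {
    stop(nrow(failures), " image(s) failed; first: ", failures$image_id[1],
         " (", failures$error[1], ")", call. = FALSE)
  }
  list(results = results, plan = plan, failures = failures,
       evaluation = evaluation)
}
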