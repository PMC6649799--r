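#' Segment the breast from the image background
#'
#' Separates breast tissue from background and detached bright objects
#' (labels, markers) ahead of texture extraction. The background intensity
#' is referenced from the top and bottom border bands of the image (the
#' breast enters the frame from a lateral border, so those bands are
#' background on a CC view); the global threshold is the 99.5th percentile
#' order statistic of the band. Foreground pixels are labelled into
#' connected components, the largest component is retained (detached bright
#' labels are separate components and drop out), then smoothed by
#' morphological closing with a disc and hole-filled. The retained
#' component must touch exactly one lateral (left/right) image border - the
#' chest-wall side - and occupy between 5% and 95% of the frame; anything
#' else is a segmentation failure.
#'
#' Because the threshold is an order statistic and only intensity
#' comparisons are used, the mask is *exactly* invariant to any strictly
#' increasing remapping of intensities (gain, offset, gamma).
#'
#' @param image a [raw_image] (CC view) or numeric intensity matrix.
#' @param closing_radius radius in pixels of the disc used for morphological
#'   closing (default 5).
#' @param border_band height in pixels of the top/bottom background
#'   reference bands (default 3).
#' @param background_quantile order-statistic level of the background band
#'   used as the threshold (default 0.995).
#' @return An object of class `breast_mask`: list with `mask` (logical
#'   matrix), `area_fraction`, and `chest_side` (`"L"` or `"R"`, the lateral
#'   border the breast touches).
#' @export
segment_breast <- function(image, closing_radius = 5L, border_band = 3L,
                           background_quantile = 0.995) {
  if (inherits(image, "raw_image") && image$view != "CC")
    stop(.seg_error("segmentation is restricted to CC views"))
  pix <- .image_pixels(image)
  rng <- range(pix)
  if (rng[1] == rng[2])
    stop(.seg_error("image is constant: no foreground exists"))

  ## order-statistic background threshold (type 1 quantile = an observed
  ## value, so thresholding commutes with monotone intensity transforms)
  nr <- nrow(pix)
  band <- pix[c(seq_len(border_band), seq.int(nr - border_band + 1L, nr)), ]
  thr <- quantile(band, background_quantile, type = 1, names = FALSE)
  fg <- pix > thr
  if (!any(fg)) stop(.seg_error("no foreground component found"))

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)

  kern <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, shape = "disc")
  mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1), kern)) > 0.5
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5

  touches_left <- any(mask[, 1L])
  touches_right <- any(mask[, ncol(mask)])
  if (touches_left == touches_right)
    stop(.seg_error(
      "breast component must touch exactly one lateral border"))
  area_fraction <- mean(mask)
  if (area_fraction <= 0.05 || area_fraction >= 0.95)
    stop(.seg_error(sprintf(
      "segmented area fraction %.3f outside (0.05, 0.95)", area_fraction)))

  structure(list(mask = mask, area_fraction = area_fraction,
                 chest_side = if (touches_left) "L" else "R"),
            class = "breast_mask")
}

.seg_error <- function(msg) {
  structure(class = c("cirrus_segmentation_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d x %d, area fraction %.3f, chest wall %s\n",
              nrow(x$mask), ncol(x$mask), x$area_fraction, x$chest_side))
  invisible(x)
}

.mask_matrix <- function(mask) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  stopifnot(is.logical(m) | is.numeric(m))
  m > 0
}

#' Orient an image so the chest wall is on the left
#'
#' Flips image and mask horizontally when the breast touches the right
#' border, making laterality irrelevant downstream.
#'
#' @param image a [raw_image] or matrix.
#' @param mask the matching [segment_breast] result.
#' @return list with elements `image` and `mask`, chest wall on the left.
#' @export
normalize_orientation <- function(image, mask) {
  stopifnot(inherits(mask, "breast_mask"))
  if (mask$chest_side == "R") {
    image <- flip_lr(image)
    mask$mask <- mask$mask[, ncol(mask$mask):1, drop = FALSE]
    mask$chest_side <- "L"
  }
  list(image = image, mask = mask)
}

#' Quality control for a segmented mammogram
#'
#' Rejects images whose within-breast contrast range is abnormally low
#' (below `min_range_fraction` of the nominal dynamic range), MLO views, and
#' negative images (median background brighter than median breast tissue).
#'
#' @param image a [raw_image] or matrix.
#' @param mask a [segment_breast] result (or logical matrix).
#' @param min_range_fraction minimum acceptable (max - min intensity within
#'   the mask) / (2^bit_depth - 1); default 0.05.
#' @return A `qc_report`: list with `passed` (logical), `reason` (one of
#'   `ok`, `low_contrast_range`, `wrong_view`, `negative_image`,
#'   `segmentation_failed`) and `range_fraction`.
#' @export
quality_check <- function(image, mask, min_range_fraction = 0.05) {
  m <- .mask_matrix(mask)
  pix <- .image_pixels(image)
  stopifnot(identical(dim(m), dim(pix)))
  maxval <- .image_maxval(image)
  inside <- pix[m]
  range_fraction <- (max(inside) - min(inside)) / maxval

  reason <- if (inherits(image, "raw_image") && image$view != "CC") {
    "wrong_view"
  } else if (range_fraction < min_range_fraction) {
    "low_contrast_range"
  } else if (any(!m) && median(pix[!m]) > median(inside)) {
    "negative_image"
  } else "ok"

  qc_report(reason, range_fraction)
}

qc_report <- function(reason, range_fraction = NA_real_) {
  reason <- match.arg(reason, c("ok", "low_contrast_range", "segmentation_failed",
                                "wrong_view", "negative_image"))
  structure(list(passed = reason == "ok", reason = reason,
                 range_fraction = range_fraction),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s (reason: %s, range fraction %.3f)\n",
              if (x$passed) "PASSED" else "FAILED", x$reason, x$range_fraction))
  invisible(x)
}

#' Segment and QC a batch of images
#'
#' Runs [segment_breast] and [quality_check] over a list of images,
#' converting segmentation failures into QC rows rather than errors.
#'
#' @param images list of [raw_image] objects.
#' @param min_range_fraction passed to [quality_check].
#' @return list with `masks` (list, `NULL` where segmentation failed) and
#'   `qc` (data frame: image_id, woman_id, passed, reason, area_fraction,
#'   range_fraction).
#' @export
preprocess_images <- function(images, min_range_fraction = 0.05) {
  masks <- vector("list", length(images))
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    mask <- tryCatch(segment_breast(img),
                     cirrus_segmentation_error = function(e) NULL)
    rep_ <- if (is.null(mask)) qc_report("segmentation_failed")
            else quality_check(img, mask, min_range_fraction)
    if (!is.null(mask)) masks[[i]] <<- mask
    data.frame(image_id = img$image_id, woman_id = img$woman_id,
               passed = rep_$passed, reason = rep_$reason,
               area_fraction = if (is.null(mask)) NA_real_ else mask$area_fraction,
               range_fraction = rep_$range_fraction,
               stringsAsFactors = FALSE)
  })
  list(masks = masks, qc = do.call(rbind, rows))
}
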