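#' Construct a raw mammogram image
#'
#' Bundles a 2D intensity matrix with the acquisition metadata the pipeline
#' needs. Intensities are stored as nonnegative numbers in digitizer units;
#' `bit_depth` declares the nominal dynamic range `[0, 2^bit_depth - 1]`.
#' Only craniocaudal (CC) views are processed downstream; mediolateral
#' oblique (MLO) images are flagged at quality control.
#'
#' @param pixels numeric matrix of nonnegative intensities (row-major image,
#'   at least 64 x 64).
#' @param bit_depth integer in 8..16; nominal digitizer bit depth.
#' @param view `"CC"` or `"MLO"`.
#' @param laterality `"L"` or `"R"`.
#' @param image_id,woman_id identifiers (coerced to character).
#' @param visit_index integer visit number (>= 1).
#'
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, bit_depth = 12L, view = "CC", laterality = "L",
                      image_id = "img", woman_id = "w", visit_index = 1L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop("raw_image requires at least a 64 x 64 pixel grid")
  bit_depth <- as.integer(bit_depth)
  stopifnot(bit_depth >= 8L, bit_depth <= 16L)
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    stop("pixel values must lie in [0, 2^bit_depth - 1] with no missing values")
  view <- match.arg(view, c("CC", "MLO"))
  laterality <- match.arg(laterality, c("L", "R"))
  structure(
    list(pixels = pixels, bit_depth = bit_depth, view = view,
         laterality = laterality, image_id = as.character(image_id),
         woman_id = as.character(woman_id),
         visit_index = as.integer(visit_index)),
    class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image %s> woman %s visit %d: %d x %d px, %d-bit, %s view (%s)\n",
              x$image_id, x$woman_id, x$visit_index,
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$view, x$laterality))
  invisible(x)
}

## Accept either a raw_image or a bare matrix (tests and oracles use matrices).
.image_pixels <- function(image) {
  if (inherits(image, "raw_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a raw_image or a numeric matrix")
}

.image_maxval <- function(image) {
  if (inherits(image, "raw_image")) 2^image$bit_depth - 1 else max(.image_pixels(image))
}

#' Read a grayscale mammogram from PNG or TIFF
#'
#' 8- or 16-bit grayscale files are supported; RGB files are averaged to one
#' channel. Pixel values are rescaled from the file's unit range back to
#' integer digitizer units at `bit_depth`.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth declared bit depth of the stored image.
#' @inheritParams raw_image
#' @return A [raw_image].
#' @export
read_mammogram <- function(path, bit_depth = NULL, view = "CC", laterality = "L",
                           image_id = NULL, woman_id = "w", visit_index = 1L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  if (is.null(bit_depth)) bit_depth <- if (ext == "png") 8L else 16L
  pix <- round(arr * (2^bit_depth - 1))
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  raw_image(pix, bit_depth = bit_depth, view = view, laterality = laterality,
            image_id = image_id, woman_id = woman_id, visit_index = visit_index)
}

#' Write a breast mask as a 0/255 PNG
#'
#' @param mask logical matrix (or a `breast_mask`).
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Geometric transforms used by the invariance checks
#'
#' `flip_lr`/`flip_ud` mirror an image, `rotate90` rotates it
#' counter-clockwise. They operate on matrices or on `raw_image` objects
#' (metadata preserved; laterality swapped on horizontal flip).
#'
#' @param x a matrix or [raw_image].
#' @return same class as the input.
#' @export
flip_lr <- function(x) .apply_geom(x, function(m) m[, ncol(m):1, drop = FALSE],
                                   swap_lat = TRUE)

#' @rdname flip_lr
#' @export
flip_ud <- function(x) .apply_geom(x, function(m) m[nrow(m):1, , drop = FALSE])

#' @rdname flip_lr
#' @export
rotate90 <- function(x) .apply_geom(x, function(m) t(m)[ncol(m):1, , drop = FALSE])

.apply_geom <- function(x, f, swap_lat = FALSE) {
  if (inherits(x, "raw_image")) {
    x$pixels <- f(x$pixels)
    if (swap_lat) x$laterality <- if (x$laterality == "L") "R" else "L"
    x
  } else f(x)
}
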