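#' Equal-mass gray-level quantization within the breast mask
#'
#' Replaces intensities by `G` rank-based gray levels with (up to ties)
#' equal pixel mass per level. Because levels depend only on the ranking of
#' intensities inside the mask, the quantized image - and every texture
#' feature computed from it - is invariant to any strictly monotone
#' intensity transform (gain, offset, gamma), which is what makes the
#' features resistant to differences between digitizers. Pixels with equal
#' intensity always receive the same level.
#'
#' @param image a [raw_image] or numeric matrix.
#' @param mask logical matrix or [segment_breast] result; `NULL` means the
#'   whole image.
#' @param G number of gray levels (>= 2); default 64.
#' @return A `quantized_image`: list with `levels` (integer matrix, values in
#'   `1..G` inside the mask, `NA` outside) and `G`.
#' @export
quantize <- function(image, mask = NULL, G = 64L) {
  pix <- .image_pixels(image)
  m <- if (is.null(mask)) matrix(TRUE, nrow(pix), ncol(pix)) else .mask_matrix(mask)
  stopifnot(identical(dim(m), dim(pix)))
  G <- as.integer(G)
  if (G < 2L) stop("G must be at least 2")
  v <- pix[m]
  n <- length(v)
  if (length(unique(v)) < G)
    stop(sprintf("masked pixels have fewer than G = %d distinct values", G))
  ## rank-based equal-mass binning; ties share the minimum rank so equal
  ## intensities always land in the same level
  r <- rank(v, ties.method = "min")
  lev <- as.integer(floor((r - 1) * G / n) + 1L)
  out <- matrix(NA_integer_, nrow(pix), ncol(pix))
  out[m] <- lev
  structure(list(levels = out, G = G), class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %d x %d, G = %d, %d masked pixels\n",
              nrow(x$levels), ncol(x$levels), x$G, sum(!is.na(x$levels))))
  invisible(x)
}

## The four distance-d offsets whose symmetrized union is closed under 90
## degree rotations and flips: E, S, SE, SW in (drow, dcol) form.
.glcm_offsets <- function(d) {
  list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
}

#' Pooled symmetric gray-level co-occurrence matrix
#'
#' Counts ordered level pairs at the four offsets `(0,d)`, `(d,0)`, `(d,d)`,
#' `(d,-d)`, adds each pair with its reverse (symmetric counting), pools all
#' four directions into a single matrix, and normalizes to total mass 1.
#' Only pairs with both pixels inside the mask are counted. Pooling the four
#' symmetric directions makes the matrix exactly invariant to 90/180/270
#' degree rotations and to horizontal/vertical flips of the masked content.
#'
#' @param q a `quantized_image` from [quantize], or an integer matrix of
#'   levels (`NA` outside the mask).
#' @param distance pixel offset distance `d` (>= 1); default 1.
#' @return A `cooccurrence_matrix`: list with `p` (G x G probability
#'   matrix), `G`, `distance` and `offsets_used`.
#' @export
cooccurrence <- function(q, distance = 1L) {
  if (inherits(q, "quantized_image")) {
    lev <- q$levels; G <- q$G
  } else {
    lev <- q; G <- max(lev, na.rm = TRUE)
  }
  d <- as.integer(distance)
  if (d < 1L) stop("distance must be >= 1")
  nr <- nrow(lev); nc <- ncol(lev)
  counts <- matrix(0, G, G)
  for (off in .glcm_offsets(d)) {
    dr <- off[1]; dc <- off[2]
    r_lo <- max(1L, 1L - dr); r_hi <- min(nr, nr - dr)
    c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
    if (r_lo > r_hi || c_lo > c_hi) next
    r1 <- r_lo:r_hi; c1 <- c_lo:c_hi
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (b[ok] - 1L) * G + a[ok]
    tab <- tabulate(idx, nbins = G * G)
    counts <- counts + matrix(tab, G, G)
  }
  counts <- counts + t(counts)   # symmetric counting: each pair and its reverse
  tot <- sum(counts)
  if (tot == 0) stop("no valid pixel pairs inside the mask at this distance")
  structure(list(p = counts / tot, G = G, distance = d,
                 offsets_used = .glcm_offsets(d)),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("<cooccurrence_matrix> G = %d, distance = %d, 4 pooled directions\n",
              x$G, x$distance))
  invisible(x)
}

#' Extract the 20 GLCM texture features from one mammogram
#'
#' Composition [quantize] -> [cooccurrence] -> [compute_features]. The
#' result is deterministic and invariant to translation of the masked
#' content, to 90/180/270 degree rotations, to horizontal/vertical flips and
#' to strictly monotone intensity transforms.
#'
#' @inheritParams quantize
#' @inheritParams cooccurrence
#' @return Named numeric vector with the 20 features of [glcm_feature_names].
#' @export
extract_features <- function(image, mask = NULL, G = 64L, distance = 1L) {
  compute_features(cooccurrence(quantize(image, mask, G), distance))
}
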