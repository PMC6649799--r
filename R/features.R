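#' Names of the 20 GLCM texture features
#'
#' The canonical feature order used throughout the package.
#'
#' @return character vector of length 20.
#' @export
glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
    "correlation", "difference_entropy", "difference_variance",
    "dissimilarity", "energy", "entropy", "homogeneity",
    "info_correlation_1", "info_correlation_2", "maximum_probability",
    "moment_normalized_inverse_difference", "normalized_inverse_difference",
    "sum_average", "sum_variance", "sum_entropy", "variance")
}

## x*log(x) with the 0*log(0) := 0 convention
.xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Scalar texture features of a co-occurrence matrix
#'
#' Computes the 20 second-order texture statistics from a normalized
#' symmetric co-occurrence matrix `p(i,j)`, `i,j = 1..G`. Marginal means
#' `mu_x, mu_y` and SDs `sigma_x, sigma_y`, the sum distribution
#' `p_{x+y}(k), k = 2..2G`, and the absolute-difference distribution
#' `p_{x-y}(k), k = 0..G-1` are formed first; entropies use natural logs
#' with `0 log 0 := 0`.
#'
#' `correlation`, `info_correlation_1` and `info_correlation_2` are
#' undefined on a degenerate (single-level) matrix and are returned as `NA`;
#' all other features remain valid.
#'
#' @param M a `cooccurrence_matrix` from [cooccurrence], or a G x G
#'   probability matrix (nonnegative, symmetric, summing to 1).
#' @return Named numeric vector with the entries of [glcm_feature_names].
#' @export
compute_features <- function(M) {
  p <- if (inherits(M, "cooccurrence_matrix")) M$p else as.matrix(M)
  G <- nrow(p)
  stopifnot(ncol(p) == G, all(p >= 0), abs(sum(p) - 1) < 1e-8)

  i <- matrix(seq_len(G), G, G)        # row index
  j <- t(i)                            # column index
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  ## sum distribution over k = 2..2G and |difference| distribution over 0..G-1
  ksum <- 2:(2 * G)
  psum <- vapply(ksum, function(k) sum(p[i + j == k]), numeric(1))
  kdiff <- 0:(G - 1)
  pdiff <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1))

  HXY <- -sum(.xlogx(p))
  HX <- -sum(.xlogx(px)); HY <- -sum(.xlogx(py))
  pxy <- outer(px, py)
  HXY1 <- -sum(p[pxy > 0] * log(pxy[pxy > 0]))
  HXY2 <- -sum(.xlogx(pxy))

  sum_average <- sum(ksum * psum)
  degenerate <- sx * sy == 0

  out <- c(
    autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (degenerate) NA_real_
                  else sum((i - mux) * (j - muy) * p) / (sx * sy),
    difference_entropy = -sum(.xlogx(pdiff)),
    difference_variance = sum(kdiff^2 * pdiff) - sum(kdiff * pdiff)^2,
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    entropy = HXY,
    homogeneity = sum(p / (1 + (i - j)^2)),
    info_correlation_1 = if (max(HX, HY) == 0) NA_real_
                         else (HXY - HXY1) / max(HX, HY),
    info_correlation_2 = if (max(HX, HY) == 0) NA_real_
                         else sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))),
    maximum_probability = max(p),
    moment_normalized_inverse_difference = sum(p / (1 + (i - j)^2 / G^2)),
    normalized_inverse_difference = sum(p / (1 + abs(i - j) / G)),
    sum_average = sum_average,
    sum_variance = sum((ksum - sum_average)^2 * psum),
    sum_entropy = -sum(.xlogx(psum)),
    variance = sum((i - mux)^2 * p)
  )
  out[glcm_feature_names()]
}
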