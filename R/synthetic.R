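#' Configuration for the synthetic image and cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' textured breast-shaped images whose smoothness differs between cases and
#' controls, plus realistic age/BMI covariates. Textures are Gaussian random
#' fields - white noise convolved with a Gaussian kernel - because texture
#' homogeneity and contrast respond monotonically to the kernel width
#' (correlation length), giving a controllable planted risk gradient. Cases
#' draw larger correlation lengths (large, homogeneous patches), controls
#' smaller ones (scattered pattern). No anatomical realism is claimed.
#'
#' Each woman has a latent log correlation length
#' `log(width) = log(cl_control) + log(cl_case / cl_control) * case +
#' covariate terms + N(0, texture_effect_sd)`, so the planted case-control
#' separation in latent SD units is
#' `log(cl_case / cl_control) / texture_effect_sd`. With the defaults
#' (4.0 vs 4.85 pixels, SD 0.3) that separation is 0.64, i.e. a true OR per
#' adjusted SD of about 1.9 for the latent texture parameter. Setting
#' `correlation_length_case == correlation_length_control` gives a null
#' configuration.
#'
#' @param n_women number of women in the cohort (default 300).
#' @param case_fraction fraction of cases (default 0.25).
#' @param images_per_woman_range integer pair; each woman has a uniform
#'   number of mammograms in this range (default 1..10).
#' @param image_size side of the square image in pixels (default 256).
#' @param correlation_length_case,correlation_length_control mean Gaussian
#'   kernel widths (pixels) for cases and controls.
#' @param texture_effect_sd per-woman SD of the latent log correlation
#'   length (default 0.3).
#' @param age_range uniform age range in years (default 40-70).
#' @param bmi_lognormal_params `(meanlog, sdlog)` of the BMI distribution
#'   (default `log(25.5), 0.15`).
#' @param covariate_slopes length-2 vector: effect of standardized age and
#'   standardized log BMI on the latent log width (default -0.05 each,
#'   mirroring the weak negative density-age/BMI association).
#' @param label_artifact_prob probability a rendered image carries a bright
#'   label rectangle outside the breast (default 0.15).
#' @param noise_sd additive sensor noise SD on the unit intensity scale
#'   (default 0.01).
#' @param bit_depth digitizer bit depth of rendered images (default 12).
#' @param density_cor correlation between the latent texture parameter and
#'   the synthetic conventional-density surrogate (default 0.45).
#' @param seed integer seed stored with the config.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_women = 300L, case_fraction = 0.25,
                             images_per_woman_range = c(1L, 10L),
                             image_size = 256L,
                             correlation_length_case = 4.85,
                             correlation_length_control = 4.0,
                             texture_effect_sd = 0.3,
                             age_range = c(40, 70),
                             bmi_lognormal_params = c(log(25.5), 0.15),
                             covariate_slopes = c(-0.05, -0.05),
                             label_artifact_prob = 0.15,
                             noise_sd = 0.01, bit_depth = 12L,
                             density_cor = 0.45, seed = 1L) {
  stopifnot(case_fraction > 0, case_fraction < 1,
            correlation_length_case > 0, correlation_length_control > 0,
            texture_effect_sd > 0, image_size >= 64,
            length(images_per_woman_range) == 2,
            images_per_woman_range[1] >= 1,
            images_per_woman_range[2] >= images_per_woman_range[1])
  structure(as.list(environment()), class = "synthetic_config")
}

## wrapped Gaussian random field with correlation length `width` (pixels)
.gaussian_field <- function(S, width) {
  noise <- matrix(rnorm(S * S), S, S)
  if (width <= 0) return(matrix(0, S, S))
  idx <- 0:(S - 1)
  d <- pmin(idx, S - idx)
  k1 <- exp(-d^2 / (2 * width^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / S^2
  s <- sd(sm)
  if (s > 0) sm / s else sm
}

## half-ellipse breast support attached to the left border
.breast_support <- function(S) {
  row <- matrix(seq_len(S), S, S)
  col <- t(row)
  ((col - 1) / (0.72 * S))^2 + ((row - S / 2) / (0.42 * S))^2 <= 1
}

#' Render one synthetic mammogram
#'
#' A Gaussian-random-field texture with the woman's correlation length,
#' masked to a half-ellipse breast phantom attached to the left image
#' border against a dark background, with additive sensor noise and an
#' optional detached bright label rectangle. Uses the current RNG state;
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param width texture correlation length in pixels (>= 0; 0 gives a
#'   constant breast interior).
#' @param config a [synthetic_config].
#' @param with_label force the label artifact on (`TRUE`), off (`FALSE`),
#'   or draw it with probability `config$label_artifact_prob` (`NULL`).
#' @inheritParams raw_image
#' @return list with `image` (a [raw_image]) and `truth_mask` (logical
#'   matrix, the phantom's exact support).
#' @export
generate_image <- function(width, config = synthetic_config(),
                           with_label = NULL, image_id = "img", woman_id = "w",
                           visit_index = 1L, laterality = "L") {
  S <- as.integer(config$image_size)
  support <- .breast_support(S)
  field <- .gaussian_field(S, width)
  img <- matrix(0.03, S, S)
  img[support] <- pmin(0.98, pmax(0.08, 0.5 + 0.16 * field[support]))
  if (is.null(with_label)) with_label <- runif(1) < config$label_artifact_prob
  if (isTRUE(with_label)) {
    rows <- 10:29
    cols <- (S - 45):(S - 6)
    img[rows, cols] <- 0.95
  }
  if (config$noise_sd > 0)
    img <- img + rnorm(S * S, sd = config$noise_sd)
  maxval <- 2^config$bit_depth - 1
  img[img < 0] <- 0
  img[img > 1] <- 1
  pix <- round(img * maxval)
  list(image = raw_image(pix, bit_depth = config$bit_depth, view = "CC",
                         laterality = laterality, image_id = image_id,
                         woman_id = woman_id, visit_index = visit_index),
       truth_mask = support)
}

#' Generate a synthetic case-control cohort
#'
#' Draws per-woman covariates (age uniform, BMI lognormal), case status at
#' the configured fraction, and a latent texture parameter whose mean
#' differs between cases and controls (see [synthetic_config]). Mammograms
#' are produced either as rendered images (`mode = "image"`), as feature
#' rows drawn directly from a calibrated multivariate-normal emulation of
#' the image pipeline (`mode = "feature"`, much faster), or as a mix
#' (`mode = "mixed"`: a fraction of women rendered, the rest at feature
#' level). Feature-level draws use a two-block correlation structure: the
#' 11 smoothness-driven features are mutually highly correlated, the
#' remaining 9 form a second correlated block, with weak cross-block
#' correlation.
#'
#' Synthetic conventional-density surrogates (`absolute_density` in cm^2,
#' `percent_density` in %) correlated with the latent texture parameter are
#' included in the cohort table.
#'
#' @param config a [synthetic_config].
#' @param mode `"feature"`, `"image"` or `"mixed"`.
#' @param image_fraction fraction of women rendered as images in mixed mode
#'   (default 0.1).
#' @return list with
#'   `cohort` (woman_id, status, age, bmi, absolute_density,
#'   percent_density), `mammograms` (feature rows: image_id, woman_id,
#'   visit_index, 20 features; feature-level women only), `images` (list of
#'   [generate_image] results; rendered women only) and `truth` (woman_id,
#'   theta, width, imaged).
#' @export
generate_cohort <- function(config = synthetic_config(),
                            mode = c("feature", "image", "mixed"),
                            image_fraction = 0.1) {
  mode <- match.arg(mode)
  set.seed(as.integer(config$seed))
  n <- as.integer(config$n_women)
  n_cases <- max(1L, round(n * config$case_fraction))
  status <- rep("control", n)
  status[sample.int(n, n_cases)] <- "case"
  age <- runif(n, config$age_range[1], config$age_range[2])
  bmi <- rlnorm(n, config$bmi_lognormal_params[1], config$bmi_lognormal_params[2])

  zage <- as.numeric(scale(age))
  zbmi <- as.numeric(scale(log(bmi)))
  delta_lw <- log(config$correlation_length_case /
                  config$correlation_length_control)
  lw <- log(config$correlation_length_control) +
    delta_lw * (status == "case") +
    config$covariate_slopes[1] * zage + config$covariate_slopes[2] * zbmi +
    rnorm(n, sd = config$texture_effect_sd)
  width <- pmin(16, pmax(0.5, exp(lw)))
  theta <- (lw - log(config$correlation_length_control)) / config$texture_effect_sd

  ## conventional-density surrogate, correlated with the latent texture
  dlat <- config$density_cor * scale(theta)[, 1] +
    sqrt(max(0, 1 - config$density_cor^2)) * rnorm(n)
  percent_density <- pmin(95, pmax(1, 30 + 12 * dlat))
  absolute_density <- percent_density / 100 * runif(n, 80, 200)

  imaged <- switch(mode,
    feature = rep(FALSE, n),
    image = rep(TRUE, n),
    mixed = seq_len(n) %in% sample.int(n, max(1L, round(n * image_fraction))))

  n_img <- sample(seq.int(config$images_per_woman_range[1],
                          config$images_per_woman_range[2]),
                  n, replace = TRUE)

  feat_rows <- list()
  images <- list()
  for (w in seq_len(n)) {
    wid <- sprintf("w%04d", w)
    for (k in seq_len(n_img[w])) {
      iid <- sprintf("%s_m%02d", wid, k)
      lat <- if (k %% 2 == 0) "R" else "L"
      if (imaged[w]) {
        images[[length(images) + 1L]] <-
          generate_image(width[w], config, image_id = iid, woman_id = wid,
                         visit_index = k, laterality = lat)
      } else {
        fv <- .draw_feature_vector(lw[w])
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          image_id = iid, woman_id = wid, visit_index = k, t(fv),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    cohort = data.frame(woman_id = sprintf("w%04d", seq_len(n)),
                        status = status, age = age, bmi = bmi,
                        absolute_density = absolute_density,
                        percent_density = percent_density,
                        stringsAsFactors = FALSE),
    mammograms = if (length(feat_rows)) do.call(rbind, feat_rows) else NULL,
    images = images,
    truth = data.frame(woman_id = sprintf("w%04d", seq_len(n)),
                       theta = theta, width = width, imaged = imaged,
                       stringsAsFactors = FALSE))
}

## One per-mammogram feature vector from the calibrated linear emulation of
## the image pipeline: mean response mu0 + slope_lw * (log width - log 4),
## plus per-image noise with the two-block correlation structure. mu0 and
## slope_lw come from regressing pipeline-extracted features on log width
## over the working range of the generator; noise_sd is the per-image
## replicate SD at fixed width.
.draw_feature_vector <- function(lw) {
  par <- .glcm_response_params()
  g0 <- rnorm(1); g1 <- rnorm(1); g2 <- rnorm(1)
  e <- rnorm(nrow(par))
  shared <- ifelse(par$block == 1,
                   par$sign * (sqrt(0.72) * g1 + sqrt(0.20) * g0),
                   sqrt(0.60) * g2 + sqrt(0.20) * g0)
  unique_sd <- ifelse(par$block == 1, sqrt(0.08), sqrt(0.20))
  eps <- shared + unique_sd * e
  val <- par$mu0 + par$slope_lw * (lw - log(4)) + par$noise_sd * eps
  setNames(val, par$feature)
}
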