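#' Extract per-mammogram features from a batch of images
#'
#' Runs segmentation, quality control and GLCM feature extraction over a
#' list of images. QC-failing images get no feature row.
#'
#' @param images list of [raw_image] objects (or [generate_image] results).
#' @param G,distance passed to [extract_features].
#' @param min_range_fraction passed to [quality_check].
#' @return list with `features` (data frame: image_id, woman_id,
#'   visit_index, 20 feature columns) and `qc` (data frame from
#'   [preprocess_images]).
#' @export
extract_cohort_features <- function(images, G = 64L, distance = 1L,
                                    min_range_fraction = 0.05) {
  images <- lapply(images, function(x) if (inherits(x, "raw_image")) x else x$image)
  prep <- preprocess_images(images, min_range_fraction)
  rows <- lapply(seq_along(images), function(i) {
    if (!prep$qc$passed[i]) return(NULL)
    img <- images[[i]]
    fv <- extract_features(img, prep$masks[[i]], G = G, distance = distance)
    data.frame(image_id = img$image_id, woman_id = img$woman_id,
               visit_index = img$visit_index, t(fv), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       qc = prep$qc)
}

#' Run the full texture risk pipeline on a synthetic or assembled cohort
#'
#' From per-mammogram material to a risk gradient: extract features from any
#' rendered images, pool them with feature-level rows, aggregate to one
#' record per woman ([aggregate_median]), fit the Bayesian lasso on the
#' training rows, score every woman ([bayes_lasso_score]), adjust scores for
#' age and BMI among controls ([opera_adjust]) and estimate the OR per
#' adjusted SD ([adjusted_or]) together with the empirical AUC.
#'
#' Fitting and evaluating on the same women is optimistic: the learned
#' score correlates with case status in-sample even when no true gradient
#' exists. `eval = "split"` therefore fits on a random half of the women
#' and estimates the OR/AUC on the held-out half (the honest analogue of
#' training on one study and testing on another); `eval = "insample"`
#' mirrors a combined-data fit evaluated on itself.
#'
#' @param cohort_data a [generate_cohort] result, or a list with elements
#'   `cohort`, `mammograms` (and optionally `images`).
#' @param n_draws,n_burnin,seed passed to [bayes_lasso_fit].
#' @param G,distance passed to feature extraction for rendered images.
#' @param eval `"insample"` (fit and evaluate on all women) or `"split"`
#'   (fit on a seeded random half, evaluate on the other half).
#' @return list with `fit`, `per_woman` (aggregated features merged with
#'   covariates), `scores`, `adjusted`, `or_result`, `auc`, `qc`,
#'   `eval_ids` (woman_ids used for evaluation).
#' @export
run_pipeline <- function(cohort_data, n_draws = 10000L, n_burnin = 1000L,
                         seed = 1L, G = 64L, distance = 1L,
                         eval = c("insample", "split")) {
  eval <- match.arg(eval)
  mam <- cohort_data$mammograms
  qc <- NULL
  if (length(cohort_data$images)) {
    ex <- extract_cohort_features(cohort_data$images, G = G, distance = distance)
    mam <- rbind(mam, ex$features)
    qc <- ex$qc
  }
  stopifnot(!is.null(mam), nrow(mam) > 0)
  per_woman <- aggregate_median(mam)
  per_woman <- merge(per_woman, cohort_data$cohort, by = "woman_id")
  feats <- per_woman[, glcm_feature_names(), drop = FALSE]

  if (eval == "split") {
    set.seed(as.integer(seed) + 10000L)
    train_idx <- sample.int(nrow(per_woman), floor(nrow(per_woman) / 2))
    test_idx <- setdiff(seq_len(nrow(per_woman)), train_idx)
  } else {
    train_idx <- test_idx <- seq_len(nrow(per_woman))
  }

  fit <- bayes_lasso_fit(feats[train_idx, , drop = FALSE],
                         per_woman$status[train_idx], n_draws = n_draws,
                         n_burnin = n_burnin, seed = seed)
  scores <- bayes_lasso_score(fit, feats)
  ev <- per_woman[test_idx, , drop = FALSE]
  adjusted_ev <- opera_adjust(scores[test_idx], ev$age, ev$bmi, ev$status)
  orr <- adjusted_or(adjusted_ev, ev$status, ev$age, ev$bmi)
  auc <- empirical_auc(adjusted_ev, ev$status)
  adjusted <- rep(NA_real_, nrow(per_woman))
  adjusted[test_idx] <- adjusted_ev
  list(fit = fit, per_woman = per_woman, scores = scores, adjusted = adjusted,
       or_result = orr, auc = auc, qc = qc, eval_ids = ev$woman_id)
}

#' Serialize a fitted model to a flat JSON artifact
#'
#' Stores posterior summaries (not the raw draws), the training
#' standardization and the sampler settings, enough to reproduce scoring
#' exactly with [bayes_lasso_score].
#'
#' @param fit a [bayes_lasso_fit].
#' @param path output `.json` path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "bayes_lasso_fit"))
  obj <- list(
    features = fit$standardization$features,
    coef_mean = unname(fit$coef_mean),
    coef_sd = unname(fit$coef_sd),
    intercept_mean = fit$intercept_mean,
    center = unname(fit$standardization$center),
    scale = unname(fit$standardization$scale),
    lambda2_mean = mean(fit$lambda2_samples),
    rhat = unname(fit$rhat),
    n_draws = fit$n_draws, n_burnin = fit$n_burnin, seed = fit$seed,
    n = fit$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @param path path of a JSON file written by [write_fit_json].
#' @return `read_fit_json` returns a reduced `bayes_lasso_fit` (summaries
#'   only; no posterior draws) usable with [bayes_lasso_score].
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coef_mean = setNames(obj$coef_mean, obj$features),
    coef_sd = setNames(obj$coef_sd, obj$features),
    intercept_mean = obj$intercept_mean,
    coefficient_samples = NULL, intercept_samples = NULL,
    lambda2_samples = obj$lambda2_mean,
    rhat = setNames(obj$rhat, obj$features),
    standardization = list(center = setNames(obj$center, obj$features),
                           scale = setNames(obj$scale, obj$features),
                           features = obj$features),
    n_draws = obj$n_draws, n_burnin = obj$n_burnin, seed = obj$seed,
    n = obj$n),
    class = "bayes_lasso_fit")
}

#' ROC curve coordinates for a score
#'
#' Sensitivity/1-specificity pairs over all score thresholds, for plotting
#' receiver operator curves.
#'
#' @param scores numeric risk scores.
#' @param status case indicator.
#' @return data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(scores, status) {
  status <- .as_case_indicator(status)
  ok <- complete.cases(scores, status)
  scores <- scores[ok]; status <- status[ok]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[status == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[status == 0] < t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}
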