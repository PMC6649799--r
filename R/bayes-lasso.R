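#' Fit a Bayesian lasso logistic regression
#'
#' Posterior sampling for a logistic regression of case status on
#' standardized texture features under independent Laplace
#' (double-exponential) shrinkage priors. The Laplace prior is represented
#' as a normal scale mixture with exponential mixing; the global
#' regularization parameter `lambda^2` carries a Gamma hyperprior and is
#' sampled alongside the coefficients, so the penalty strength is estimated
#' from the data. The logistic likelihood is handled by Polya-Gamma data
#' augmentation, giving a fully Gibbs sampler with no tuning. The intercept
#' is unpenalized (flat prior).
#'
#' Features are standardized to zero mean and unit SD on the supplied
#' (training) sample - cases and controls combined - before sampling, so
#' posterior-mean coefficients are standardized weights. Shrinkage keeps
#' the fit stable under heavy collinearity and under separation.
#'
#' Rows with any missing feature are excluded from training with a message.
#' A split-chain potential-scale-reduction diagnostic above 1.1 on any
#' coefficient raises a warning (not an error).
#'
#' @param X numeric matrix or data frame of per-woman features (columns
#'   named).
#' @param y case indicator: logical, 0/1, or `"case"`/`"control"`.
#' @param n_draws total MCMC draws (default 10000).
#' @param n_burnin draws discarded as burn-in (default 1000).
#' @param seed integer seed; the fit is bit-reproducible given the seed.
#' @param lambda_a,lambda_b shape and rate of the Gamma hyperprior on
#'   `lambda^2` (defaults 1, 1: diffuse).
#' @return A `bayes_lasso_fit`: list with `coef_mean`, `coef_sd`
#'   (posterior mean/SD of standardized-scale coefficients),
#'   `intercept_mean`, `coefficient_samples`, `intercept_samples`,
#'   `lambda2_samples`, `rhat`, `standardization` (`center`, `scale`,
#'   `features`), `n_draws`, `n_burnin`, `seed`.
#' @export
bayes_lasso_fit <- function(X, y, n_draws = 10000L, n_burnin = 1000L,
                            seed = 1L, lambda_a = 1, lambda_b = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  y <- .as_case_indicator(y)
  stopifnot(nrow(X) == length(y), n_draws > n_burnin, n_burnin >= 0)
  ok <- complete.cases(X) & !is.na(y)
  if (any(!ok)) message(sum(!ok), " rows with missing features excluded from training")
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 cases and 2 controls")

  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  if (any(scale_ == 0))
    stop("constant feature column(s): ",
         paste(colnames(X)[scale_ == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")

  set.seed(as.integer(seed))
  draws <- .bayes_lasso_gibbs(Xs, as.numeric(y), as.integer(n_draws),
                              as.integer(n_burnin), lambda_a, lambda_b)
  B <- draws$beta
  colnames(B) <- colnames(X)
  rhat <- apply(B, 2, .split_rhat)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("possible non-convergence: split-chain Rhat > 1.1 for ",
            paste(colnames(X)[rhat > 1.1], collapse = ", "))

  structure(list(
    coef_mean = colMeans(B),
    coef_sd = apply(B, 2, sd),
    intercept_mean = mean(draws$intercept),
    coefficient_samples = B,
    intercept_samples = as.numeric(draws$intercept),
    lambda2_samples = as.numeric(draws$lambda2),
    rhat = rhat,
    standardization = list(center = center, scale = scale_,
                           features = colnames(X)),
    n_draws = as.integer(n_draws), n_burnin = as.integer(n_burnin),
    seed = as.integer(seed), n = nrow(X)),
    class = "bayes_lasso_fit")
}

## split-chain potential scale reduction on one coefficient's draws
.split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  half <- list(x[seq_len(n)], x[seq.int(length(x) - n + 1, length(x))])
  W <- mean(vapply(half, var, numeric(1)))
  B <- n * var(vapply(half, mean, numeric(1)))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.bayes_lasso_fit <- function(x, ...) {
  cat(sprintf("<bayes_lasso_fit> %d features, n = %d, %d draws (%d burn-in), seed %d\n",
              length(x$coef_mean), x$n, x$n_draws, x$n_burnin, x$seed))
  tab <- data.frame(posterior_mean = x$coef_mean, posterior_sd = x$coef_sd,
                    rhat = x$rhat)
  print(round(tab, 4))
  invisible(x)
}

#' Linear texture risk score from a fitted model
#'
#' The risk score is the linear combination of the posterior-mean
#' standardized coefficients with the feature values standardized using the
#' *training* centering and scaling. The intercept is omitted: the score is
#' relative, so women with all features at the training means score 0.
#' Missing feature values are imputed as the training mean (standardized 0)
#' with a warning.
#'
#' @param fit a [bayes_lasso_fit].
#' @param X matrix or data frame containing at least the fit's feature
#'   columns.
#' @return numeric vector of scores, one per row of `X`.
#' @export
bayes_lasso_score <- function(fit, X) {
  stopifnot(inherits(fit, "bayes_lasso_fit"))
  X <- as.data.frame(X)
  missing_cols <- setdiff(fit$standardization$features, names(X))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  Xm <- as.matrix(X[, fit$standardization$features, drop = FALSE])
  storage.mode(Xm) <- "double"
  Xs <- sweep(sweep(Xm, 2, fit$standardization$center), 2,
              fit$standardization$scale, "/")
  if (anyNA(Xs)) {
    warning(sum(is.na(Xs)), " missing feature values imputed at the training mean")
    Xs[is.na(Xs)] <- 0
  }
  drop(Xs %*% fit$coef_mean)
}

#' Train/test cross-scoring of texture risk measures across studies
#'
#' For every ordered (train, test) pair of the supplied studies: fit the
#' Bayesian lasso on the training study's features, score the test study,
#' adjust the scores for age and BMI among the test study's controls
#' ([opera_adjust]) and estimate the OR per adjusted SD ([adjusted_or]).
#' The diagonal measures in-sample (optimistic) performance; off-diagonal
#' entries measure external replication.
#'
#' @param datasets named list of per-woman data frames, each with columns
#'   `status`, `age`, `bmi` and the shared feature columns.
#' @param feature_cols feature column names (default: the 20 GLCM names
#'   present in the first dataset).
#' @param n_draws,n_burnin,seed passed to [bayes_lasso_fit]; the seed is
#'   advanced per training study.
#' @return list with `grid` (data frame: train, test, or, ci_low, ci_high,
#'   p_value, log_or) and `results` (matrix-indexed list of `or_result`).
#' @export
cross_study_evaluate <- function(datasets, feature_cols = NULL,
                                 n_draws = 10000L, n_burnin = 1000L,
                                 seed = 1L) {
  stopifnot(is.list(datasets), length(datasets) >= 1, !is.null(names(datasets)))
  if (is.null(feature_cols))
    feature_cols <- intersect(glcm_feature_names(), names(datasets[[1]]))
  nm <- names(datasets)
  results <- matrix(list(), length(nm), length(nm), dimnames = list(nm, nm))
  rows <- list()
  for (a in seq_along(nm)) {
    train <- datasets[[a]]
    fit <- bayes_lasso_fit(train[, feature_cols, drop = FALSE], train$status,
                           n_draws = n_draws, n_burnin = n_burnin,
                           seed = seed + a - 1L)
    for (b in seq_along(nm)) {
      test <- datasets[[b]]
      sc <- bayes_lasso_score(fit, test[, feature_cols, drop = FALSE])
      adj <- opera_adjust(sc, test$age, test$bmi, test$status)
      orr <- adjusted_or(adj, test$status, test$age, test$bmi)
      results[[a, b]] <- orr
      rows[[length(rows) + 1L]] <- data.frame(
        train = nm[a], test = nm[b], or = orr$or_per_sd,
        ci_low = orr$ci_low, ci_high = orr$ci_high,
        p_value = orr$p_value, log_or = orr$log_or)
    }
  }
  list(grid = do.call(rbind, rows), results = results)
}
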