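test_that("the Polya-Gamma sampler reproduces the PG(1,z) mean", {
  set.seed(41)
  for (z in c(0, 0.5, 2, 8)) {
    draws <- cirrus:::.rpg_vec(rep(z, 5e4))
    theory <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_equal(mean(draws), theory, tolerance = 0.01)
    expect_true(all(draws > 0))
  }
})

test_that("fits are bit-reproducible given a seed and differ across seeds", {
  sim <- simulate_sparse_logistic(200, 5, c(1, 0, 0, 0, 0), seed = 42)
  f1 <- bayes_lasso_fit(sim$X, sim$y, n_draws = 500, n_burnin = 50, seed = 7)
  f2 <- bayes_lasso_fit(sim$X, sim$y, n_draws = 500, n_burnin = 50, seed = 7)
  f3 <- bayes_lasso_fit(sim$X, sim$y, n_draws = 500, n_burnin = 50, seed = 8)
  expect_identical(f1$coefficient_samples, f2$coefficient_samples)
  expect_identical(f1$coef_mean, f2$coef_mean)
  expect_false(identical(f1$coef_mean, f3$coef_mean))
})

test_that("under a null model most 95% posterior intervals cover zero", {
  sim <- simulate_sparse_logistic(500, 20, rep(0, 20), seed = 43)
  fit <- bayes_lasso_fit(sim$X, sim$y, n_draws = 1500, n_burnin = 150, seed = 1)
  ci <- apply(fit$coefficient_samples, 2, quantile, c(0.025, 0.975))
  covers <- ci[1, ] <= 0 & 0 <= ci[2, ]
  expect_gte(sum(covers), 18)
})

test_that("a single true effect is recovered near a fixed-penalty oracle, with shrinkage", {
  sim <- simulate_sparse_logistic(2000, 20, c(1, rep(0, 19)), seed = 44)
  fit <- bayes_lasso_fit(sim$X, sim$y, n_draws = 2000, n_burnin = 200, seed = 2)

  # oracle: penalized MLE with the l1 penalty fixed at the posterior mean of
  # the sampled regularization parameter (glmnet is the independent route)
  lam <- mean(sqrt(fit$lambda2_samples))
  Xs <- scale(sim$X)
  gfit <- glmnet::glmnet(Xs, sim$y, family = "binomial",
                         lambda = lam / nrow(Xs), standardize = FALSE)
  oracle <- as.numeric(gfit$beta)
  expect_lt(abs(fit$coef_mean[["f1"]] - oracle[1]), 0.2)

  # l1 shrinkage relative to the unpenalized MLE
  mle <- coef(glm(sim$y ~ Xs, family = binomial()))[-1]
  expect_lt(sum(abs(fit$coef_mean)), sum(abs(mle)))
  nulls <- 2:20
  expect_lt(sum(abs(fit$coef_mean[nulls])), sum(abs(mle[nulls])))
})

test_that("perfectly collinear predictors stay stable and share the joint effect", {
  set.seed(45)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.0 * x))
  X <- cbind(a = x, b = x)  # exact copies
  fit <- bayes_lasso_fit(X, y, n_draws = 2000, n_burnin = 200, seed = 3)
  expect_true(all(is.finite(fit$coef_mean)))
  expect_lt(abs(sum(fit$coef_mean) - 1.0), 0.2)
})

test_that("separation is handled gracefully by the prior", {
  set.seed(46)
  x <- c(rnorm(50, -2), rnorm(50, 2))
  y <- rep(c(0, 1), each = 50)   # perfectly separable
  X <- cbind(f1 = x, f2 = rnorm(100))
  fit <- bayes_lasso_fit(X, y, n_draws = 1500, n_burnin = 150, seed = 4)
  expect_true(all(is.finite(fit$coef_mean)))
  expect_lt(max(abs(fit$coef_mean)), 20)
})

test_that("scoring is the standardized linear form with training parameters held fixed", {
  sim <- simulate_sparse_logistic(300, 3, c(0.8, 0, 0), seed = 47)
  fit <- bayes_lasso_fit(sim$X, sim$y, n_draws = 500, n_burnin = 50, seed = 5)

  # women at the training means score exactly 0
  mu <- as.data.frame(t(fit$standardization$center))
  expect_equal(bayes_lasso_score(fit, mu), 0, tolerance = 1e-12, ignore_attr = TRUE)

  # hand-computed linear combination
  fit2 <- fit
  fit2$coef_mean <- setNames(c(0.5, -1.0, 0), fit$standardization$features)
  x_raw <- fit$standardization$center + c(2, 1, 0) * fit$standardization$scale
  expect_equal(bayes_lasso_score(fit2, as.data.frame(t(x_raw))),
               0.5 * 2 - 1.0 * 1, ignore_attr = TRUE)

  # adding a constant to one raw feature in the test set shifts all scores
  # by the same constant (training standardization fixed)
  Xt <- as.data.frame(sim$X)
  s0 <- bayes_lasso_score(fit, Xt)
  Xt$f1 <- Xt$f1 + 3
  s1 <- bayes_lasso_score(fit, Xt)
  shift <- 3 / fit$standardization$scale[["f1"]] * fit$coef_mean[["f1"]]
  expect_equal(s1 - s0, rep(shift, nrow(Xt)), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(bayes_lasso_score(fit, Xt[, 1:2]), "f3")
})

test_that("fit serialization round-trips through the JSON artifact", {
  sim <- simulate_sparse_logistic(200, 4, c(0.5, 0, 0, 0), seed = 48)
  fit <- bayes_lasso_fit(sim$X, sim$y, n_draws = 400, n_burnin = 40, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  fit2 <- read_fit_json(path)
  expect_equal(fit2$coef_mean, fit$coef_mean)
  expect_equal(fit2$standardization$center, fit$standardization$center)
  expect_equal(bayes_lasso_score(fit2, as.data.frame(sim$X)),
               bayes_lasso_score(fit, as.data.frame(sim$X)))
})

test_that("cross-study evaluation replicates a shared gradient across synthetic studies", {
  cfgA <- synthetic_config(n_women = 1200, images_per_woman_range = c(1, 4), seed = 61)
  cfgB <- synthetic_config(n_women = 1200, images_per_woman_range = c(1, 4), seed = 62)
  per_woman <- function(cfg) {
    coh <- generate_cohort(cfg, mode = "feature")
    pw <- aggregate_median(coh$mammograms)
    merge(pw, coh$cohort, by = "woman_id")
  }
  studies <- list(A = per_woman(cfgA), B = per_woman(cfgB))
  cv <- cross_study_evaluate(studies, n_draws = 1200, n_burnin = 120, seed = 9)
  expect_identical(nrow(cv$grid), 4L)
  expect_true(all(cv$grid$or > 1))
  # off-diagonal log(OR) within 25% of the in-sample diagonal log(OR)
  g <- cv$grid
  for (tr in c("A", "B")) {
    diag_lor <- g$log_or[g$train == tr & g$test == tr]
    off_lor <- g$log_or[g$train == tr & g$test != tr]
    expect_lt(abs(off_lor - diag_lor) / diag_lor, 0.25)
  }
})
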