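test_that("quantization is an equal-mass median split on simple input", {
  m <- matrix(c(10, 20, 30, 40), 1, 4)
  q <- quantize(m, G = 2)
  expect_identical(as.integer(q$levels), c(1L, 1L, 2L, 2L))
})

test_that("quantization is invariant to strictly monotone intensity transforms", {
  set.seed(11)
  m <- matrix(runif(400), 20, 20)
  q0 <- quantize(m, G = 8)
  expect_identical(quantize(3 * m + 7, G = 8)$levels, q0$levels)
  expect_identical(quantize(m^2.2, G = 8)$levels, q0$levels)
  expect_identical(quantize(exp(m), G = 8)$levels, q0$levels)
})

test_that("quantization of continuous noise gives near-uniform level occupancy", {
  set.seed(12)
  m <- matrix(runif(256 * 256), 256, 256)
  q <- quantize(m, G = 16)
  occ <- tabulate(q$levels, 16) / length(q$levels)
  expect_true(all(occ >= 0.9 / 16 & occ <= 1.1 / 16))
})

test_that("quantization enforces G distinct values and same level for ties", {
  expect_error(quantize(matrix(rep(c(1, 2, 3), 10), 5, 6), G = 4), "distinct")
  m <- matrix(c(5, 5, 5, 1, 9, 9), 1, 6)
  q <- quantize(m, G = 3)
  lv <- as.integer(q$levels)
  expect_true(all(lv[c(1, 2, 3)] == lv[1]))  # tied intensities share a level
  expect_identical(lv[4], 1L)
  expect_true(all(lv[c(5, 6)] == lv[5]))
})

test_that("a single pair produces the symmetrized two-cell matrix", {
  lev <- matrix(c(1L, 2L), 1, 2)
  M <- cooccurrence(lev, distance = 1)
  expect_equal(M$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("pooled co-occurrence matches the brute-force pair-count oracle", {
  set.seed(13)
  for (rep in 1:25) {
    S <- sample(8:16, 1); G <- sample(2:4, 1); d <- sample(1:2, 1)
    lev <- matrix(sample.int(G, S * S, replace = TRUE), S, S)
    if (rep %% 3 == 0) lev[sample(S * S, S)] <- NA  # holes in the mask
    M <- cooccurrence(structure(list(levels = lev, G = G),
                                class = "quantized_image"), distance = d)
    expect_equal(M$p, oracle_cooccurrence(lev, G, d), tolerance = 1e-15)
  }
})

test_that("co-occurrence is symmetric, normalized, and exactly rotation invariant", {
  set.seed(14)
  lev <- matrix(sample.int(4, 144, replace = TRUE), 12, 12)
  q <- structure(list(levels = lev, G = 4L), class = "quantized_image")
  M <- cooccurrence(q)
  expect_equal(sum(M$p), 1, tolerance = 1e-12)
  expect_equal(M$p, t(M$p), tolerance = 1e-12)
  r90 <- structure(list(levels = rotate90(lev), G = 4L), class = "quantized_image")
  expect_identical(cooccurrence(r90)$p, M$p)
  r180 <- structure(list(levels = rotate90(rotate90(lev)), G = 4L), class = "quantized_image")
  expect_identical(cooccurrence(r180)$p, M$p)
})

test_that("features match hand-computed values on 2x2 matrices", {
  # all mass on the diagonal: perfectly correlated levels
  f <- compute_features(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(f[["energy"]], 0.5)
  expect_equal(f[["entropy"]], log(2))
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["maximum_probability"]], 0.5)
  expect_equal(f[["autocorrelation"]], 2.5)
  expect_equal(f[["correlation"]], 1)

  # all mass off the diagonal: perfectly anti-correlated
  g <- compute_features(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(g[["contrast"]], 1)
  expect_equal(g[["correlation"]], -1)
  expect_equal(g[["homogeneity"]], 0.5)
  expect_equal(g[["sum_average"]], 3)
})

test_that("degenerate single-cell matrix yields sentinels only for correlation-type features", {
  p <- matrix(0, 3, 3); p[2, 2] <- 1
  f <- compute_features(p)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["dissimilarity"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["maximum_probability"]], 1)
  expect_equal(f[["difference_variance"]], 0)
  expect_true(is.na(f[["correlation"]]))
  expect_true(is.na(f[["info_correlation_1"]]))
  expect_true(is.na(f[["info_correlation_2"]]))
  expect_false(anyNA(f[setdiff(names(f), c("correlation", "info_correlation_1",
                                           "info_correlation_2"))]))
})

test_that("feature ranges and distribution identities hold on random matrices", {
  set.seed(15)
  for (rep in 1:20) {
    G <- sample(3:8, 1)
    lev <- matrix(sample.int(G, 400, replace = TRUE), 20, 20)
    M <- cooccurrence(structure(list(levels = lev, G = G),
                                class = "quantized_image"))
    p <- M$p
    f <- compute_features(M)
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_true(f[["maximum_probability"]] > 0 && f[["maximum_probability"]] <= 1)
    expect_true(f[["homogeneity"]] > 0 && f[["homogeneity"]] <= 1)
    expect_gte(f[["entropy"]], 0)
    expect_gte(f[["contrast"]], 0)
    expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
    expect_true(f[["info_correlation_2"]] >= 0 && f[["info_correlation_2"]] <= 1)
    # probability conservation of the derived distributions
    i <- matrix(seq_len(G), G, G); j <- t(i)
    psum <- vapply(2:(2 * G), function(k) sum(p[i + j == k]), numeric(1))
    pdiff <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
    expect_equal(sum(psum), 1, tolerance = 1e-12)
    expect_equal(sum(pdiff), 1, tolerance = 1e-12)
    # contrast equals the second moment of the difference distribution
    expect_equal(f[["contrast"]], sum((0:(G - 1))^2 * pdiff), tolerance = 1e-12)
  }
})

test_that("extracted features are invariant to flips and monotone transforms of a phantom", {
  ph <- tiny_phantom(96, seed = 16)
  f0 <- extract_features(ph$pixels, ph$support, G = 16)
  expect_identical(extract_features(flip_lr(ph$pixels), flip_lr(ph$support), G = 16), f0)
  expect_identical(extract_features(ph$pixels^2, ph$support, G = 16), f0)
})

test_that("smoother long-range texture scores higher homogeneity than rough texture", {
  set.seed(17)
  cfg <- synthetic_config()
  h <- function(width) {
    g <- generate_image(width, cfg, with_label = FALSE)
    fv <- extract_features(g$image, segment_breast(g$image))
    c(fv[["homogeneity"]], fv[["contrast"]])
  }
  smooth <- rowMeans(replicate(3, h(8)))
  rough <- rowMeans(replicate(3, h(2)))
  expect_gt(smooth[1], rough[1])   # homogeneity increases with smoothness
  expect_lt(smooth[2], rough[2])   # contrast decreases
})

test_that("scale-free features are stable when resolution and offset double together", {
  set.seed(18)
  feats <- c("energy", "entropy", "homogeneity", "correlation")
  f1 <- f2 <- NULL
  for (r in 1:6) {
    g1 <- generate_image(3, synthetic_config(image_size = 128), with_label = FALSE)
    g2 <- generate_image(6, synthetic_config(image_size = 256), with_label = FALSE)
    f1 <- rbind(f1, extract_features(g1$image, segment_breast(g1$image), distance = 1))
    f2 <- rbind(f2, extract_features(g2$image, segment_breast(g2$image), distance = 2))
  }
  for (f in feats) {
    rel <- abs(mean(f1[, f]) - mean(f2[, f])) / abs(mean(f2[, f]))
    expect_lt(rel, 0.05)
  }
})
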