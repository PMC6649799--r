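# Shared fixtures and independent oracles, built in code at test time.

# Brute-force co-occurrence oracle: explicit double loop over every pixel and
# the four symmetric offsets, counting each ordered pair and its reverse.
# Deliberately naive and independent of the package's vectorized counting.
oracle_cooccurrence <- function(lev, G, d = 1L) {
  counts <- matrix(0, G, G)
  nr <- nrow(lev); nc <- ncol(lev)
  offsets <- list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lev[r, c])) next
    for (off in offsets) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(lev[r2, c2])) next
      a <- lev[r, c]; b <- lev[r2, c2]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# Brute-force Mann-Whitney AUC: exhaustive case-control pair comparison.
oracle_auc <- function(scores, status) {
  cs <- scores[status == 1]; ct <- scores[status == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Small breast-like phantom (half-ellipse, textured) as a bare matrix plus
# its exact support, for tests that do not need the full generator.
tiny_phantom <- function(S = 96, noise = 5, seed = 1) {
  set.seed(seed)
  row <- matrix(seq_len(S), S, S); col <- t(row)
  support <- ((col - 1) / (0.7 * S))^2 + ((row - S / 2) / (0.4 * S))^2 <= 1
  pix <- matrix(10, S, S)
  pix[support] <- 150 + round(rnorm(sum(support), sd = 40))
  pix <- pix + round(rnorm(S * S, sd = noise))
  pix[pix < 0] <- 0
  pix[pix > 255] <- 255
  list(pixels = pix, support = support)
}

# Simulated logistic data with a sparse standardized truth.
simulate_sparse_logistic <- function(n, p, beta, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- drop(X %*% beta)
  y <- rbinom(n, 1, plogis(eta - mean(eta)))
  list(X = X, y = y)
}

# Quick logistic case-control simulation: measure x with a planted
# case-control mean shift delta (in SD units), so the true OR per SD of x
# is exp(delta) under the equal-variance normal model; age and BMI are
# independent noise covariates.
simulate_measure_cohort <- function(n, delta, case_fraction = 0.25) {
  n_case <- round(n * case_fraction)
  status <- c(rep(1, n_case), rep(0, n - n_case))
  x <- rnorm(n) + delta * status
  list(x = x, status = status,
       age = runif(n, 40, 70), bmi = rlnorm(n, log(25.5), 0.15))
}
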