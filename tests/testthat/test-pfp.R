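test_that("fit_pfp recovers the closed-form Fisher direction", {
  # two features, separation along the first, isotropic within-class scatter
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * 0.1
  x1 <- sweep(base, 2, c(1, 0), "+")
  x2 <- base
  colnames(x1) <- colnames(x2) <- c("f1", "f2")
  m <- fit_pfp(x1, x2, standardize = FALSE)
  expect_equal(abs(sum(m$W * c(1, 0))), 1, tolerance = 1e-10)
  expect_gt(m$mu1_tilde, m$mu2_tilde)   # sign convention
  expect_equal(sqrt(sum(m$W^2)), 1, tolerance = 1e-12)

  expect_error(fit_pfp(x1, x1, standardize = FALSE), "no class separation")
  expect_error(fit_pfp(x1[1:1, , drop = FALSE], x2[1:1, , drop = FALSE]),
               "at least as many pixels")
})

test_that("fit_pfp agrees with the oracle and dominates other directions", {
  set.seed(91)
  for (rep in 1:10) {
    n <- 15
    a <- matrix(rnorm(n * n), n)
    sig <- crossprod(a) / n + diag(n) * 0.1
    ch <- chol(sig)
    mu <- rnorm(n, sd = 0.5)
    x1 <- matrix(rnorm(600 * n), 600) %*% ch
    x2 <- sweep(matrix(rnorm(500 * n), 500) %*% ch, 2, mu, "+")
    colnames(x1) <- colnames(x2) <- paste0("f", 1:n)
    m <- fit_pfp(x1, x2, standardize = FALSE)
    w_star <- oracle_fisher_direction(x1, x2)
    expect_gte(abs(sum(m$W * w_star)), 1 - 1e-8)
    # F dominance over random directions and every single-feature axis
    v <- matrix(rnorm(n * 300), n)
    v <- cbind(sweep(v, 2, sqrt(colSums(v^2)), "/"), diag(n))
    expect_true(all(m$F >= f_many(v, x1, x2) - 1e-10))
    expect_equal(m$F, f_score(m$W, x1, x2), tolerance = 1e-10)
  }
})

test_that("standardization record is stored and reused", {
  set.seed(92)
  x1 <- matrix(rnorm(200, mean = 2, sd = 3), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  x2 <- matrix(rnorm(200, mean = 1, sd = 3), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  m <- fit_pfp(x1, x2)
  expect_named(m$standardization$center, c("a", "b"))
  pooled <- rbind(x1, x2)
  expect_equal(as.numeric(m$standardization$center),
               as.numeric(colMeans(pooled)))
  # raw mode skips the record
  expect_null(fit_pfp(x1, x2, standardize = FALSE)$standardization)
  # unnormalized raw-sum scatter mode is exposed for unbalanced classes
  m2 <- fit_pfp(x1, rbind(x2, x2 + 0.01), scatter = "unnormalized")
  expect_s3_class(m2, "pfp_model")
})

test_that("f_score matches the hand-computed value and is scale invariant", {
  c1 <- matrix(c(0.9, 1.0, 1.1), ncol = 1)
  c2 <- matrix(c(-0.1, 0, 0.1), ncol = 1)
  expect_equal(f_score(1, c1, c2), 75.0, tolerance = 1e-12)
  expect_equal(f_score(3, c1, c2), 75.0, tolerance = 1e-12)
  expect_error(f_score(1, matrix(1, 3, 1), matrix(0, 3, 1)),
               "variance is zero")
})

test_that("a single differing feature dominates the learned weights", {
  set.seed(93)
  n <- 15
  for (k in c(1, 7, 15)) {
    x1 <- matrix(rnorm(800 * n), 800)
    x2 <- matrix(rnorm(800 * n), 800)
    x2[, k] <- x2[, k] + 2
    colnames(x1) <- colnames(x2) <- paste0("f", 1:n)
    m <- fit_pfp(x1, x2)
    expect_gte(abs(m$W[k]), 0.95)
  }
})

test_that("apply_pfp projects stacks pixel-wise with masking", {
  st <- phantom_stack(default_presets()$normal, 24, 24, seed = 95)$stack
  fg <- !st$background & !st$degenerate
  # one-hot model on delta reproduces the standardized delta map
  center <- mean(st$maps$delta[fg]); scale <- sd(st$maps$delta[fg])
  m <- make_model()
  m$W <- c(delta = 1); m$feature_names <- "delta"
  m$standardization <- list(center = c(delta = center), scale = c(delta = scale))
  y <- apply_pfp(m, st)
  expect_equal(y[fg], (st$maps$delta[fg] - center) / scale, tolerance = 1e-12)
  expect_true(all(is.na(y[!fg])))

  m$feature_names <- "nonexistent"
  names(m$W) <- "nonexistent"
  expect_error(apply_pfp(m, st), "nonexistent")

  # matrix input path
  m2 <- make_model()
  xm <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(apply_pfp(m2, xm), c(1, 2, 3))
})

test_that("treatment_score honors the forced identities", {
  m <- make_model(mu1 = 2, mu2 = -1, d1 = 0.4)
  s100 <- treatment_score(rnorm_fixed(2, 0.4), m)
  expect_equal(s100$S, 100, tolerance = 1e-9)
  s0 <- treatment_score(rnorm_fixed(-1, 0.4), m)
  expect_equal(s0$S, 0, tolerance = 1e-9)
  # midpoint: first term vanishes, S = 50 D1 / Dr
  smid <- treatment_score(rnorm_fixed(0.5, 0.8), m)
  expect_equal(smid$S, 50 * 0.4 / 0.8, tolerance = 1e-9)

  expect_error(treatment_score(rep(1, 5), m), "zero")
  expect_error(treatment_score(numeric(0), m), "empty")
})

test_that("treatment_score is invariant under consistent affine rescaling", {
  set.seed(97)
  v <- rnorm(2000, 0.3, 0.6)
  m <- make_model(mu1 = 1, mu2 = -1, d1 = 0.5)
  s0 <- treatment_score(v, m)$S
  a <- 3.7; b <- -2.1
  m2 <- make_model(mu1 = a * 1 + b, mu2 = a * -1 + b, d1 = a^2 * 0.5)
  expect_equal(treatment_score(a * v + b, m2)$S, s0, tolerance = 1e-9)
})
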