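test_that("normalize_mm divides by m11 and separates background", {
  # scaled identity everywhere: normalization is plain scalar division
  el <- array(0, c(2, 2, 4, 4))
  for (i in 1:4) el[, , i, i] <- 3
  img <- normalize_mm(mueller_image(el))
  expect_true(img$normalized)
  expect_equal(sum(img$background), 0)
  for (i in 1:4) expect_equal(img$elements[, , i, i], matrix(1, 2, 2))

  # m11 = 0 pixel goes to background untouched
  el[1, 1, , ] <- 0
  img2 <- normalize_mm(mueller_image(el))
  expect_true(img2$background[1, 1])
  expect_equal(img2$elements[1, 1, 2, 2], 0)

  # known transmittance field: normalized elements equal the pre-scaling ones
  set.seed(11)
  base <- replicate(6, random_composed()$m, simplify = FALSE)
  tau <- runif(6, 0.3, 0.9)
  scaled <- matrices_as_image(Map(function(m, t) m * t, base, tau),
                              normalized = FALSE)
  norm <- normalize_mm(scaled)
  for (k in seq_along(base)) {
    expect_equal(norm$elements[1, k, , ], base[[k]], tolerance = 1e-12)
  }

  expect_error(normalize_mm(mueller_image(array(0, c(2, 2, 4, 4)))),
               "empty foreground")
})

test_that("validate_mm flags non-physical pixels only", {
  ident <- array(0, c(3, 3, 4, 4))
  for (i in 1:4) ident[, , i, i] <- 1
  d <- validate_mm(mueller_image(ident))
  expect_equal(d$n_flagged, 0)

  bad <- ident
  bad[2, 2, 1, 2] <- 1.5
  d2 <- validate_mm(mueller_image(bad))
  expect_true(d2$passivity_violated[2, 2])
  expect_equal(d2$n_flagged, 1)

  # noise-free phantom: element composition preserves passivity
  ph <- generate_phantom(default_presets(noise_sigma = 0)$model, 32, 32, seed = 5)
  expect_equal(validate_mm(ph$image)$n_flagged, 0)
})

test_that("stokes_set validates physicality and rank", {
  expect_error(stokes_set(cbind(c(-1, 0, 0, 0), diag(4)[, 2:4] + 1)), "S0 > 0")
  expect_error(stokes_set(rbind(1, 2, 0, 0)), "4 x N")
  bad <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1))
  expect_error(stokes_set(bad), "condition number")
  s <- default_psg()
  expect_s3_class(s, "stokes_set")
  expect_lt(kappa(s$states, exact = TRUE), 10)
})

test_that("reconstruct_mm inverts the measurement model", {
  psg <- default_psg()
  # S_out == S_in -> identity
  m <- reconstruct_mm(psg, psg$states)
  expect_equal(unclass(m), diag(4), ignore_attr = TRUE, tolerance = 1e-12)

  # known retarder through 6 states, exact recovery
  ret <- element_retarder(1.1, 25)
  states6 <- cbind(psg$states, c(1, 0.5, 0.5, sqrt(0.5)), c(1, 0, -0.6, 0.8))
  s_in <- stokes_set(states6, "generator")
  s_out <- ret %*% states6
  expect_lt(max(abs(reconstruct_mm(s_in, s_out) - ret)), 1e-10)

  # random matrix round trip at N = 4 is machine-precision identity
  set.seed(21)
  for (k in 1:20) {
    m0 <- random_composed()$m
    expect_lt(max(abs(reconstruct_mm(psg, m0 %*% psg$states) - m0)), 1e-10)
  }

  expect_error(reconstruct_mm(psg$states[, c(1, 1, 2, 3)], diag(4)),
               "condition number")
})

test_that("reconstruction error scales with noise level and frame averaging", {
  set.seed(31)
  m0 <- random_composed()$m
  img <- mueller_image(m0, normalized = TRUE)
  psg <- default_psg()
  rmse <- function(sigma, n_frames = 1, draws = 100) {
    errs <- vapply(seq_len(draws), function(k) {
      meas <- simulate_measurement(img, psg, noise_sigma = sigma,
                                   seed = 7000 + k, n_frames = n_frames)
      rec <- reconstruct_mm(psg, meas)
      sqrt(mean((rec$elements[1, 1, , ] - m0)^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r1 <- rmse(0.02); r2 <- rmse(0.01)
  expect_gt(r1 / r2, 2 * 0.8)
  expect_lt(r1 / r2, 2 * 1.2)
  # averaging k frames shrinks the error like 1/sqrt(k)
  r4 <- rmse(0.02, n_frames = 4)
  expect_gt(r1 / r4, 2 * 0.8)
  expect_lt(r1 / r4, 2 * 1.2)
})
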