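test_that("phantom generation is seeded and deterministic", {
  p <- default_presets()$normal
  a <- generate_phantom(p, 32, 32, seed = 42)
  b <- generate_phantom(p, 32, 32, seed = 42)
  expect_identical(a$image$elements, b$image$elements)
  expect_identical(a$truth$orient_map, b$truth$orient_map)
  c <- generate_phantom(p, 32, 32, seed = 43)
  expect_false(identical(a$image$elements, c$image$elements))
  expect_error(generate_phantom(p, 32, 32), "seed")
})

test_that("zero-spread preset gives a constant foreground", {
  p <- group_preset("flat", delta_mean = 0.8, delta_sd = 0, diat_mean = 0.1,
                    diat_sd = 0, orient_mean_deg = 40, orient_sd_deg = 0,
                    depol_diag = c(0.9, 0.9, 0.8), fiber_fill_fraction = 1)
  ph <- generate_phantom(p, 16, 16, seed = 1, tau_foreground = 0.8)
  norm <- normalize_mm(ph$image)
  fld <- matrix(norm$elements, 256)
  expect_lt(max(apply(fld, 2, function(v) diff(range(v)))), 1e-10)
})

test_that("group contrast matches the designed ordering", {
  pr <- default_presets(noise_sigma = 0)
  n <- phantom_stack(pr$normal, 48, 48, seed = 11, noise_sigma = 0)
  m <- phantom_stack(pr$model, 48, 48, seed = 12, noise_sigma = 0)
  expect_gt(mean(n$stack$maps$delta, na.rm = TRUE),
            mean(m$stack$maps$delta, na.rm = TRUE))
  expect_lt(mean(n$stack$maps$D, na.rm = TRUE),
            mean(m$stack$maps$D, na.rm = TRUE))
  expect_lt(axial_sd(n$stack$maps$theta), axial_sd(m$stack$maps$theta))
})

test_that("extracted retardance is linear in preset birefringence", {
  dn <- c(0.004, 0.008, 0.012)
  deltas <- vapply(dn, function(d) {
    p <- group_preset("lin", retardance_from_birefringence(d, 10, 633), 0,
                      0.05, 0, 90, 0, c(0.95, 0.95, 0.9),
                      fiber_fill_fraction = 1)
    ph <- generate_phantom(p, 8, 8, seed = 2)
    mmpd(normalize_mm(ph$image))$delta[1, 1]
  }, numeric(1))
  slope <- 2 * pi * 10 * 1000 / 633
  expect_equal(deltas, dn * slope, tolerance = 1e-6)
  # and the preset invariant links delta, dn, thickness and wavelength
  p <- default_presets()$normal
  expect_equal(p$delta_mean,
               retardance_from_birefringence(p$dn, p$thickness_um, p$wavelength_nm),
               tolerance = 1e-12)
})

test_that("simulated measurement closes the reconstruction loop", {
  pr <- default_presets(noise_sigma = 0)$normal
  ph <- generate_phantom(pr, 12, 12, seed = 4)
  psg <- default_psg()
  meas <- simulate_measurement(ph$image, psg, noise_sigma = 0)
  rec <- reconstruct_mm(psg, meas)
  expect_lt(max(abs(rec$elements - ph$image$elements)), 1e-10)

  dup <- stokes_set(default_psg()$states, "generator")
  dup$states[, 2] <- dup$states[, 1]
  expect_error(simulate_measurement(ph$image, dup$states), "condition number")
  expect_error(simulate_measurement(ph$image, psg, noise_sigma = 0.01),
               "seed")
})

test_that("air lacunae respect the fill fraction and carry no tissue truth", {
  p <- default_presets()$model  # fill 0.80
  ph <- generate_phantom(p, 64, 64, seed = 8)
  frac_air <- mean(ph$truth$air_mask)
  expect_equal(frac_air, 0.2, tolerance = 0.02)
  expect_true(all(is.na(ph$truth$delta_map[ph$truth$air_mask])))
  bg <- normalize_mm(ph$image)$background
  expect_equal(bg, ph$truth$air_mask)
})
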