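test_that("stain maps background and value bands to the three colors", {
  # all background -> all blue
  empty <- matrix(NA_real_, 4, 4)
  s <- stain(empty)
  expect_equal(attr(s, "bands"), matrix(0L, 4, 4))
  blue <- grDevices::col2rgb("#08306B") / 255
  expect_equal(as.numeric(s[1, 1, ]), as.numeric(blue), tolerance = 1e-12)

  # three plateaus around absolute breaks -> exactly three bands
  pfp <- matrix(c(rep(-1, 5), rep(0.5, 6), rep(2, 5)), 4, 4)
  s3 <- stain(pfp, stain_scheme(low = 0, high = 1, space = "absolute"))
  expect_setequal(unique(as.vector(attr(s3, "bands"))), c(1L, 2L, 3L))
  expect_equal(as.numeric(band_fractions(s3)), c(5, 6, 5) / 16)

  # degenerate constant image warns and yields a single band
  expect_warning(sc <- stain(matrix(1, 3, 3)), "constant")
  expect_equal(length(unique(as.vector(attr(sc, "bands")))), 1)

  # purity: identical inputs give bit-identical output
  expect_identical(stain(pfp, stain_scheme(low = 0, high = 1, space = "absolute")),
                   s3)
})

test_that("percentile breaks make band fractions invariant to monotone transforms", {
  set.seed(111)
  pfp <- matrix(rnorm(400), 20, 20)
  sch <- stain_scheme(low = 0.1, high = 0.6, space = "percentile")
  f0 <- band_fractions(stain(pfp, sch))
  f1 <- band_fractions(stain(exp(pfp), sch))          # strictly increasing
  f2 <- band_fractions(stain(2 * pfp + 5, sch))
  expect_equal(f0, f1, tolerance = 1e-12)
  expect_equal(f0, f2, tolerance = 1e-12)
  expect_error(stain_scheme(low = 0.7, high = 0.2), "smaller")
})

test_that("healthy phantoms show more orange than injured ones", {
  pr <- default_presets()
  sn <- phantom_stack(pr$normal, 48, 48, seed = 121)
  sm <- phantom_stack(pr$model, 48, 48, seed = 122)
  m <- fit_pfp(pbp_features(sn$stack), pbp_features(sm$stack))
  sch <- stain_scheme()
  fn <- band_fractions(stain(apply_pfp(m, sn$stack), sch, model = m))
  fm <- band_fractions(stain(apply_pfp(m, sm$stack), sch, model = m))
  expect_gt(fn[["orange"]], fm[["orange"]])
})

test_that("group_report overlays FDHs and scores groups", {
  set.seed(131)
  # classes designed with equal widths so the forced S identities hold
  x1 <- rnorm_fixed(1, 0.25, 4000)
  x2 <- rnorm_fixed(-1, 0.25, 4000)
  m <- make_model(mu1 = 1, mu2 = -1, d1 = 0.25, d2 = 0.25)
  groups <- list(normal = x1, model = x2,
                 like_normal = sample(x1, 2000),
                 like_model = sample(x2, 2000))
  rep_ <- group_report(groups, m, n_bins = 40)
  expect_named(rep_$fdh, names(groups))
  # resampled normal pixels: FDH within sampling error of the normal FDH
  expect_lt(max(abs(rep_$fdh$like_normal$frequencies -
                      rep_$fdh$normal$frequencies)), 0.05)
  sc <- rep_$scores
  expect_equal(sc$S[sc$group == "like_normal"], 100, tolerance = 5)
  expect_equal(sc$S[sc$group == "like_model"], 0, tolerance = 5)
  expect_equal(rep_$ranking[1], "like_normal")
  expect_error(group_report(list(a = x1), m), "normal")
})

test_that("stain images serialize to PPM", {
  pfp <- matrix(runif(16), 4, 4)
  s <- stain(pfp, stain_scheme(low = 0.3, high = 0.7, space = "percentile"))
  path <- withr::local_tempfile(fileext = ".ppm")
  write_stain(s, path)
  lines <- readLines(path)
  expect_equal(lines[1], "P3")
  expect_equal(lines[2], "4 4")
  vals <- as.integer(strsplit(lines[4], " ")[[1]])
  expect_length(vals, 4 * 4 * 3)
  expect_true(all(vals >= 0 & vals <= 255))
})
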