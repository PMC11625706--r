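test_that("mmt reproduces Table-style closed forms on pure elements", {
  ident <- mmt(diag(4))
  for (p in c("D_L", "P_L", "q_L", "r_L", "t1", "A", "CD", "m14", "m41")) {
    expect_equal(ident[[p]][1, 1], 0, info = p)
  }
  expect_equal(ident$detB[1, 1], 1)
  expect_equal(ident$normB[1, 1], sqrt(2))
  expect_equal(ident$m44[1, 1], 1)

  qwp <- mmt(element_retarder(pi / 2, 0))
  expect_equal(qwp$r_L[1, 1], 1)
  expect_equal(qwp$q_L[1, 1], 1)
  expect_equal(qwp$t1[1, 1], 0.5)
  expect_equal(qwp$b[1, 1], 0.5)
  expect_equal(qwp$A[1, 1], 1)
  expect_equal(qwp$detB[1, 1], 0)
  expect_equal(qwp$normB[1, 1], 1)
  expect_equal(qwp$alpha_r_deg[1, 1], 0)

  dia <- mmt(element_diattenuator(0.5, 0))
  expect_equal(dia$D_L[1, 1], 0.5)
  expect_equal(dia$P_L[1, 1], 0.5)
  expect_equal(dia$m14[1, 1], 0)
  expect_equal(dia$m41[1, 1], 0)
  expect_equal(dia$CD[1, 1], 0)
})

test_that("printed t1 variant is exposed but not the default", {
  as_printed <- mmt(diag(4), t1_printed = TRUE)
  expect_equal(as_printed$t1[1, 1], 1)   # the typeset formula on the identity
  expect_equal(mmt(diag(4))$t1[1, 1], 0) # default invariant form
  # and the printed form is not rotation invariant
  m <- element_retarder(1, 0)
  t_rot <- mmt(rotate_sample(m, 30), t1_printed = TRUE)$t1[1, 1]
  expect_gt(abs(t_rot - mmt(m, t1_printed = TRUE)$t1[1, 1]), 1e-3)
})

test_that("pure retarders satisfy r_L = q_L = sin(delta) and alpha_r = theta", {
  for (delta in c(0.3, 1.0, pi / 2, 2.4)) {
    for (theta in c(0, 28, 91.5, 160)) {
      mt <- mmt(element_retarder(delta, theta))
      expect_equal(mt$r_L[1, 1], sin(delta), tolerance = 1e-12)
      expect_equal(mt$q_L[1, 1], sin(delta), tolerance = 1e-12)
      expect_lt(axial_diff(mt$alpha_r_deg[1, 1], theta), 1e-9)
      # mmpd's theta agrees with alpha_r on pure retarders
      expect_lt(axial_diff(mmpd(element_retarder(delta, theta))$theta_deg[1, 1],
                           theta), 1e-9)
    }
  }
})

test_that("pbp_stack bundles maps with correct rotation-variance flags", {
  ph <- generate_phantom(default_presets(noise_sigma = 0)$normal, 16, 16, seed = 3)
  img <- normalize_mm(ph$image)
  st <- pbp_stack(img, "all")
  expect_length(st$maps, 17)
  expect_equal(sum(st$rotation_variant), 2)
  expect_setequal(names(st$rotation_variant)[st$rotation_variant],
                  c("theta", "alpha_r"))

  inv <- pbp_stack(img, "invariant")
  expect_length(inv$maps, 15)
  expect_false(any(inv$rotation_variant))

  sel <- pbp_stack(img, c("delta", "r_L"))
  expect_named(sel$maps, c("delta", "r_L"))
  expect_error(pbp_stack(img, c("delta", "bogus")), "bogus")
  expect_error(pbp_stack(img, "bogus"), "valid names")
})

test_that("the 15 invariant parameters survive in-plane rotation", {
  ph <- generate_phantom(default_presets(noise_sigma = 0)$model, 16, 16, seed = 7)
  img <- normalize_mm(ph$image)
  st0 <- pbp_stack(img, "all")
  phi <- 30
  st1 <- pbp_stack(rotate_sample(img, phi), "all")
  fg <- !st0$background & !st0$degenerate & !st1$degenerate
  # orientation is only defined where some retardance exists
  oriented <- fg & !is.na(st0$maps$delta) & sin(st0$maps$delta) > 0.05
  for (p in names(st0$maps)) {
    if (st0$rotation_variant[[p]]) {
      expect_lt(max(axial_diff(st1$maps[[p]][oriented],
                               st0$maps[[p]][oriented] + phi)),
                1e-6, label = p)
    } else {
      expect_lt(max(abs(st1$maps[[p]][fg] - st0$maps[[p]][fg])), 1e-6,
                label = p)
    }
  }
})
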