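#' Retardance implied by birefringence and section thickness
#'
#' `delta = 2 pi dn t / lambda` with the thickness in micrometers and the
#' wavelength in nanometers.
#'
#' @param dn birefringence (dimensionless refractive-index difference).
#' @param thickness_um section thickness, micrometers.
#' @param wavelength_nm wavelength, nanometers.
#' @return retardance in radians.
#' @export
retardance_from_birefringence <- function(dn, thickness_um, wavelength_nm = 633) {
  2 * pi * dn * thickness_um * 1000 / wavelength_nm
}

#' @rdname retardance_from_birefringence
#' @param delta retardance in radians.
#' @export
birefringence_from_retardance <- function(delta, thickness_um, wavelength_nm = 633) {
  delta * wavelength_nm / (2 * pi * thickness_um * 1000)
}

#' Literature tendon birefringence values
#'
#' The source literature quotes the tendon birefringence inconsistently
#' (0.0013 in running text, 0.013 in the simulation settings); both values are
#' exposed here and neither is asserted as ground truth anywhere in the
#' package. Presets derive their own `dn` from the designed retardance.
#'
#' @return named numeric vector with entries `text` and `figure`.
#' @export
reference_birefringence <- function() c(text = 0.0013, figure = 0.013)

#' Per-group phantom preset
#'
#' A `group_preset` fixes the effective-optics description of one sample
#' group: retardance (mean/SD, radians), diattenuation (mean/SD), axial fiber
#' orientation (mean/SD, degrees, period 180), diagonal depolarization
#' factors, fiber fill fraction (1 - air fraction), relative measurement noise
#' and the section geometry. The birefringence `dn` is derived from
#' `delta_mean` through [birefringence_from_retardance] so the
#' retardance-birefringence link always holds.
#'
#' @param name group name.
#' @param delta_mean,delta_sd retardance field mean and SD, radians.
#' @param diat_mean,diat_sd diattenuation field mean and SD.
#' @param orient_mean_deg,orient_sd_deg axial orientation mean and SD, degrees.
#' @param depol_diag three depolarization factors in `(0, 1]`.
#' @param fiber_fill_fraction fraction of pixels occupied by tissue.
#' @param noise_sigma default relative intensity noise for
#'   [simulate_measurement].
#' @param thickness_um,wavelength_nm section geometry.
#' @return object of class `group_preset`.
#' @export
group_preset <- function(name, delta_mean, delta_sd, diat_mean, diat_sd,
                         orient_mean_deg, orient_sd_deg, depol_diag,
                         fiber_fill_fraction = 0.9, noise_sigma = 0,
                         thickness_um = 10, wavelength_nm = 633) {
  stopifnot(delta_mean >= 0, delta_sd >= 0, orient_sd_deg >= 0,
            diat_mean >= 0, diat_sd >= 0,
            fiber_fill_fraction > 0, fiber_fill_fraction <= 1,
            length(depol_diag) == 3L, all(depol_diag > 0), all(depol_diag <= 1))
  if (diat_mean + 3 * diat_sd >= 1) {
    stop("diat_mean + 3 * diat_sd must stay below 1")
  }
  structure(
    list(name = name, delta_mean = delta_mean, delta_sd = delta_sd,
         diat_mean = diat_mean, diat_sd = diat_sd,
         orient_mean_deg = orient_mean_deg, orient_sd_deg = orient_sd_deg,
         depol_diag = as.numeric(depol_diag),
         fiber_fill_fraction = fiber_fill_fraction,
         noise_sigma = noise_sigma, thickness_um = thickness_um,
         wavelength_nm = wavelength_nm,
         dn = birefringence_from_retardance(delta_mean, thickness_um, wavelength_nm)),
    class = "group_preset"
  )
}

#' Default study presets
#'
#' The stated world of the phantom study: the normal group has high
#' retardance, low diattenuation and a narrow orientation distribution; the
#' injured model group the reverse; the treatment groups are graded so that
#' `medium` sits closest to (and in retardance beyond) normal, `high` second,
#' and `low`/`positive` remain near the model group. These values are fixed
#' design constants, not tuning knobs; see the methods vignette.
#'
#' @param noise_sigma relative measurement noise applied to every preset
#'   (default 1%, a typical camera noise floor; the phantom world includes
#'   pixel noise so that no polarization feature is deterministically tied to
#'   another).
#' @return named list of [group_preset] objects.
#' @export
default_presets <- function(noise_sigma = 0.01) {
  gp <- function(...) group_preset(..., noise_sigma = noise_sigma)
  list(
    normal   = gp("normal",   1.00, 0.10, 0.05, 0.015,  90,  5,  c(0.95, 0.95, 0.90), 0.95),
    model    = gp("model",    0.40, 0.18, 0.15, 0.030,  90, 35,  c(0.85, 0.85, 0.75), 0.80),
    low      = gp("low",      0.45, 0.17, 0.14, 0.030,  90, 30,  c(0.86, 0.86, 0.76), 0.82),
    medium   = gp("medium",   1.20, 0.10, 0.04, 0.015,  90,  6,  c(0.95, 0.95, 0.90), 0.95),
    high     = gp("high",     0.80, 0.13, 0.08, 0.020,  90, 14,  c(0.92, 0.92, 0.85), 0.90),
    positive = gp("positive", 0.42, 0.18, 0.145, 0.030, 90, 32,  c(0.85, 0.85, 0.75), 0.81)
  )
}

# separable Gaussian smoothing with reflection padding, then rescaling back to
# zero mean / unit SD so the marginal distribution of the field is preserved
smooth_field <- function(z, sigma_px) {
  if (sigma_px <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {
    nr <- nrow(m)
    idx <- clamp(c(rev(seq_len(half)), seq_len(nr), nr - seq_len(half) + 1L), 1L, nr)
    padded <- m[idx, , drop = FALSE]
    out <- apply(padded, 2L, function(col) stats::filter(col, k, sides = 2))
    out[(half + 1L):(half + nr), , drop = FALSE]
  }
  s <- t(pad_conv(t(pad_conv(z))))
  sdv <- stats::sd(as.vector(s))
  if (sdv > 0) (s - mean(s)) / sdv else s * 0
}

gaussian_field <- function(h, w, sigma_px) {
  smooth_field(matrix(stats::rnorm(h * w), h, w), sigma_px)
}

#' Generate a synthetic tissue phantom with known ground truth
#'
#' Draws spatially smoothed random fields for retardance, diattenuation and
#' axial fiber orientation according to a [group_preset], inserts air lacunae
#' up to the preset's fill fraction, and composes each tissue pixel as
#' `tau * depolarizer %*% retarder(delta, theta) %*% diattenuator(D, theta)`.
#' Air pixels carry a near-zero transmittance identity matrix, so they land in
#' the background mask of [normalize_mm]. Identical seeds give bit-identical
#' output.
#'
#' @param preset a [group_preset].
#' @param height,width image size in pixels.
#' @param seed integer random seed (mandatory: phantoms are reproducible
#'   objects).
#' @param smooth_px Gaussian smoothing kernel SD in pixels for all fields.
#' @param tau_foreground mean tissue transmittance before normalization.
#' @return list with `image` (unnormalized [mueller_image]) and `truth`
#'   (class `phantom_truth`: `delta_map`, `diat_map`, `orient_map`,
#'   `depol_map`, `air_mask`).
#' @export
generate_phantom <- function(preset, height = 128, width = 128, seed,
                             smooth_px = 5, tau_foreground = 0.8) {
  stopifnot(inherits(preset, "group_preset"))
  if (missing(seed)) stop("`seed` is mandatory for phantom generation")
  set.seed(as.integer(seed))

  delta_map <- clamp(preset$delta_mean +
                       preset$delta_sd * gaussian_field(height, width, smooth_px),
                     0, pi)
  diat_map <- clamp(preset$diat_mean +
                      preset$diat_sd * gaussian_field(height, width, smooth_px),
                    0, 0.999)
  orient_map <- wrap_axial(preset$orient_mean_deg +
                             preset$orient_sd_deg * gaussian_field(height, width, smooth_px))
  tau <- clamp(tau_foreground * (1 + 0.05 * gaussian_field(height, width, smooth_px)),
               0.05, 1)

  air <- matrix(FALSE, height, width)
  if (preset$fiber_fill_fraction < 1) {
    lac <- gaussian_field(height, width, 2 * smooth_px)
    air <- lac < stats::quantile(lac, 1 - preset$fiber_fill_fraction, names = FALSE)
  }

  n <- height * width
  dep <- element_depolarizer(preset$depol_diag)
  fld <- array(0, c(n, 4L, 4L))
  dvec <- as.vector(diat_map); thv <- as.vector(orient_map)
  dlv <- as.vector(delta_map); tav <- as.vector(tau); airv <- as.vector(air)

  # closed-form per-pixel composition, vectorized over pixels
  ct <- cos(2 * thv * pi / 180); st <- sin(2 * thv * pi / 180)
  cd <- cos(dlv); sd_ <- sin(dlv)
  ret <- array(0, c(n, 4L, 4L))
  ret[, 1, 1] <- 1
  ret[, 2, 2] <- ct^2 + st^2 * cd; ret[, 2, 3] <- ct * st * (1 - cd); ret[, 2, 4] <- -st * sd_
  ret[, 3, 2] <- ret[, 2, 3];      ret[, 3, 3] <- st^2 + ct^2 * cd;   ret[, 3, 4] <- ct * sd_
  ret[, 4, 2] <- st * sd_;         ret[, 4, 3] <- -ct * sd_;          ret[, 4, 4] <- cd

  r <- sqrt(1 - dvec^2)
  dia <- array(0, c(n, 4L, 4L))
  dia[, 1, 1] <- 1
  dia[, 1, 2] <- dvec * ct; dia[, 1, 3] <- dvec * st
  dia[, 2, 1] <- dia[, 1, 2]; dia[, 3, 1] <- dia[, 1, 3]
  dia[, 2, 2] <- r + (1 - r) * ct^2; dia[, 2, 3] <- (1 - r) * ct * st
  dia[, 3, 2] <- dia[, 2, 3]; dia[, 3, 3] <- r + (1 - r) * st^2
  dia[, 4, 4] <- r

  fld <- fld_matmul(fld_matmul(fld_const(dep, n), ret), dia) * tav

  # air: tiny-transmittance identity, below any sensible background threshold
  if (any(airv)) {
    fld[airv, , ] <- 0
    for (i in 1:4) fld[airv, i, i] <- 1e-4
  }

  truth <- structure(
    list(delta_map = ifelse(air, NA_real_, delta_map),
         diat_map = ifelse(air, NA_real_, diat_map),
         orient_map = ifelse(air, NA_real_, orient_map),
         depol_map = preset$depol_diag, air_mask = air,
         preset = preset),
    class = "phantom_truth"
  )
  list(image = mueller_image(array(fld, c(height, width, 4L, 4L)),
                             wavelength_nm = preset$wavelength_nm),
       truth = truth)
}

#' Simulate a polarimetric measurement of a Mueller image
#'
#' For each generator state `s`, forms `S_out = M s` per pixel, projects onto
#' an ideal six-state analyzer, optionally adds Gaussian intensity noise
#' (relative scale `noise_sigma`, the stated simplification of photon noise),
#' averages `n_frames` repeated frames, and reassembles output Stokes vectors
#' by analyzer least squares. Feeding the result to [reconstruct_mm] closes
#' the measurement loop.
#'
#' @param image a [mueller_image].
#' @param generator generator [stokes_set]; default [default_psg].
#' @param noise_sigma additive Gaussian intensity noise SD relative to unit
#'   incident intensity.
#' @param seed integer seed (mandatory when `noise_sigma > 0`).
#' @param n_frames number of repeated frames averaged before Stokes assembly.
#' @return array `c(height, width, 4, N)` of measured output Stokes vectors,
#'   with the generator attached as attribute `"generator"`.
#' @export
simulate_measurement <- function(image, generator = default_psg(),
                                 noise_sigma = 0, seed = NULL, n_frames = 1) {
  stopifnot(inherits(image, "mueller_image"))
  gen <- as_state_matrix(generator)
  if (inherits(generator, "stokes_set") && generator$role != "generator") {
    stop("`generator` must be a generator-role stokes_set")
  }
  sv <- svd(gen, nu = 0, nv = 0)$d
  if (sv[4L] / sv[1L] < 1e-10) {
    stop(sprintf("generator state matrix is rank deficient (condition number %.3g)",
                 sv[1L] / max(sv[4L], .Machine$double.xmin)))
  }
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("`seed` is mandatory when noise_sigma > 0")
    set.seed(as.integer(seed))
  }
  h <- image$height; w <- image$width; n <- h * w; nst <- ncol(gen)
  fld <- mm_field(image)
  an <- analyzer_states()
  an_pinv <- solve(t(an) %*% an) %*% t(an)  # least-squares Stokes assembly
  out <- array(0, c(n, 4L, nst))
  for (k in seq_len(nst)) {
    s_out <- matrix(0, n, 4L)
    for (i in 1:4) s_out[, i] <- fld[, i, ] %*% gen[, k]
    intens <- 0.5 * s_out %*% t(an)          # I_j = a_j . S / 2
    if (noise_sigma > 0) {
      acc <- matrix(0, n, nrow(an))
      for (f in seq_len(n_frames)) {
        acc <- acc + intens + matrix(stats::rnorm(n * nrow(an), sd = noise_sigma),
                                     n, nrow(an))
      }
      intens <- acc / n_frames
    }
    out[, , k] <- 2 * intens %*% t(an_pinv)
  }
  res <- array(out, c(h, w, 4L, nst))
  attr(res, "generator") <- stokes_set(gen, "generator")
  res
}
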