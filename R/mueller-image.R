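#' Per-pixel Mueller matrix image
#'
#' The central container of the package: a real 4x4 Mueller matrix at every
#' pixel of an image grid, stored as an `height x width x 4 x 4` array in the
#' Stokes basis (I, Q, U, V) with horizontal linear polarization mapped to +Q.
#' Every constructor and extractor in the package uses this one convention.
#'
#' @param elements numeric array of dimension `c(height, width, 4, 4)`, or a
#'   single 4x4 matrix (promoted to a 1x1-pixel image).
#' @param normalized logical; `TRUE` means every foreground pixel has been
#'   divided by its `m11` (so `m11 == 1` there).
#' @param wavelength_nm illumination wavelength metadata (default 633).
#' @param background optional logical `height x width` matrix marking
#'   non-tissue (air) pixels; they are excluded from all parameter statistics.
#' @return an object of class `mueller_image`.
#' @export
mueller_image <- function(elements, normalized = FALSE, wavelength_nm = 633,
                          background = NULL) {
  if (is.matrix(elements) && all(dim(elements) == c(4L, 4L))) {
    elements <- array(elements, c(1L, 1L, 4L, 4L))
  }
  d <- dim(elements)
  if (length(d) != 4L || d[3L] != 4L || d[4L] != 4L) {
    stop("`elements` must be an array of dimension c(height, width, 4, 4)")
  }
  if (!is.null(background)) {
    background <- matrix(as.logical(background), d[1L], d[2L])
  }
  structure(
    list(elements = elements, height = d[1L], width = d[2L],
         normalized = isTRUE(normalized), wavelength_nm = wavelength_nm,
         background = background),
    class = "mueller_image"
  )
}

#' @export
print.mueller_image <- function(x, ...) {
  nbg <- if (is.null(x$background)) 0L else sum(x$background)
  cat(sprintf("<mueller_image> %d x %d px, %s, wavelength %g nm, %d background px\n",
              x$height, x$width,
              if (x$normalized) "m11-normalized" else "unnormalized",
              x$wavelength_nm, nbg))
  invisible(x)
}

#' @export
dim.mueller_image <- function(x) c(x$height, x$width)

# flatten image pixels to an (n, 4, 4) field; optionally foreground only
mm_field <- function(image, foreground_only = FALSE) {
  n <- image$height * image$width
  fld <- array(image$elements, c(n, 4L, 4L))
  if (foreground_only && !is.null(image$background)) {
    fld <- fld[!as.vector(image$background), , , drop = FALSE]
  }
  fld
}

foreground_mask <- function(image) {
  if (is.null(image$background)) {
    matrix(TRUE, image$height, image$width)
  } else {
    !image$background
  }
}

#' Normalize a Mueller image by its per-pixel m11
#'
#' Divides every retained pixel by its `m11` (total transmittance) so that
#' derived parameters such as linear diattenuation lie in `[0, 1]`. Pixels
#' whose `m11` falls at or below the air threshold `epsilon_air` are flagged
#' as background and left untouched.
#'
#' @param image a [mueller_image].
#' @param epsilon_air background threshold on `m11`. Default: 5% of the 99th
#'   percentile of the image's `m11`, a configurable stand-in for the air/tissue
#'   separation the measurement itself does not provide.
#' @return a normalized [mueller_image] carrying the background mask.
#' @export
normalize_mm <- function(image, epsilon_air = NULL) {
  stopifnot(inherits(image, "mueller_image"))
  m11 <- image$elements[, , 1L, 1L]
  if (is.null(epsilon_air)) {
    epsilon_air <- 0.05 * stats::quantile(m11, 0.99, names = FALSE)
  }
  bg <- m11 <= epsilon_air
  if (!is.null(image$background)) bg <- bg | image$background
  if (all(bg)) {
    stop("empty foreground: every pixel has m11 <= epsilon_air (", epsilon_air, ")")
  }
  el <- image$elements
  scale <- ifelse(bg, 1, m11)
  for (i in 1:4) for (j in 1:4) el[, , i, j] <- el[, , i, j] / scale
  mueller_image(el, normalized = TRUE, wavelength_nm = image$wavelength_nm,
                background = bg)
}

#' Diagnose physically suspect Mueller pixels
#'
#' Flags pixels with non-positive transmittance (`m11 <= 0`) and pixels
#' violating passivity (`|m_ij| > m11`, within `tol`). Purely diagnostic:
#' nothing is modified and no error is raised.
#'
#' @param image a [mueller_image].
#' @param tol numeric slack on the passivity comparison.
#' @return a list of class `mm_diagnostics` with per-pixel logical maps
#'   `m11_nonpositive` and `passivity_violated`, combined `flagged`, and the
#'   `fraction_flagged` scalar.
#' @export
validate_mm <- function(image, tol = 1e-9) {
  stopifnot(inherits(image, "mueller_image"))
  m11 <- image$elements[, , 1L, 1L]
  nonpos <- m11 <= 0
  pass <- matrix(FALSE, image$height, image$width)
  for (i in 1:4) for (j in 1:4) {
    if (i == 1L && j == 1L) next
    pass <- pass | (abs(image$elements[, , i, j]) > abs(m11) + tol)
  }
  flagged <- nonpos | pass
  structure(
    list(m11_nonpositive = nonpos, passivity_violated = pass, flagged = flagged,
         n_flagged = sum(flagged), fraction_flagged = mean(flagged)),
    class = "mm_diagnostics"
  )
}

#' @export
print.mm_diagnostics <- function(x, ...) {
  cat(sprintf("<mm_diagnostics> %d flagged pixels (%.3f%%): %d with m11 <= 0, %d passivity\n",
              x$n_flagged, 100 * x$fraction_flagged,
              sum(x$m11_nonpositive), sum(x$passivity_violated)))
  invisible(x)
}

#' Rotate a sample in-plane
#'
#' Conjugates each Mueller matrix by the Stokes rotation, `M' = R(phi) M
#' R(-phi)`, which is what physically rotating the sample by `phi` does to its
#' measured matrix. Rotation-invariant parameters must not change under this
#' transform; axial orientation parameters shift by exactly `phi` mod 180.
#'
#' @param x a [mueller_image] or a single 4x4 matrix.
#' @param phi_deg rotation angle in degrees.
#' @return object of the same type as `x`.
#' @export
rotate_sample <- function(x, phi_deg) {
  r <- mm_rotation(phi_deg)
  rinv <- mm_rotation(-phi_deg)
  if (is.matrix(x)) return(r %*% x %*% rinv)
  stopifnot(inherits(x, "mueller_image"))
  n <- x$height * x$width
  fld <- mm_field(x)
  fld <- fld_matmul(fld_matmul(fld_const(r, n), fld), fld_const(rinv, n))
  mueller_image(array(fld, c(x$height, x$width, 4L, 4L)),
                normalized = x$normalized, wavelength_nm = x$wavelength_nm,
                background = x$background)
}
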