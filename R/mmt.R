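#' Mueller matrix transformation (MMT) parameters
#'
#' Closed-form per-pixel parameters computed directly from matrix elements of
#' an m11-normalized Mueller image:
#' \describe{
#'   \item{m14, m41, CD = m14 + m41}{circular diattenuation / circular
#'     dichroism anisotropy.}
#'   \item{m44}{circular depolarization.}
#'   \item{D_L, P_L}{linear diattenuation `sqrt(m12^2+m13^2)` and polarizance
#'     `sqrt(m21^2+m31^2)`.}
#'   \item{q_L, r_L}{capability of transforming between linear and circular
#'     polarization, `sqrt(m42^2+m43^2)` and `sqrt(m24^2+m34^2)`.}
#'   \item{t1, b, A}{overall linear anisotropy. Default (rotation-invariant
#'     literature form): `t1 = sqrt((m22-m33)^2 + (m23+m32)^2)/2`,
#'     `b = (m22+m33)/2`, `A = 2 b t1 / (b^2 + t1^2)`.}
#'   \item{detB, normB}{determinant and Frobenius norm of the central 2x2
#'     block `(m22, m23; m32, m33)`.}
#'   \item{alpha_r_deg}{retardance orientation, `atan2(-m24, m34)/2`, axial
#'     degrees in `[0, 180)`.}
#' }
#'
#' @param image an m11-normalized [mueller_image] or a single 4x4 matrix.
#' @param t1_printed if `TRUE`, use the typeset variant
#'   `t1 = sqrt((m22-m33)^2 + (m22+m33)^2)/2`. This variant equals 1 on the
#'   identity and is not rotation invariant; it is provided for comparison
#'   only and the default remains the invariant form.
#' @return object of class `mmt_result`: named list of `height x width`
#'   parameter maps (background pixels `NA`).
#' @export
mmt <- function(image, t1_printed = FALSE) {
  if (is.matrix(image)) image <- mueller_image(image, normalized = TRUE)
  stopifnot(inherits(image, "mueller_image"))
  h <- image$height; w <- image$width
  e <- function(i, j) matrix(image$elements[, , i, j], h, w)
  mask <- !foreground_mask(image)
  put <- function(v) { v[mask] <- NA_real_; v }

  t1 <- if (t1_printed) {
    0.5 * sqrt((e(2, 2) - e(3, 3))^2 + (e(2, 2) + e(3, 3))^2)
  } else {
    0.5 * sqrt((e(2, 2) - e(3, 3))^2 + (e(2, 3) + e(3, 2))^2)
  }
  b <- 0.5 * (e(2, 2) + e(3, 3))
  denom <- b^2 + t1^2
  a_par <- ifelse(denom > 0, 2 * b * t1 / denom, 0)

  maps <- list(
    m14 = e(1, 4), m41 = e(4, 1), CD = e(1, 4) + e(4, 1), m44 = e(4, 4),
    D_L = sqrt(e(1, 2)^2 + e(1, 3)^2),
    P_L = sqrt(e(2, 1)^2 + e(3, 1)^2),
    q_L = sqrt(e(4, 2)^2 + e(4, 3)^2),
    r_L = sqrt(e(2, 4)^2 + e(3, 4)^2),
    t1 = t1, b = b, A = a_par,
    detB = e(2, 2) * e(3, 3) - e(2, 3) * e(3, 2),
    normB = sqrt(e(2, 2)^2 + e(2, 3)^2 + e(3, 2)^2 + e(3, 3)^2),
    alpha_r_deg = wrap_axial(0.5 * atan2(-e(2, 4), e(3, 4)) * 180 / pi)
  )
  structure(c(lapply(maps, put), list(t1_printed = t1_printed)),
            class = "mmt_result")
}

# canonical parameter catalogue ------------------------------------------------

PBP_INVARIANT <- c("D", "Delta", "delta", "m14", "m41", "CD", "m44",
                   "D_L", "P_L", "q_L", "r_L", "t1", "A", "detB", "normB")
PBP_VARIANT <- c("theta", "alpha_r")

#' Catalogue of polarization basic parameters
#'
#' @return data.frame with columns `name`, `source` (`"mmpd"` or `"mmt"`) and
#'   `rotation_variant`. Exactly 15 parameters are rotation invariant; the two
#'   axial orientation angles `theta` and `alpha_r` are rotation variant.
#' @export
pbp_parameters <- function() {
  data.frame(
    name = c(PBP_INVARIANT, PBP_VARIANT),
    source = c("mmpd", "mmpd", "mmpd", rep("mmt", 12L), "mmpd", "mmt"),
    rotation_variant = c(rep(FALSE, 15L), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Bundle per-pixel parameter maps into a PBP stack
#'
#' Runs [mmpd] and/or [mmt] as needed and collects the selected parameter maps
#' with their rotation-variance flags and the shared background mask.
#'
#' @param image an m11-normalized [mueller_image].
#' @param selection character vector of parameter names (see
#'   [pbp_parameters]), or `"all"` for all 17, or `"invariant"` for the 15
#'   rotation-invariant ones.
#' @param t1_printed forwarded to [mmt].
#' @return object of class `pbp_stack`: `maps` (named list of matrices),
#'   `rotation_variant` (named logical), `background`, `degenerate`.
#' @export
pbp_stack <- function(image, selection = "all", t1_printed = FALSE) {
  cat_tab <- pbp_parameters()
  if (identical(selection, "all")) {
    selection <- cat_tab$name
  } else if (identical(selection, "invariant")) {
    selection <- PBP_INVARIANT
  }
  bad <- setdiff(selection, cat_tab$name)
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(cat_tab$name, collapse = ", "))
  }
  need_mmpd <- any(selection %in% cat_tab$name[cat_tab$source == "mmpd"])
  need_mmt <- any(selection %in% cat_tab$name[cat_tab$source == "mmt"])
  pd <- if (need_mmpd) mmpd(image) else NULL
  mt <- if (need_mmt) mmt(image, t1_printed = t1_printed) else NULL
  grab <- function(nm) {
    switch(nm,
           D = pd$D, Delta = pd$Delta, delta = pd$delta, theta = pd$theta_deg,
           alpha_r = mt$alpha_r_deg, mt[[nm]])
  }
  maps <- stats::setNames(lapply(selection, grab), selection)
  rv <- stats::setNames(cat_tab$rotation_variant[match(selection, cat_tab$name)],
                        selection)
  bg <- if (is.null(image$background)) {
    matrix(FALSE, image$height, image$width)
  } else {
    image$background
  }
  structure(
    list(maps = maps, rotation_variant = rv, background = bg,
         degenerate = if (is.null(pd)) matrix(FALSE, image$height, image$width) else pd$degenerate,
         t1_printed = t1_printed),
    class = "pbp_stack"
  )
}

#' @export
print.pbp_stack <- function(x, ...) {
  cat(sprintf("<pbp_stack> %d parameters (%d rotation-variant), %d x %d px\n",
              length(x$maps), sum(x$rotation_variant),
              nrow(x$background), ncol(x$background)))
  invisible(x)
}
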