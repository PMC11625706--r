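#' Stokes rotation matrix
#'
#' Mueller matrix of an in-plane coordinate rotation by `phi_deg`: mixes the
#' Q and U components by the doubled angle, leaves I and V alone.
#'
#' @param phi_deg rotation angle in degrees.
#' @return 4x4 matrix.
#' @export
mm_rotation <- function(phi_deg) {
  c2 <- cos(2 * phi_deg * pi / 180)
  s2 <- sin(2 * phi_deg * pi / 180)
  rbind(c(1, 0, 0, 0),
        c(0, c2, -s2, 0),
        c(0, s2, c2, 0),
        c(0, 0, 0, 1))
}

#' Pure linear retarder
#'
#' Mueller matrix of an elliptically non-absorbing linear retarder with
#' retardance `delta` (radians, phase delay between the fast and slow axes)
#' and fast-axis orientation `theta_deg` (axial, degrees).
#'
#' @param delta retardance in radians, in `[0, pi]`.
#' @param theta_deg fast-axis orientation, degrees in `[0, 180)`.
#' @return 4x4 matrix with `m11 = 1`.
#' @export
element_retarder <- function(delta, theta_deg = 0) {
  if (!is.finite(delta) || delta < 0 || delta > pi) {
    stop("retardance `delta` must lie in [0, pi] radians")
  }
  ct <- cos(2 * theta_deg * pi / 180)
  st <- sin(2 * theta_deg * pi / 180)
  cd <- cos(delta); sd <- sin(delta)
  rbind(c(1, 0, 0, 0),
        c(0, ct^2 + st^2 * cd, ct * st * (1 - cd), -st * sd),
        c(0, ct * st * (1 - cd), st^2 + ct^2 * cd, ct * sd),
        c(0, st * sd, -ct * sd, cd))
}

#' Pure linear diattenuator
#'
#' Mueller matrix (m11-normalized) of a linear diattenuator with diattenuation
#' `d` and transmission axis `theta_deg`.
#'
#' @param d diattenuation in `[0, 1]`.
#' @param theta_deg transmission-axis orientation, degrees.
#' @return 4x4 matrix with `m11 = 1`.
#' @export
element_diattenuator <- function(d, theta_deg = 0) {
  if (!is.finite(d) || d < 0 || d > 1) stop("diattenuation `d` must lie in [0, 1]")
  ct <- cos(2 * theta_deg * pi / 180)
  st <- sin(2 * theta_deg * pi / 180)
  dv <- c(d * ct, d * st, 0)
  r <- sqrt(1 - d^2)
  dhat <- if (d > 0) dv / d else c(0, 0, 0)
  md <- r * diag(3) + (1 - r) * (dhat %o% dhat)
  out <- rbind(c(1, dv), cbind(dv, md))
  dimnames(out) <- NULL
  out
}

#' Pure diagonal depolarizer
#'
#' Mueller matrix `diag(1, a, b, c)`: each factor is the fraction of the
#' corresponding polarized Stokes component that survives.
#'
#' @param a,b,c depolarization factors in `(0, 1]` (Q, U, V channels). `a` may
#'   also be a length-3 vector.
#' @return 4x4 diagonal matrix.
#' @export
element_depolarizer <- function(a, b = NULL, c = NULL) {
  f <- if (length(a) == 3L && is.null(b)) as.numeric(a) else c(a, b, c)
  if (length(f) != 3L || any(!is.finite(f)) || any(f <= 0) || any(f > 1)) {
    stop("depolarization factors must be three values in (0, 1]")
  }
  diag(c(1, f))
}

#' Pure-element Mueller matrix dispatcher
#'
#' @param kind `"retarder"`, `"diattenuator"` or `"depolarizer"`.
#' @param ... parameters forwarded to [element_retarder],
#'   [element_diattenuator] or [element_depolarizer].
#' @return 4x4 matrix.
#' @export
element_mm <- function(kind = c("retarder", "diattenuator", "depolarizer"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         retarder = element_retarder(...),
         diattenuator = element_diattenuator(...),
         depolarizer = element_depolarizer(...))
}

#' Compose optical elements
#'
#' Left-to-right matrix product of 4x4 Mueller matrices; the conventional
#' depolarizer - retarder - diattenuator order reproduces the polar
#' decomposition factor order `M_Delta M_R M_D`.
#'
#' @param elements list of 4x4 matrices (or several matrices via `...`).
#' @param ... alternative way to pass the matrices directly.
#' @return 4x4 matrix product.
#' @export
compose_elements <- function(elements = NULL, ...) {
  if (is.null(elements)) {
    elements <- list(...)
  } else if (is.matrix(elements)) {
    elements <- c(list(elements), list(...))
  }
  if (length(elements) < 1L) stop("need at least one element matrix")
  Reduce(`%*%`, elements)
}
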