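#' Ordered set of Stokes states for a polarization state generator/analyzer
#'
#' @param states 4 x N numeric matrix, one Stokes vector (S0, S1, S2, S3) per
#'   column, N >= 4.
#' @param role `"generator"` (PSG: illumination states sent into the sample)
#'   or `"analyzer"`. Generator sets must have full rank 4.
#' @return object of class `stokes_set`.
#' @export
stokes_set <- function(states, role = c("generator", "analyzer")) {
  role <- match.arg(role)
  states <- as.matrix(states)
  if (nrow(states) != 4L || ncol(states) < 4L) {
    stop("`states` must be a 4 x N matrix with N >= 4")
  }
  s0 <- states[1L, ]
  if (any(s0 <= 0)) stop("every Stokes state must have S0 > 0")
  dop2 <- colSums(states[2:4, , drop = FALSE]^2)
  if (any(dop2 > s0^2 * (1 + 1e-9))) {
    stop("unphysical Stokes state: S1^2 + S2^2 + S3^2 > S0^2")
  }
  if (role == "generator") {
    sv <- svd(states, nu = 0, nv = 0)$d
    if (sv[4L] / sv[1L] < 1e-10) {
      stop(sprintf("generator state matrix is rank deficient (condition number %.3g)",
                   sv[1L] / max(sv[4L], .Machine$double.xmin)))
    }
  }
  structure(list(states = states, role = role), class = "stokes_set")
}

#' @export
print.stokes_set <- function(x, ...) {
  cat(sprintf("<stokes_set> role=%s, %d states, condition number %.3g\n",
              x$role, ncol(x$states), kappa(x$states, exact = TRUE)))
  invisible(x)
}

as_state_matrix <- function(x) {
  if (inherits(x, "stokes_set")) x$states else as.matrix(x)
}

#' Default polarization state generator
#'
#' A fixed 0-degree linear polarizer followed by a quarter-wave plate at the
#' rotation angles `qwp_angles_deg`. The default angles (-45, 0, 30, 60)
#' produce four independent states with a well-conditioned 4x4 state matrix.
#'
#' @param qwp_angles_deg quarter-wave-plate fast-axis angles, degrees.
#' @return a generator [stokes_set].
#' @export
default_psg <- function(qwp_angles_deg = c(-45, 0, 30, 60)) {
  pol0 <- element_diattenuator(1, 0)
  states <- vapply(qwp_angles_deg, function(a) {
    qwp <- element_retarder(pi / 2, a)
    as.numeric(qwp %*% (pol0 %*% c(1, 0, 0, 0)))
  }, numeric(4L))  # m11-normalized elements: states come out at unit intensity
  stokes_set(states, "generator")
}

# ideal six-state analyzer: H, V, +45, -45, right circular, left circular.
# rows are analyzer Stokes vectors a_k; measured intensity I_k = a_k . S / 2
analyzer_states <- function() {
  rbind(c(1,  1,  0,  0),
        c(1, -1,  0,  0),
        c(1,  0,  1,  0),
        c(1,  0, -1,  0),
        c(1,  0,  0,  1),
        c(1,  0,  0, -1))
}

#' Reconstruct Mueller matrices from generator and measured output states
#'
#' Implements the polarimetric measurement equation `S_out = M S_in`: given N
#' generator states and the corresponding measured output Stokes vectors, the
#' Mueller matrix is the least-squares solution `M = S_out S_in^+`, which is
#' the exact inverse when N = 4.
#'
#' @param s_in generator [stokes_set] (or 4 x N matrix).
#' @param s_out measured output states: a 4 x N matrix for a single pixel, or
#'   an array of dimension `c(height, width, 4, N)` for an image batch.
#' @param wavelength_nm carried into the returned [mueller_image] metadata.
#' @return a 4x4 matrix (single pixel) or a [mueller_image] (batch); both carry
#'   the condition number of the generator matrix as attribute `"condition"`.
#' @export
reconstruct_mm <- function(s_in, s_out, wavelength_nm = 633) {
  sin_m <- as_state_matrix(s_in)
  if (nrow(sin_m) != 4L || ncol(sin_m) < 4L) {
    stop("`s_in` must provide at least 4 Stokes states")
  }
  sv <- svd(sin_m, nu = 0, nv = 0)$d
  cond <- sv[1L] / max(sv[4L], .Machine$double.xmin)
  if (sv[4L] / sv[1L] < 1e-10) {
    stop(sprintf("generator state matrix is rank deficient (condition number %.3g)",
                 cond))
  }
  # right pseudo-inverse: exact inverse when N = 4
  pinv <- t(sin_m) %*% solve(sin_m %*% t(sin_m))
  if (is.matrix(s_out)) {
    if (!all(dim(s_out) == dim(sin_m))) {
      stop("`s_out` must have the same 4 x N shape as the generator set")
    }
    m <- s_out %*% pinv
    attr(m, "condition") <- cond
    return(m)
  }
  d <- dim(s_out)
  if (length(d) != 4L || d[3L] != 4L || d[4L] != ncol(sin_m)) {
    stop("batch `s_out` must be an array c(height, width, 4, N)")
  }
  n <- d[1L] * d[2L]
  fld <- array(s_out, c(n, 4L, ncol(sin_m)))
  mfld <- fld_matmul(fld, fld_const(pinv, n))
  img <- mueller_image(array(mfld, c(d[1L], d[2L], 4L, 4L)),
                       wavelength_nm = wavelength_nm)
  attr(img, "condition") <- cond
  img
}
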