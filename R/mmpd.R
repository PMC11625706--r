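#' Lu-Chipman polar decomposition of a Mueller image
#'
#' Factorizes every foreground pixel as `M = M_Delta M_R M_D` (depolarizer,
#' retarder, diattenuator) and extracts the scalar polarization basic
#' parameters:
#' \describe{
#'   \item{D}{diattenuation, `sqrt(m12^2 + m13^2 + m14^2) / m11`, in `[0,1]`.}
#'   \item{Delta}{degree of overall depolarization, `1 - |tr(m_Delta)| / 3`
#'     computed from the 3x3 depolarizer submatrix, in `[0,1]`.}
#'   \item{delta}{linear retardance in radians,
#'     `acos(sqrt((MR22+MR33)^2 + (MR32-MR23)^2) - 1)`, branch `[0, pi]`.}
#'   \item{alpha}{optical rotation angle,
#'     `atan2(MR32 - MR23, MR22 + MR33)` (quadrant-aware), radians.}
#'   \item{theta_deg}{fast-axis orientation,
#'     `0.5 atan2(MR42 - MR24, MR34 - MR43)`, axial degrees in `[0, 180)`.}
#' }
#'
#' The depolarizer/retarder split uses the eigen solution of `m' m'^T` with
#' the determinant-sign rule. Pixels where the retained 3x3 submatrix is
#' numerically singular (fully depolarizing, `|det| <= degeneracy_tol`) or
#' where the diattenuation saturates are flagged `degenerate` and return `NA`
#' parameters instead of raising an error.
#'
#' @param image an m11-normalized [mueller_image] (see [normalize_mm]), or a
#'   single 4x4 matrix.
#' @param degeneracy_tol singularity threshold on `|det m'|`.
#' @return object of class `mmpd_result`: parameter maps (`height x width`
#'   matrices) `D`, `Delta`, `delta`, `alpha`, `theta_deg`; factor fields
#'   `M_D`, `M_Delta`, `M_R` (`height x width x 4 x 4`); logical maps
#'   `degenerate` and `background`.
#' @export
mmpd <- function(image, degeneracy_tol = 1e-12) {
  if (is.matrix(image)) image <- mueller_image(image, normalized = TRUE)
  stopifnot(inherits(image, "mueller_image"))
  h <- image$height; w <- image$width
  fg <- foreground_mask(image)
  fld <- mm_field(image)
  m11 <- fld[, 1L, 1L]
  if (any(abs(m11[as.vector(fg)] - 1) > 1e-6)) {
    stop("`mmpd` expects an m11-normalized image; run normalize_mm() first")
  }
  n <- h * w
  na_map <- matrix(NA_real_, h, w)

  dvec <- fld[, 1L, 2:4, drop = TRUE]
  if (is.null(dim(dvec))) dvec <- matrix(dvec, nrow = n)
  d <- sqrt(rowSums(dvec^2))
  sat <- d > 1 - 1e-6            # saturated diattenuation: split undefined
  dcl <- pmin(d, 1 - 1e-6)
  c2 <- 1 / (1 - dcl^2)
  c1 <- 1 / sqrt(1 - dcl^2)
  dhat <- dvec / ifelse(d > 1e-12, d, 1)
  dhat[d <= 1e-12, ] <- 0

  # analytic inverse of the diattenuator factor (Schur complement form)
  mdinv <- array(0, c(n, 4L, 4L))
  mdinv[, 1L, 1L] <- c2
  for (j in 1:3) {
    mdinv[, 1L, j + 1L] <- -c2 * dvec[, j]
    mdinv[, j + 1L, 1L] <- -c2 * dvec[, j]
  }
  for (i in 1:3) for (j in 1:3) {
    mdinv[, i + 1L, j + 1L] <- (c2 - c1) * dhat[, i] * dhat[, j] +
      if (i == j) c1 else 0
  }

  mp4 <- fld_matmul(fld, mdinv)          # M' = M M_D^-1
  mp <- mp4[, 2:4, 2:4, drop = FALSE]    # 3x3 remainder
  pdelta <- mp4[, 2:4, 1L, drop = TRUE]
  if (is.null(dim(pdelta))) pdelta <- matrix(pdelta, nrow = n)

  a <- fld_matmul(mp, fld_transpose(mp)) # m' m'^T, symmetric PSD
  lam <- pmax(fld_eigvals_sym3(a), 0)
  sq <- sqrt(lam)
  k1 <- sq[, 1L] + sq[, 2L] + sq[, 3L]
  k2 <- sq[, 1L] * sq[, 2L] + sq[, 2L] * sq[, 3L] + sq[, 3L] * sq[, 1L]
  k3 <- sq[, 1L] * sq[, 2L] * sq[, 3L]
  detmp <- fld_det3(mp)
  sgn <- ifelse(detmp < 0, -1, 1)

  cc <- a
  dd <- a * k1
  for (i in 1:3) {
    cc[, i, i] <- cc[, i, i] + k2
    dd[, i, i] <- dd[, i, i] + k3
  }
  ccinv <- fld_inv3(cc, tol = degeneracy_tol)
  mdelta <- fld_matmul(ccinv$inv, dd) * sgn
  mdinv3 <- fld_inv3(mdelta, tol = degeneracy_tol)
  mr <- fld_matmul(mdinv3$inv, mp)

  degen <- sat | !is.finite(detmp) | abs(detmp) <= degeneracy_tol |
    ccinv$singular | mdinv3$singular
  degen[!as.vector(fg)] <- FALSE

  tr_mdelta <- mdelta[, 1L, 1L] + mdelta[, 2L, 2L] + mdelta[, 3L, 3L]
  delta_big <- 1 - abs(tr_mdelta) / 3
  cosd <- sqrt((mr[, 1L, 1L] + mr[, 2L, 2L])^2 + (mr[, 2L, 1L] - mr[, 1L, 2L])^2) - 1
  delta_ret <- acos(clamp(cosd, -1, 1))
  alpha <- atan2(mr[, 2L, 1L] - mr[, 1L, 2L], mr[, 1L, 1L] + mr[, 2L, 2L])
  theta <- wrap_axial(0.5 * atan2(mr[, 3L, 1L] - mr[, 1L, 3L],
                                  mr[, 2L, 3L] - mr[, 3L, 2L]) * 180 / pi)

  mask <- !as.vector(fg) | degen
  put <- function(v) { v[mask] <- NA_real_; matrix(v, h, w) }

  # assemble factor fields
  md4 <- array(0, c(n, 4L, 4L))
  md4[, 1L, 1L] <- 1
  r <- sqrt(pmax(1 - dcl^2, 0))
  for (j in 1:3) {
    md4[, 1L, j + 1L] <- dvec[, j]
    md4[, j + 1L, 1L] <- dvec[, j]
  }
  for (i in 1:3) for (j in 1:3) {
    md4[, i + 1L, j + 1L] <- (1 - r) * dhat[, i] * dhat[, j] + if (i == j) r else 0
  }
  mdelta4 <- array(0, c(n, 4L, 4L)); mdelta4[, 1L, 1L] <- 1
  mr4 <- array(0, c(n, 4L, 4L)); mr4[, 1L, 1L] <- 1
  for (i in 1:3) {
    mdelta4[, i + 1L, 1L] <- pdelta[, i]
    for (j in 1:3) {
      mdelta4[, i + 1L, j + 1L] <- mdelta[, i, j]
      mr4[, i + 1L, j + 1L] <- mr[, i, j]
    }
  }

  structure(
    list(D = put(d), Delta = put(delta_big), delta = put(delta_ret),
         alpha = put(alpha), theta_deg = put(theta),
         M_D = array(md4, c(h, w, 4L, 4L)),
         M_Delta = array(mdelta4, c(h, w, 4L, 4L)),
         M_R = array(mr4, c(h, w, 4L, 4L)),
         degenerate = matrix(degen, h, w),
         background = if (is.null(image$background)) matrix(FALSE, h, w) else image$background),
    class = "mmpd_result"
  )
}

#' @export
print.mmpd_result <- function(x, ...) {
  cat(sprintf("<mmpd_result> %d x %d px, %d degenerate px\n",
              nrow(x$D), ncol(x$D), sum(x$degenerate)))
  invisible(x)
}

#' Reconstruction residual of the polar decomposition factors
#'
#' Frobenius norm of `M - M_Delta M_R M_D` per pixel; a self-check that the
#' factorization reproduces its input.
#'
#' @param image the [mueller_image] that was decomposed.
#' @param result the matching [mmpd] output.
#' @return `height x width` matrix of residual norms (`NA` on background).
#' @export
mmpd_residual <- function(image, result) {
  h <- image$height; w <- image$width; n <- h * w
  recon <- fld_matmul(
    fld_matmul(array(result$M_Delta, c(n, 4L, 4L)), array(result$M_R, c(n, 4L, 4L))),
    array(result$M_D, c(n, 4L, 4L))
  )
  res <- fld_fnorm(array(mm_field(image) - recon, c(n, 4L, 4L)))
  res[as.vector(!foreground_mask(image)) | as.vector(result$degenerate)] <- NA_real_
  matrix(res, h, w)
}
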