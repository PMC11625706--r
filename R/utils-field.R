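# Vectorized linear algebra on "pixel fields": arrays of shape (n, d, d)
# holding one small matrix per pixel. All operations are elementwise over the
# first index so image-sized batches stay in vectorized R.

fld_matmul <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 3L, length(db) == 3L, da[1L] == db[1L], da[3L] == db[2L])
  n <- da[1L]; p <- da[2L]; q <- da[3L]; r <- db[3L]
  out <- array(0, c(n, p, r))
  for (i in seq_len(p)) for (j in seq_len(r)) {
    acc <- numeric(n)
    for (k in seq_len(q)) acc <- acc + a[, i, k] * b[, k, j]
    out[, i, j] <- acc
  }
  out
}

fld_transpose <- function(a) aperm(a, c(1L, 3L, 2L))

# determinant of each 3x3 matrix
fld_det3 <- function(a) {
  a[, 1, 1] * (a[, 2, 2] * a[, 3, 3] - a[, 2, 3] * a[, 3, 2]) -
  a[, 1, 2] * (a[, 2, 1] * a[, 3, 3] - a[, 2, 3] * a[, 3, 1]) +
  a[, 1, 3] * (a[, 2, 1] * a[, 3, 2] - a[, 2, 2] * a[, 3, 1])
}

# inverse of each 3x3 matrix via the adjugate; rows with |det| <= tol give NA
fld_inv3 <- function(a, tol = 0) {
  d <- fld_det3(a)
  bad <- !is.finite(d) | abs(d) <= tol
  d[bad] <- NA_real_
  inv <- array(NA_real_, dim(a))
  inv[, 1, 1] <-  (a[, 2, 2] * a[, 3, 3] - a[, 2, 3] * a[, 3, 2]) / d
  inv[, 1, 2] <- -(a[, 1, 2] * a[, 3, 3] - a[, 1, 3] * a[, 3, 2]) / d
  inv[, 1, 3] <-  (a[, 1, 2] * a[, 2, 3] - a[, 1, 3] * a[, 2, 2]) / d
  inv[, 2, 1] <- -(a[, 2, 1] * a[, 3, 3] - a[, 2, 3] * a[, 3, 1]) / d
  inv[, 2, 2] <-  (a[, 1, 1] * a[, 3, 3] - a[, 1, 3] * a[, 3, 1]) / d
  inv[, 2, 3] <- -(a[, 1, 1] * a[, 2, 3] - a[, 1, 3] * a[, 2, 1]) / d
  inv[, 3, 1] <-  (a[, 2, 1] * a[, 3, 2] - a[, 2, 2] * a[, 3, 1]) / d
  inv[, 3, 2] <- -(a[, 1, 1] * a[, 3, 2] - a[, 1, 2] * a[, 3, 1]) / d
  inv[, 3, 3] <-  (a[, 1, 1] * a[, 2, 2] - a[, 1, 2] * a[, 2, 1]) / d
  list(inv = inv, det = d, singular = bad)
}

# Eigenvalues of each symmetric 3x3 matrix, descending, by the closed-form
# trigonometric solution of the characteristic cubic. Numerically safe for
# repeated eigenvalues (p -> 0 handled by the isotropic branch).
fld_eigvals_sym3 <- function(a) {
  n <- dim(a)[1L]
  a11 <- a[, 1, 1]; a22 <- a[, 2, 2]; a33 <- a[, 3, 3]
  a12 <- a[, 1, 2]; a13 <- a[, 1, 3]; a23 <- a[, 2, 3]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detb / 2, -1), 1)) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

# Frobenius norm of each matrix in the field
fld_fnorm <- function(a) {
  d <- dim(a)
  sqrt(rowSums(matrix(a^2, nrow = d[1L])))
}

# embed a single dxd matrix as a constant field of length n
fld_const <- function(m, n) {
  d <- dim(m)
  aperm(array(m, c(d[1L], d[2L], n)), c(3L, 1L, 2L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# wrap angles in degrees to the axial interval [0, 180)
wrap_axial <- function(theta_deg) {
  out <- theta_deg %% 180
  out[out >= 180 - 1e-12] <- 0
  out
}

# Polynomial rolling checksum of a character vector; manifest integrity only,
# not cryptographic.
checksum32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
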