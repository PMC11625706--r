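# Independent reference implementations used as oracles. These deliberately
# use base solve()/eigen() per pixel rather than the package's vectorized
# closed forms, so agreement is a genuine dual-route check.

oracle_mmpd <- function(m) {
  d3 <- m[1, 2:4]
  d <- sqrt(sum(d3^2))
  r <- sqrt(1 - d^2)
  dhat <- if (d > 0) d3 / d else rep(0, 3)
  md <- r * diag(3) + (1 - r) * dhat %o% dhat
  md4 <- rbind(c(1, d3), cbind(d3, md))
  mp4 <- m %*% solve(md4)
  mp <- mp4[2:4, 2:4]
  aa <- mp %*% t(mp)
  lam <- pmax(eigen(aa, symmetric = TRUE, only.values = TRUE)$values, 0)
  sq <- sqrt(lam)
  k1 <- sum(sq)
  k2 <- sq[1] * sq[2] + sq[2] * sq[3] + sq[3] * sq[1]
  k3 <- prod(sq)
  mdelta <- sign(det(mp)) * solve(aa + k2 * diag(3)) %*% (k1 * aa + k3 * diag(3))
  mr <- solve(mdelta) %*% mp
  list(
    D = d,
    Delta = 1 - abs(sum(diag(mdelta))) / 3,
    delta = acos(min(max(sqrt((mr[1, 1] + mr[2, 2])^2 +
                                (mr[2, 1] - mr[1, 2])^2) - 1, -1), 1)),
    theta_deg = (0.5 * atan2(mr[3, 1] - mr[1, 3], mr[2, 3] - mr[3, 2]) * 180 / pi) %% 180,
    m_delta = mdelta, m_r = mr
  )
}

# closed-form Fisher direction (well-conditioned problems only)
oracle_fisher_direction <- function(x1, x2) {
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  s_p <- crossprod(sweep(x1, 2, mu1)) / nrow(x1) +
    crossprod(sweep(x2, 2, mu2)) / nrow(x2)
  w <- solve(s_p, mu1 - mu2)
  w / sqrt(sum(w^2))
}

# distribution-difference F for many candidate directions at once (columns of v)
f_many <- function(v, x1, x2) {
  y1 <- x1 %*% v; y2 <- x2 %*% v
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  d1 <- colMeans(sweep(y1, 2, m1)^2)
  d2 <- colMeans(sweep(y2, 2, m2)^2)
  (m1 - m2)^2 / (d1 + d2)
}

# random composition M_Delta . M_R . M_D with bounded depolarization
random_composed <- function(delta_rng = c(0.1, pi - 0.1), depol_rng = c(0.25, 1)) {
  delta <- stats::runif(1, delta_rng[1], delta_rng[2])
  theta <- stats::runif(1, 0, 180)
  dd <- stats::runif(1, 0, 0.6)
  dep <- stats::runif(3, depol_rng[1], depol_rng[2])
  list(m = element_depolarizer(dep) %*% element_retarder(delta, theta) %*%
         element_diattenuator(dd, stats::runif(1, 0, 180)),
       delta = delta, theta = theta, D = dd, Delta = 1 - sum(dep) / 3)
}

# pack a list of 4x4 matrices into a 1 x n mueller_image
matrices_as_image <- function(mats, normalized = TRUE) {
  n <- length(mats)
  el <- array(0, c(1, n, 4, 4))
  for (k in seq_len(n)) el[1, k, , ] <- mats[[k]]
  mueller_image(el, normalized = normalized)
}

# minimal hand-built pfp_model for score arithmetic tests
make_model <- function(mu1 = 1, mu2 = -1, d1 = 0.5, d2 = 0.5) {
  structure(list(W = c(x = 1), feature_names = "x", standardization = NULL,
                 mu1 = c(x = mu1), mu2 = c(x = mu2),
                 mu1_tilde = mu1, mu2_tilde = mu2, D1 = d1, D2 = d2,
                 F = (mu1 - mu2)^2 / (d1 + d2), lambda = NA_real_,
                 scatter = "normalized", model_median = mu2,
                 normal_median = mu1),
            class = "pfp_model")
}

# sample with exact mean and exact population variance
rnorm_fixed <- function(mean, var, n = 100) {
  v <- stats::rnorm(n)
  v <- v - base::mean(v)
  v <- v / sqrt(base::mean(v^2))
  mean + sqrt(var) * v
}

axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# small measured stack: phantom -> measurement -> reconstruction -> stack
phantom_stack <- function(preset, h, w, seed, noise_sigma = preset$noise_sigma) {
  ph <- generate_phantom(preset, h, w, seed = seed)
  psg <- default_psg()
  meas <- simulate_measurement(ph$image, psg, noise_sigma = noise_sigma,
                               seed = seed + 1000L)
  norm <- normalize_mm(reconstruct_mm(psg, meas))
  list(stack = pbp_stack(norm, "all"), truth = ph$truth, image = norm)
}
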