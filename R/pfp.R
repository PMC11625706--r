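#' Extract a pixel-feature matrix from a PBP stack
#'
#' One row per foreground pixel, one column per selected rotation-invariant
#' parameter; the raw material of the PFP fit. Rotation-variant parameters
#' (`theta`, `alpha_r`) are refused: they depend on sample placement.
#'
#' @param stack a [pbp_stack].
#' @param features parameter names; default the 15 rotation-invariant PBPs.
#' @param rois optional list of `list(x, y, w, h)` regions restricting the
#'   pixels used.
#' @return numeric matrix `N x n` with feature names as column names.
#' @export
pbp_features <- function(stack, features = PBP_INVARIANT, rois = NULL) {
  stopifnot(inherits(stack, "pbp_stack"))
  missing_f <- setdiff(features, names(stack$maps))
  if (length(missing_f)) {
    stop("feature map(s) missing from stack: ", paste(missing_f, collapse = ", "))
  }
  variant <- features[stack$rotation_variant[features]]
  if (length(variant)) {
    stop("rotation-variant parameters not admitted as PFP features: ",
         paste(variant, collapse = ", "))
  }
  keep <- !stack$background & !stack$degenerate
  if (!is.null(rois)) {
    sel <- matrix(FALSE, nrow(keep), ncol(keep))
    for (r in rois) {
      sel[r$y:(r$y + r$h - 1L), r$x:(r$x + r$w - 1L)] <- TRUE
    }
    keep <- keep & sel
  }
  x <- vapply(features, function(p) stack$maps[[p]][keep], numeric(sum(keep)))
  x <- matrix(x, ncol = length(features), dimnames = list(NULL, features))
  x[stats::complete.cases(x), , drop = FALSE]
}

standardize_apply <- function(x, record) {
  if (is.null(record)) return(x)
  sweep(sweep(x, 2L, record$center, "-"), 2L, record$scale, "/")
}

pinv_sym <- function(s, tol = 1e-10) {
  sv <- svd(s)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) return(NULL)
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Fit the polarization feature parameter (PFP) weighting
#'
#' Learns the unit weight vector `W` whose pixel-wise linear combination of
#' rotation-invariant PBPs maximizes the distribution difference
#' `F(W) = (mu1~ - mu2~)^2 / (D1 + D2)` between the normal class and the
#' injured model class. `W` is the top eigenvector of `S_p^+ S_u` (computed
#' through singular-value machinery), where `S_u` is the rank-1
#' between-class scatter and `S_p` the within-class scatter; the sign is
#' fixed so the normal class projects higher than the model class.
#'
#' @param normal,model feature matrices (`N x n`, matching column names), as
#'   from [pbp_features]; rows are pixels, `normal` is class C1 and `model`
#'   class C2.
#' @param standardize z-standardize each feature using center/scale pooled
#'   over both classes (default: raw PBPs mix radians with unit-interval
#'   quantities, so coefficients are only comparable on a common scale). Set
#'   `FALSE` for raw-feature fitting.
#' @param scatter `"normalized"` (default): `S_p` is the sum of the
#'   class-covariances with 1/N_j weights, consistent with the definition of
#'   `D_j`; `"unnormalized"`: plain scatter sums.
#' @param pinv_tol relative singular-value cutoff of the pseudo-inverse.
#' @return object of class `pfp_model`: `W` (unit norm, named),
#'   `feature_names`, `standardization`, class means `mu1`, `mu2`, projected
#'   centers `mu1_tilde`, `mu2_tilde`, projected variances `D1`, `D2`,
#'   `F` (achieved F(W)), `lambda` (top eigenvalue), `model_median`
#'   (median projected model-class value, used by the default stain breaks).
#' @export
fit_pfp <- function(normal, model, standardize = TRUE,
                    scatter = c("normalized", "unnormalized"),
                    pinv_tol = 1e-10) {
  scatter <- match.arg(scatter)
  normal <- as.matrix(normal); model <- as.matrix(model)
  if (ncol(normal) != ncol(model)) stop("feature dimensions differ between classes")
  if (!is.null(colnames(normal)) && !is.null(colnames(model)) &&
      !identical(colnames(normal), colnames(model))) {
    stop("feature names differ between classes")
  }
  nfeat <- ncol(normal)
  if (nrow(normal) < nfeat || nrow(model) < nfeat) {
    stop("each class needs at least as many pixels as features")
  }
  record <- NULL
  if (standardize) {
    pooled <- rbind(normal, model)
    record <- list(center = colMeans(pooled),
                   scale = apply(pooled, 2L, stats::sd))
    record$scale[record$scale == 0] <- 1
  }
  x1 <- standardize_apply(normal, record)
  x2 <- standardize_apply(model, record)
  n1 <- nrow(x1); n2 <- nrow(x2)
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  d <- mu1 - mu2
  if (sqrt(sum(d^2)) < 1e-12) stop("no class separation: class means coincide (S_u = 0)")
  s_u <- d %o% d
  c1 <- crossprod(sweep(x1, 2L, mu1)) ; c2 <- crossprod(sweep(x2, 2L, mu2))
  s_p <- if (scatter == "normalized") c1 / n1 + c2 / n2 else c1 + c2
  if (max(abs(s_p)) < 1e-300) stop("within-class scatter S_p is numerically zero")
  sp_pinv <- pinv_sym(s_p, tol = pinv_tol)
  if (is.null(sp_pinv)) stop("within-class scatter S_p is numerically zero")
  eg <- eigen(sp_pinv %*% s_u)
  vals <- Re(eg$values)
  w <- Re(eg$vectors[, which.max(vals)])
  w <- w / sqrt(sum(w^2))
  if (sum(w * mu1) < sum(w * mu2)) w <- -w
  names(w) <- colnames(normal)
  mu1t <- sum(w * mu1); mu2t <- sum(w * mu2)
  y1 <- drop(x1 %*% w); y2 <- drop(x2 %*% w)
  d1 <- mean((y1 - mu1t)^2); d2 <- mean((y2 - mu2t)^2)
  structure(
    list(W = w, feature_names = colnames(normal), standardization = record,
         mu1 = mu1, mu2 = mu2, mu1_tilde = mu1t, mu2_tilde = mu2t,
         D1 = d1, D2 = d2, F = (mu1t - mu2t)^2 / (d1 + d2),
         lambda = max(vals), scatter = scatter,
         model_median = stats::median(y2), normal_median = stats::median(y1)),
    class = "pfp_model"
  )
}

#' @export
print.pfp_model <- function(x, ...) {
  cat(sprintf("<pfp_model> %d features, F(W) = %.4g, centers %.3g (normal) / %.3g (model)\n",
              length(x$W), x$F, x$mu1_tilde, x$mu2_tilde))
  ord <- order(abs(x$W), decreasing = TRUE)
  cat("  top weights:", paste(sprintf("%s=%.2f", names(x$W)[ord][1:min(5, length(ord))],
                                      x$W[ord][1:min(5, length(ord))]), collapse = ", "), "\n")
  invisible(x)
}

#' Distribution-difference score of a weighting vector
#'
#' `F(W) = (mu1~ - mu2~)^2 / (D1 + D2)` with the projected class variances
#' normalized by 1/N_j. Invariant to rescaling `W`; comparable across
#' parameters (a one-hot `W` gives the single-PBP score).
#'
#' @param w weight vector (any nonzero scale).
#' @param normal,model feature matrices as in [fit_pfp].
#' @param standardization optional center/scale record to apply first (use
#'   the fitted model's record when comparing against its F).
#' @return scalar F value.
#' @export
f_score <- function(w, normal, model, standardization = NULL) {
  x1 <- standardize_apply(as.matrix(normal), standardization)
  x2 <- standardize_apply(as.matrix(model), standardization)
  y1 <- drop(x1 %*% w); y2 <- drop(x2 %*% w)
  d1 <- mean((y1 - mean(y1))^2); d2 <- mean((y2 - mean(y2))^2)
  if (d1 + d2 == 0) stop("projected within-class variance is zero")
  (mean(y1) - mean(y2))^2 / (d1 + d2)
}

#' Apply a fitted PFP model pixel-wise
#'
#' Computes `y = W^T x` at every foreground pixel of a PBP stack (same grid,
#' no resolution loss), after applying the model's standardization record.
#'
#' @param model a [pfp_model].
#' @param stack a [pbp_stack] containing all model features, or a feature
#'   matrix with matching columns.
#' @return `height x width` PFP map with `NA` outside the foreground (or a
#'   vector when `stack` is a matrix).
#' @export
apply_pfp <- function(model, stack) {
  stopifnot(inherits(model, "pfp_model"))
  if (is.matrix(stack)) {
    x <- standardize_apply(stack[, model$feature_names, drop = FALSE],
                           model$standardization)
    return(drop(x %*% model$W))
  }
  stopifnot(inherits(stack, "pbp_stack"))
  missing_f <- setdiff(model$feature_names, names(stack$maps))
  if (length(missing_f)) {
    stop("feature map(s) missing from stack: ", paste(missing_f, collapse = ", "))
  }
  keep <- !stack$background & !stack$degenerate
  h <- nrow(keep); w <- ncol(keep)
  out <- matrix(NA_real_, h, w)
  if (!any(keep)) return(out)
  x <- vapply(model$feature_names, function(p) stack$maps[[p]][keep],
              numeric(sum(keep)))
  x <- matrix(x, ncol = length(model$feature_names),
              dimnames = list(NULL, model$feature_names))
  ok <- stats::complete.cases(x)
  y <- rep(NA_real_, nrow(x))
  y[ok] <- drop(standardize_apply(x[ok, , drop = FALSE], model$standardization) %*% model$W)
  out[keep] <- y
  out
}

#' Treatment-effect score of a group's PFP distribution
#'
#' `S = 50 * ((|u_r - mu2~| - |u_r - mu1~|) / (|u_r - mu2~| + |u_r - mu1~|)
#' + D1 / D_r)`: the first term rewards a group mean close to normal and far
#' from the injured model, the second rewards a distribution no wider than the
#' normal class (narrow = consistent recovery). Equals 100 when the group
#' matches the normal class statistics and 0 when it sits at the model center
#' with normal-class width.
#'
#' @param values PFP values of the treatment group (vector or map; `NA`s
#'   dropped).
#' @param model the fitted [pfp_model] supplying `mu1_tilde`, `mu2_tilde`,
#'   `D1`.
#' @return object of class `treatment_score`: `u_r`, `D_r`, `S`.
#' @export
treatment_score <- function(values, model) {
  stopifnot(inherits(model, "pfp_model"))
  v <- as.vector(values)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty treatment group")
  u_r <- mean(v)
  d_r <- mean((v - u_r)^2)
  if (d_r == 0) stop("treatment-group variance D_r is zero")
  a <- abs(u_r - model$mu2_tilde); b <- abs(u_r - model$mu1_tilde)
  if (a + b == 0) stop("degenerate position: group mean coincides with both class centers")
  s <- 50 * ((a - b) / (a + b) + model$D1 / d_r)
  structure(list(group = NULL, u_r = u_r, D_r = d_r, S = s),
            class = "treatment_score")
}

#' @export
print.treatment_score <- function(x, ...) {
  cat(sprintf("<treatment_score> u_r = %.4g, D_r = %.4g, S = %.2f\n",
              x$u_r, x$D_r, x$S))
  invisible(x)
}
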