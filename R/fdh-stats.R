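# natural display/binning ranges per parameter; NULL means data-driven
natural_range <- function(param) {
  switch(param,
         delta = c(0, pi),
         D = , Delta = , D_L = , P_L = , q_L = , r_L = , t1 = , A = c(0, 1),
         theta = , alpha_r = c(0, 180),
         m14 = , m41 = , m44 = , detB = c(-1, 1),
         CD = c(-2, 2),
         normB = c(0, 2),
         NULL)
}

#' Frequency distribution histogram
#'
#' Proportion-normalized histogram of a parameter map over its foreground
#' pixels: the group-comparison curve used throughout the evaluation system.
#' Values falling outside `range` are clamped into the end bins so that the
#' frequencies always sum to one.
#'
#' @param values numeric vector or matrix map; `NA`s are dropped.
#' @param n_bins number of equal-width bins (default 100 so curves from
#'   different groups overlay directly).
#' @param range length-2 numeric; defaults to the data range. Pass a
#'   parameter's natural range (e.g. `c(0, pi)` for retardance) to make
#'   histograms comparable across groups.
#' @param mask optional logical map; only `TRUE` pixels are used.
#' @return object of class `fdh`: `bin_edges`, `mids`, `frequencies`
#'   (summing to 1), `n_pixels`.
#' @export
compute_fdh <- function(values, n_bins = 100, range = NULL, mask = NULL) {
  v <- as.vector(values)
  if (!is.null(mask)) v <- v[as.vector(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no foreground values to histogram")
  if (is.null(range)) range <- base::range(v)
  if (range[2L] <= range[1L]) range <- range[1L] + c(-5e-10, 5e-10)
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  v <- clamp(v, range[1L], range[2L])
  idx <- clamp(findInterval(v, edges, rightmost.closed = TRUE), 1L, n_bins)
  freq <- tabulate(idx, nbins = n_bins) / length(v)
  structure(list(bin_edges = edges, mids = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 frequencies = freq, n_pixels = length(v)),
            class = "fdh")
}

#' @export
print.fdh <- function(x, ...) {
  cat(sprintf("<fdh> %d bins on [%.4g, %.4g], n = %d\n",
              length(x$frequencies), x$bin_edges[1L],
              x$bin_edges[length(x$bin_edges)], x$n_pixels))
  invisible(x)
}

#' Axial circular standard deviation
#'
#' Dispersion of axial (period-180) orientation data by angle doubling:
#' `R = |mean(exp(2 i theta))|`, `sd = sqrt(-2 log R) / 2`, reported in
#' degrees. Invariant to adding any constant angle and to relabeling
#' `theta -> theta + 180`; consistent for wrapped-normal draws.
#'
#' @param theta_deg angles in degrees (axial, period 180); `NA`s dropped.
#' @return standard deviation in degrees.
#' @export
axial_sd <- function(theta_deg) {
  th <- as.vector(theta_deg)
  th <- th[is.finite(th)]
  if (length(th) == 0L) stop("no foreground angles")
  z <- exp(2i * th * pi / 180)
  r <- Mod(mean(z))
  if (r <= 0) return(Inf)
  0.5 * sqrt(pmax(-2 * log(r), 0)) * 180 / pi
}

#' First-order statistic of a parameter map
#'
#' The evaluation system's summary rule: rotation-invariant parameters are
#' summarized by their arithmetic mean; rotation-variant axial angles by the
#' axial circular standard deviation (means of axial angles depend on sample
#' placement and are not meaningful). A plain linear SD is available for
#' comparison.
#'
#' @param map numeric map or vector.
#' @param mask optional logical foreground mask.
#' @param rotation_variant is this parameter an axial orientation angle?
#' @param method `"auto"` (the rule above), `"mean"`, `"axial_sd"`, or
#'   `"linear_sd"`.
#' @return scalar statistic (degrees for `axial_sd`).
#' @export
summary_stat <- function(map, mask = NULL, rotation_variant = FALSE,
                         method = c("auto", "mean", "axial_sd", "linear_sd")) {
  method <- match.arg(method)
  v <- as.vector(map)
  if (!is.null(mask)) v <- v[as.vector(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty foreground")
  if (method == "auto") method <- if (rotation_variant) "axial_sd" else "mean"
  switch(method,
         mean = mean(v),
         axial_sd = axial_sd(v),
         linear_sd = stats::sd(v))
}

#' Recovery indicator relative to the normal-group reference
#'
#' `S_parameter = p / p_n`: the statistic of the evaluated sample divided by
#' the same statistic of the normal group.
#'
#' @param p statistic of the sample under evaluation.
#' @param p_n normal-group reference statistic (nonzero).
#' @return the ratio.
#' @export
s_parameter <- function(p, p_n) {
  if (any(!is.finite(p_n)) || any(p_n == 0)) {
    stop("normal-group reference `p_n` is degenerate (zero or non-finite)")
  }
  p / p_n
}

#' Per-ROI group statistics for a PBP stack
#'
#' Computes [summary_stat] inside each region of interest and, by default,
#' averages the per-ROI values into the group statistic (matching per-ROI
#' sampling of tissue sections); a pooled-pixel mode is available.
#'
#' @param stack a [pbp_stack].
#' @param rois list of ROIs, each `list(x, y, w, h)` in 1-based pixel
#'   coordinates (x = column, y = row).
#' @param params parameter names to summarize (default: all in the stack).
#' @param pooled if `TRUE`, pool all ROI pixels instead of averaging per-ROI
#'   statistics.
#' @return data.frame with columns `parameter`, `roi`, `statistic`, `value`;
#'   ROI 0 rows hold the group-level statistic.
#' @export
roi_stats <- function(stack, rois, params = names(stack$maps), pooled = FALSE) {
  stopifnot(inherits(stack, "pbp_stack"))
  params <- match.arg(params, names(stack$maps), several.ok = TRUE)
  fg <- !stack$background & !stack$degenerate
  out <- list()
  for (p in params) {
    rv <- stack$rotation_variant[[p]]
    map <- stack$maps[[p]]
    per_roi <- vapply(seq_along(rois), function(k) {
      r <- rois[[k]]
      rows <- r$y:(r$y + r$h - 1L); cols <- r$x:(r$x + r$w - 1L)
      summary_stat(map[rows, cols], mask = fg[rows, cols], rotation_variant = rv)
    }, numeric(1L))
    group <- if (pooled) {
      pix <- unlist(lapply(rois, function(r) {
        rows <- r$y:(r$y + r$h - 1L); cols <- r$x:(r$x + r$w - 1L)
        map[rows, cols][fg[rows, cols]]
      }))
      summary_stat(pix, rotation_variant = rv)
    } else {
      mean(per_roi)
    }
    out[[p]] <- data.frame(
      parameter = p,
      roi = c(seq_along(rois), 0L),
      statistic = if (rv) "axial_sd" else "mean",
      value = c(per_roi, group),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
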