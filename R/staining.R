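#' Three-band virtual staining scheme
#'
#' Defines how a PFP map is rendered: background and the lowest band are blue
#' (air), the mid band green (injured-like tissue), the high band orange-red
#' (healthy-like tissue), with continuous shading inside each band. Breaks
#' may be absolute PFP values or percentiles of the image foreground; when a
#' fitted model is attached at stain time the default green/orange boundary is
#' the median projected model-class value.
#'
#' @param low,high band boundaries (`low < high`). Interpreted in PFP units
#'   when `space = "absolute"`, as foreground percentiles in `[0, 1]` when
#'   `space = "percentile"`.
#' @param space `"percentile"` or `"absolute"`.
#' @param blue,green,orange length-2 character vectors of color anchors
#'   (shade ramp within each band, low to high).
#' @return object of class `stain_scheme`.
#' @export
stain_scheme <- function(low = 0.02, high = 0.5,
                         space = c("percentile", "absolute"),
                         blue = c("#08306B", "#6BAED6"),
                         green = c("#74C476", "#00441B"),
                         orange = c("#FD8D3C", "#7F2704")) {
  space <- match.arg(space)
  if (!(low < high)) stop("`low` break must be smaller than `high` break")
  structure(list(low = low, high = high, space = space,
                 blue = blue, green = green, orange = orange),
            class = "stain_scheme")
}

resolve_breaks <- function(values, scheme, model = NULL) {
  if (scheme$space == "absolute") return(c(scheme$low, scheme$high))
  v <- values[is.finite(values)]
  lo <- stats::quantile(v, scheme$low, names = FALSE)
  hi <- if (!is.null(model)) model$model_median else stats::quantile(v, scheme$high, names = FALSE)
  if (hi <= lo) hi <- lo + .Machine$double.eps * max(1, abs(lo))
  c(lo, hi)
}

ramp_band <- function(values, anchors) {
  rng <- range(values)
  pos <- if (rng[2L] > rng[1L]) (values - rng[1L]) / (rng[2L] - rng[1L]) else rep(0.5, length(values))
  grDevices::colorRamp(anchors)(pos) / 255
}

#' Virtual polarization staining of a PFP image
#'
#' Deterministic false-color rendering: background pixels and the lowest PFP
#' band map to blue, the mid band to green, the high band to orange-red, each
#' with continuous within-band shading. A constant (degenerate) foreground
#' produces a single-band image and a recorded warning.
#'
#' @param pfp `height x width` PFP map (`NA` = background), as from
#'   [apply_pfp].
#' @param scheme a [stain_scheme].
#' @param model optional [pfp_model]; with the default percentile scheme its
#'   median model-class projection becomes the green/orange boundary.
#' @return `height x width x 3` RGB array in `[0, 1]`, class `stain_image`,
#'   with attributes `bands` (integer map: 0 background, 1 blue, 2 green,
#'   3 orange) and `breaks`.
#' @export
stain <- function(pfp, scheme = stain_scheme(), model = NULL) {
  stopifnot(is.matrix(pfp), inherits(scheme, "stain_scheme"))
  fg <- is.finite(pfp)
  if (!any(fg)) {
    rgb <- array(0, c(nrow(pfp), ncol(pfp), 3L))
    col <- grDevices::col2rgb(scheme$blue[1L]) / 255
    for (k in 1:3) rgb[, , k] <- col[k]
    attr(rgb, "bands") <- matrix(0L, nrow(pfp), ncol(pfp))
    attr(rgb, "breaks") <- c(NA_real_, NA_real_)
    class(rgb) <- "stain_image"
    return(rgb)
  }
  vals <- pfp[fg]
  warn <- NULL
  if (max(vals) - min(vals) < .Machine$double.eps * max(1, abs(max(vals)))) {
    warn <- "constant PFP image: single-band staining"
    warning(warn)
  }
  brk <- resolve_breaks(vals, scheme, model)
  bands <- matrix(0L, nrow(pfp), ncol(pfp))
  bands[fg & pfp <= brk[1L]] <- 1L
  bands[fg & pfp > brk[1L] & pfp <= brk[2L]] <- 2L
  bands[fg & pfp > brk[2L]] <- 3L

  rgb <- array(0, c(nrow(pfp), ncol(pfp), 3L))
  bgcol <- grDevices::col2rgb(scheme$blue[1L]) / 255
  for (k in 1:3) {
    plane <- rgb[, , k]
    plane[!fg] <- bgcol[k]
    rgb[, , k] <- plane
  }
  anchors <- list(scheme$blue, scheme$green, scheme$orange)
  for (band in 1:3) {
    sel <- bands == band
    if (!any(sel)) next
    cols <- ramp_band(pfp[sel], anchors[[band]])
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[sel] <- cols[, k]
      rgb[, , k] <- plane
    }
  }
  attr(rgb, "bands") <- bands
  attr(rgb, "breaks") <- brk
  if (!is.null(warn)) attr(rgb, "warning") <- warn
  class(rgb) <- "stain_image"
  rgb
}

#' Fraction of foreground pixels per stain band
#'
#' @param x a `stain_image` from [stain].
#' @return named numeric vector `c(blue, green, orange)` over foreground
#'   pixels.
#' @export
band_fractions <- function(x) {
  bands <- attr(x, "bands")
  fgn <- sum(bands > 0L)
  if (fgn == 0L) return(c(blue = 0, green = 0, orange = 0))
  c(blue = sum(bands == 1L), green = sum(bands == 2L), orange = sum(bands == 3L)) / fgn
}

#' Group comparison report in PFP space
#'
#' Overlaid frequency-distribution histograms of every group on a common
#' range, treatment scores against the fitted model, and the resulting
#' ranking of treatment groups.
#'
#' @param groups named list of PFP value vectors or maps; must include
#'   `"normal"` and `"model"` entries for the reference curves.
#' @param model the fitted [pfp_model].
#' @param n_bins histogram bins (common edges across groups).
#' @return object of class `pfp_report`: `fdh` (named list of [compute_fdh]
#'   results), `scores` (data.frame `group`, `u_r`, `D_r`, `S`), `ranking`
#'   (treatment groups by decreasing S).
#' @export
group_report <- function(groups, model, n_bins = 100) {
  stopifnot(inherits(model, "pfp_model"), length(groups) >= 1L)
  if (!all(c("normal", "model") %in% names(groups))) {
    stop("`groups` must include 'normal' and 'model' reference entries")
  }
  vals <- lapply(groups, function(v) { v <- as.vector(v); v[is.finite(v)] })
  rng <- range(unlist(vals))
  fdhs <- lapply(vals, compute_fdh, n_bins = n_bins, range = rng)
  scores <- do.call(rbind, lapply(names(vals), function(g) {
    ts <- treatment_score(vals[[g]], model)
    data.frame(group = g, u_r = ts$u_r, D_r = ts$D_r, S = ts$S,
               stringsAsFactors = FALSE)
  }))
  treat <- setdiff(names(vals), c("normal", "model"))
  ranking <- treat[order(-scores$S[match(treat, scores$group)])]
  structure(list(fdh = fdhs, scores = scores, ranking = ranking),
            class = "pfp_report")
}

#' @export
print.pfp_report <- function(x, ...) {
  cat("<pfp_report>\n")
  print(x$scores, row.names = FALSE)
  cat("  ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
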