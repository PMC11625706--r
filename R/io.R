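# File containers. The Mueller image is stored as a TSV of 16 columns
# (m11..m44, row-major element order) with pixels in row-major order, plus a
# JSON sidecar header; a deliberately portable plain-text stand-in for a
# multi-page float TIFF.

element_order <- function() {
  as.vector(t(outer(1:4, 1:4, function(i, j) sprintf("m%d%d", i, j))))
}

#' Write / read a Mueller image container
#'
#' `write_mueller` produces `<stem>.mm.tsv` (16 element columns, pixels in
#' row-major order) and `<stem>.json` (height, width, normalized flag,
#' wavelength, element order, background mask as row-major 0/1). The pair
#' round-trips through `read_mueller`.
#'
#' @param image a [mueller_image].
#' @param stem path prefix without extension.
#' @return `write_mueller`: the stem, invisibly. `read_mueller`: a
#'   [mueller_image].
#' @export
write_mueller <- function(image, stem) {
  stopifnot(inherits(image, "mueller_image"))
  h <- image$height; w <- image$width
  fld <- matrix(aperm(image$elements, c(2L, 1L, 4L, 3L)), nrow = h * w)
  # aperm above gives row-major pixel order and row-major element order
  colnames(fld) <- element_order()
  utils::write.table(format(fld, digits = 9, trim = TRUE, scientific = TRUE),
                     paste0(stem, ".mm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  header <- list(height = h, width = w, normalized = image$normalized,
                 wavelength_nm = image$wavelength_nm,
                 element_order = paste(element_order(), collapse = ","),
                 pixel_order = "row-major",
                 background = if (is.null(image$background)) NULL else
                   as.integer(t(image$background)))
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_mueller
#' @export
read_mueller <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(stem, ".mm.tsv"), header = TRUE, sep = "\t")
  h <- header$height; w <- header$width
  stopifnot(nrow(tab) == h * w, ncol(tab) == 16L)
  el <- aperm(array(as.matrix(tab), c(w, h, 4L, 4L)), c(2L, 1L, 4L, 3L))
  bg <- NULL
  if (!is.null(header$background) && length(header$background)) {
    bg <- matrix(as.logical(header$background), h, w, byrow = TRUE)
  }
  mueller_image(el, normalized = isTRUE(header$normalized),
                wavelength_nm = header$wavelength_nm, background = bg)
}

#' Write / read ROI rectangles as JSON
#'
#' Rectangles are `{x, y, w, h}` in 1-based pixel coordinates (x = column).
#'
#' @param rois list of `list(x, y, w, h)`.
#' @param path JSON file path.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) list(x = as.integer(r$x), y = as.integer(r$y),
                               w = as.integer(r$w), h = as.integer(r$h)))
}

#' Serialize / restore a fitted PFP model as JSON
#'
#' @param model a [pfp_model].
#' @param path JSON file path.
#' @export
write_pfp_model <- function(model, path) {
  stopifnot(inherits(model, "pfp_model"))
  payload <- unclass(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pfp_model
#' @export
read_pfp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- p$feature_names
  model <- list(
    W = stats::setNames(as.numeric(p$W), nm), feature_names = nm,
    standardization = if (is.null(p$standardization)) NULL else
      list(center = stats::setNames(as.numeric(p$standardization$center), nm),
           scale = stats::setNames(as.numeric(p$standardization$scale), nm)),
    mu1 = stats::setNames(as.numeric(p$mu1), nm),
    mu2 = stats::setNames(as.numeric(p$mu2), nm),
    mu1_tilde = p$mu1_tilde, mu2_tilde = p$mu2_tilde,
    D1 = p$D1, D2 = p$D2, F = p$F, lambda = p$lambda, scatter = p$scatter,
    model_median = p$model_median, normal_median = p$normal_median
  )
  class(model) <- "pfp_model"
  model
}

#' Write a stained image
#'
#' PNG when the `png` package is available and the path ends in `.png`,
#' otherwise a plain-text PPM (P3).
#'
#' @param x a `stain_image` from [stain].
#' @param path output path (`.png` or `.ppm`).
#' @export
write_stain <- function(x, path) {
  rgb <- unclass(x)[, , , drop = FALSE]
  if (grepl("\\.png$", path) && requireNamespace("png", quietly = TRUE)) {
    png::writePNG(rgb, path)
    return(invisible(path))
  }
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  vals <- round(255 * aperm(rgb, c(3L, 2L, 1L)))  # per pixel RGB, row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(as.integer(vals), collapse = " "), con)
  invisible(path)
}

#' Write frequency histograms as JSON
#'
#' @param fdhs named list of [compute_fdh] results.
#' @param path JSON file path.
#' @export
write_fdh <- function(fdhs, path) {
  payload <- lapply(fdhs, function(f) list(bin_edges = f$bin_edges,
                                           frequencies = f$frequencies,
                                           n_pixels = f$n_pixels))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}
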