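#' Write a binary layer image as PNG
#'
#' @param x a `layer_image` or logical matrix.
#' @param file output PNG path.
#' @return the file path, invisibly.
#' @export
write_layer_png <- function(x, file) {
  m <- if (inherits(x, "layer_image")) x$mask else x
  png::writePNG(m * 1, file)
  invisible(file)
}

#' Write a color scene as PNG
#'
#' @param scene a `sim_photo` or rows x cols x 3 array in `[0, 1]`.
#' @param file output PNG path.
#' @return the file path, invisibly.
#' @export
write_scene_png <- function(scene, file) {
  if (inherits(scene, "sim_photo")) scene <- scene$scene
  png::writePNG(scene, file)
  invisible(file)
}

#' Write the localization heatmap overlay as PNG
#'
#' Renders the smoothed normalized grid-index field over the design layer
#' image, with start/stop points marked, in the style used to communicate
#' localized printing inaccuracies.
#'
#' @param report an `accuracy_report` from [assess()].
#' @param file output PNG path.
#' @return the file path, invisibly.
#' @export
write_heatmap_png <- function(report, file) {
  stopifnot(inherits(report, "accuracy_report"))
  fr <- report$frame
  g <- report$field$g
  # upsample the grid field to the pixel raster
  hm <- report$heatmap[rep(seq_len(nrow(report$heatmap)), each = g)[seq_len(fr$ny)],
                       rep(seq_len(ncol(report$heatmap)), each = g)[seq_len(fr$nx)]]
  hm <- hm / max(hm, 1e-9)
  base <- report$G$mask * 0.35
  img <- array(0, c(fr$ny, fr$nx, 3))
  img[, , 1] <- pmin(1, base + hm)           # heat in red
  img[, , 2] <- pmin(1, base + 0.6 * hm^2)
  img[, , 3] <- base
  if (!is.null(report$start_stop) && nrow(report$start_stop)) {
    s <- fr$scale
    rr <- round((fr$height_mm - report$start_stop$y) * s + 0.5) + report$shift$dy
    cc <- round(report$start_stop$x * s + 0.5) + report$shift$dx
    for (k in seq_along(rr)) {
      rows <- max(1, rr[k] - 2):min(fr$ny, rr[k] + 2)
      cols <- max(1, cc[k] - 2):min(fr$nx, cc[k] + 2)
      img[rows, cols, 1] <- 1; img[rows, cols, 2] <- 0; img[rows, cols, 3] <- 0.2
    }
  }
  png::writePNG(img, file)
  invisible(file)
}
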