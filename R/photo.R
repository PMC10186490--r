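#' Locate the four green fiducial markers
#'
#' Detects the green corner markers that delimit the metric reference frame in
#' a raw top-view photograph. Pixels are screened in HSV space (green hue
#' window with saturation/value floors), connected components below a minimum
#' area are dropped, and the centroids of the four largest remaining blobs are
#' ordered by quadrant.
#'
#' @param photo color raster: array `[rows, cols, 3]` with values in `[0, 1]`,
#'   or a PNG/JPEG file path readable by [png::readPNG()].
#' @param hue_window green hue limits as fractions of the hue circle.
#' @param min_sat,min_val saturation and value floors.
#' @param min_area minimum blob area in px.
#' @return an object of class `marker_set`: 4 x 2 matrix of centroid (x, y)
#'   pixel coordinates (x = column, y = row), rows ordered TL, TR, BR, BL.
#' @export
find_markers <- function(photo, hue_window = c(0.20, 0.45),
                         min_sat = 0.3, min_val = 0.2, min_area = 20) {
  photo <- load_scene(photo)
  r <- photo[, , 1]; g <- photo[, , 2]; b <- photo[, , 3]
  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                            maxColorValue = 1)
  green <- matrix(hsv[1, ] >= hue_window[1] & hsv[1, ] <= hue_window[2] &
                  hsv[2, ] >= min_sat & hsv[3, ] >= min_val,
                  nrow(r), ncol(r))
  lab <- EBImage::bwlabel(EBImage::Image(t(green)))  # EBImage is x-major
  lab <- t(EBImage::imageData(lab))
  if (max(lab) == 0)
    pf_stop("marker_detection", "marker detection failed: found 0 candidate blobs")
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) < 4L)
    pf_stop("marker_detection", "marker detection failed: found %d candidate blob(s)",
            length(keep))
  keep <- keep[order(areas[keep], decreasing = TRUE)][1:4]
  cent <- t(vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]))  # (x = col, y = row)
  }, numeric(2)))
  order_markers(cent)
}

# Order 4 centroids TL, TR, BR, BL by quadrant around their mean.
order_markers <- function(cent) {
  cx <- mean(cent[, 1]); cy <- mean(cent[, 2])
  quad <- function(p) {
    if (p[1] < cx && p[2] < cy) 1L else if (p[1] >= cx && p[2] < cy) 2L
    else if (p[1] >= cx && p[2] >= cy) 3L else 4L
  }
  q <- apply(cent, 1, quad)
  if (!setequal(q, 1:4))
    pf_stop("marker_detection", "markers do not occupy four distinct quadrants")
  out <- cent[order(q), , drop = FALSE]
  d <- stats::dist(out)
  diag_len <- sqrt(sum((out[1, ] - out[3, ])^2))
  if (min(d) < 0.05 * diag_len)
    pf_stop("marker_detection", "two markers nearly coincide")
  structure(out, dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")),
            class = "marker_set")
}

load_scene <- function(photo) {
  if (is.character(photo)) photo <- png::readPNG(photo)
  if (length(dim(photo)) == 2L)
    photo <- array(rep(photo, 3), c(dim(photo), 3L))
  if (dim(photo)[3] > 3L) photo <- photo[, , 1:3, drop = FALSE]
  photo
}

# 4-point homography by direct linear solve: maps src (x, y) -> dst (x, y).
homography_from_points <- function(src, dst) {
  A <- matrix(0, 8, 8); bvec <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    bvec[2 * i - 1] <- u; bvec[2 * i] <- v
  }
  h <- tryCatch(solve(A, bvec), error = function(e)
    pf_stop("homography", "degenerate marker quadrilateral: %s", conditionMessage(e)))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, xy) {
  p <- H %*% rbind(t(xy), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

# Inverse-map warp with bilinear interpolation. H maps source px -> dest px;
# the dest raster is filled by pulling through H^-1.
warp_image <- function(img, H, out_nrow, out_ncol, fill = 0) {
  Hi <- solve(H)
  grid <- cbind(rep(seq_len(out_ncol), each = out_nrow),
                rep(seq_len(out_nrow), out_ncol))
  src <- apply_homography(Hi, grid)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  nr <- nrow(img); nc <- ncol(img)
  get <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- rep(fill, length(rr))
    v[ok] <- img[cbind(rr[ok], cc[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * get(y0, x0) +
       fx * (1 - fy) * get(y0, x0 + 1) +
       (1 - fx) * fy * get(y0 + 1, x0) +
       fx * fy * get(y0 + 1, x0 + 1)
  matrix(v, out_nrow, out_ncol)
}

#' Rectify a photograph onto the metric frame
#'
#' Computes the projective transform taking the marker quadrilateral to the
#' frame rectangle and resamples the photo onto the frame raster
#' (2400 x 1500 px for the default frame), so that pixel scale is known from
#' the marker spacing.
#'
#' @param photo color raster or file path (see [find_markers()]).
#' @param markers a `marker_set`; detected automatically when `NULL`.
#' @param frame a [frame_spec()].
#' @return an object of class `rectified_photo`: list with `gray` (matrix,
#'   frame raster), `frame`, `homography` (source px -> frame px), and
#'   `markers_px` (marker positions mapped onto the frame raster).
#' @export
rectify <- function(photo, markers = NULL, frame = frame_spec()) {
  photo <- load_scene(photo)
  if (is.null(markers)) markers <- find_markers(photo)
  stopifnot(inherits(markers, "marker_set"))
  dst <- rbind(c(0.5, 0.5), c(frame$nx - 0.5, 0.5),
               c(frame$nx - 0.5, frame$ny - 0.5), c(0.5, frame$ny - 0.5))
  H <- homography_from_points(unclass(markers), dst)
  gray <- 0.2989 * photo[, , 1] + 0.587 * photo[, , 2] + 0.114 * photo[, , 3]
  out <- warp_image(gray, H, frame$ny, frame$nx)
  structure(list(gray = out, frame = frame, homography = H,
                 markers_px = apply_homography(H, unclass(markers))),
            class = "rectified_photo")
}

#' @export
print.rectified_photo <- function(x, ...) {
  cat(sprintf("Rectified photo: %d x %d px (%g x %g mm frame)\n",
              x$frame$nx, x$frame$ny, x$frame$width_mm, x$frame$height_mm))
  invisible(x)
}

#' Segment the printed object from a rectified photo
#'
#' Otsu automatic thresholding on the rectified grayscale image. Marker
#' regions are excluded before the threshold is computed; foreground/
#' background polarity is resolved by taking as object the side with less
#' contact with the image border; components smaller than `min_area` are
#' dropped (oozed satellites above that size are kept, as they are genuine
#' print material), and internal holes are preserved since pores carry the
#' infill signal.
#'
#' @param photo a `rectified_photo`.
#' @param exclude_radius_mm radius around each marker position to exclude.
#' @param min_area minimum component area in px.
#' @param polarity "auto", "light" (object brighter) or "dark".
#' @return a `layer_image` with role "print".
#' @export
segment <- function(photo, exclude_radius_mm = 5, min_area = 25,
                    polarity = c("auto", "light", "dark")) {
  stopifnot(inherits(photo, "rectified_photo"))
  polarity <- match.arg(polarity)
  g <- photo$gray
  fr <- photo$frame
  excl <- matrix(FALSE, nrow(g), ncol(g))
  if (!is.null(photo$markers_px) && exclude_radius_mm > 0) {
    r <- exclude_radius_mm * fr$scale
    for (i in seq_len(nrow(photo$markers_px))) {
      m <- photo$markers_px[i, ]
      rows <- pmax(1, floor(m[2] - r)):pmin(nrow(g), ceiling(m[2] + r))
      cols <- pmax(1, floor(m[1] - r)):pmin(ncol(g), ceiling(m[1] + r))
      excl[rows, cols] <- TRUE
    }
  }
  vals <- g[!excl]
  if (max(vals) - min(vals) < 1e-3)
    pf_stop("segmentation", "uniform image: no foreground/background separation")
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)),
                       range = range(vals))
  light <- g > thr & !excl
  obj <- switch(polarity,
    light = light,
    dark = !light & !excl,
    auto = {
      border <- function(m) sum(m[1, ]) + sum(m[nrow(m), ]) +
        sum(m[, 1]) + sum(m[, ncol(m)])
      dark <- !light & !excl
      if (border(light) <= border(dark)) light else dark
    })
  if (!any(obj))
    pf_stop("segmentation", "empty foreground after thresholding")
  if (min_area > 0) {
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(obj)))))
    areas <- tabulate(lab[lab > 0])
    small <- which(areas < min_area)
    if (length(small)) obj[lab %in% small] <- FALSE
    if (!any(obj))
      pf_stop("segmentation", "no component reaches the minimum area")
  }
  layer_image(obj, fr, "print")
}
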