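# Internal helpers shared across modules.

# Classed condition so callers/tests can catch specific failure modes.
pf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("printfid_", class), "printfid_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pf_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("printfid_", class), "printfid_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Fill a polygon on a raster frame
#'
#' Scan-line even-odd fill of a closed polygon given in frame millimetre
#' coordinates (y up). Used for design footprints when measuring infill.
#'
#' @param xy two-column matrix of vertices (mm); the polygon is closed
#'   implicitly.
#' @param frame a [frame_spec()].
#' @return logical matrix (rows = y down, cols = x) matching the frame raster.
#' @keywords internal
#' @noRd
polygon_mask <- function(xy, frame) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) pf_stop("degenerate_polygon", "polygon needs >= 3 vertices")
  nr <- frame$ny; nc <- frame$nx; s <- frame$scale
  px <- xy[, 1]; py <- xy[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  mask <- matrix(FALSE, nr, nc)
  xc <- (seq_len(nc) - 0.5) / s
  yc <- (nr - seq_len(nr) + 0.5) / s  # pixel-centre y (mm), rows top-down
  for (r in seq_len(nr)) {
    y <- yc[r]
    # edges crossing the scan line (half-open to handle vertices robustly)
    cross <- (py <= y & qy > y) | (qy <= y & py > y)
    if (!any(cross)) next
    xint <- px[cross] + (y - py[cross]) / (qy[cross] - py[cross]) *
      (qx[cross] - px[cross])
    xint <- sort(xint)
    for (k in seq(1L, length(xint) - 1L, by = 2L)) {
      c0 <- ceiling(xint[k] * s + 0.5)
      c1 <- floor(xint[k + 1] * s + 0.5)
      if (c1 >= c0) mask[r, max(1L, c0):min(nc, c1)] <- TRUE
    }
  }
  mask
}

# Separable Gaussian smoothing with zero padding; kernel radius 3*sigma.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(0, r), v, rep(0, r))
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(vp[i:(i + 2 * r)] * k)
    out
  }
  m1 <- apply(m, 2, pad_conv)
  t(apply(m1, 1, pad_conv))
}

# Integer translation of a logical matrix with FALSE fill.
# Raster convention throughout registration: dx = +columns (right),
# dy = +rows (down).
shift_mask <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  dr <- as.integer(dy); dc <- as.integer(dx)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
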