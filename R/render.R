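#' Binary layer image
#'
#' Container for a binary raster on the metric frame: either a digital design
#' layer `G` rendered from a toolpath, or a segmented print `P` from a
#' photograph.
#'
#' @param mask logical matrix, rows = y top-down, columns = x.
#' @param frame a [frame_spec()].
#' @param role "design" (G) or "print" (P).
#' @return an object of class `layer_image`.
#' @export
layer_image <- function(mask, frame, role = c("design", "print")) {
  role <- match.arg(role)
  stopifnot(inherits(frame, "frame_spec"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), as.integer(c(frame$ny, frame$nx))))
    pf_stop("bad_mask", "mask dimensions %dx%d do not match frame %dx%d",
            nrow(mask), ncol(mask), frame$ny, frame$nx)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, frame = frame, role = role),
            class = "layer_image")
}

#' @export
print.layer_image <- function(x, ...) {
  cat(sprintf("Layer image (%s): %d x %d px, %.1f mm2 foreground (%.1f%%)\n",
              x$role, x$frame$nx, x$frame$ny,
              sum(x$mask) / x$frame$scale^2,
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
plot.layer_image <- function(x, ...) {
  graphics::image(t(x$mask[nrow(x$mask):1, , drop = FALSE]),
                  col = c("grey15", "wheat"), axes = FALSE, asp = x$frame$ny / x$frame$nx,
                  main = sprintf("layer image (%s)", x$role), ...)
  invisible(x)
}

# Draw thick segments (round caps) onto a logical matrix. Segments is a data
# frame with x1,y1,x2,y2 (mm) and a width column w (mm). Pure raster test:
# pixel centre within w/2 of the segment.
draw_segments <- function(mask, segments, frame) {
  if (!nrow(segments)) return(mask)
  s <- frame$scale; ny <- frame$ny; nx <- frame$nx
  for (i in seq_len(nrow(segments))) {
    x1 <- segments$x1[i]; y1 <- segments$y1[i]
    x2 <- segments$x2[i]; y2 <- segments$y2[i]
    r <- segments$w[i] / 2
    c0 <- max(1L, floor((min(x1, x2) - r) * s + 0.5))
    c1 <- min(nx, ceiling((max(x1, x2) + r) * s + 0.5))
    rw0 <- max(1L, floor((frame$height_mm - max(y1, y2) - r) * s + 0.5))
    rw1 <- min(ny, ceiling((frame$height_mm - min(y1, y2) + r) * s + 0.5))
    if (c1 < c0 || rw1 < rw0) next
    cols <- c0:c1; rows <- rw0:rw1
    px <- (cols - 0.5) / s
    py <- (ny - rows + 0.5) / s
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    PX <- matrix(px, length(rows), length(cols), byrow = TRUE)
    PY <- matrix(py, length(rows), length(cols))
    if (len2 == 0) {
      d2 <- (PX - x1)^2 + (PY - y1)^2
    } else {
      t <- ((PX - x1) * dx + (PY - y1) * dy) / len2
      t[t < 0] <- 0; t[t > 1] <- 1
      d2 <- (PX - (x1 + t * dx))^2 + (PY - (y1 + t * dy))^2
    }
    blk <- mask[rows, cols, drop = FALSE]
    blk[d2 <= r * r] <- TRUE
    mask[rows, cols] <- blk
  }
  mask
}

#' Rasterize a toolpath into a digital layer image
#'
#' Every extruding segment is drawn as a thick line with round caps and joins
#' on the metric frame raster; travel moves are not drawn. Line width is
#' either fixed (the survey-image convention, 1.5 mm by default) or evaluated
#' per segment from the flattened-filament width model ([filament_width()]).
#'
#' @param path a `toolpath` or `design_path`.
#' @param frame a [frame_spec()].
#' @param width_mode "fixed" or "model".
#' @param line_width line width in mm for `width_mode = "fixed"`.
#' @param place "none" draws at the toolpath's own coordinates (an error if it
#'   leaves the frame), "center" translates the extrusion bounding box to the
#'   frame centre.
#' @return a `layer_image` with role "design".
#' @examples
#' fr <- frame_spec(40, 20, 10)
#' tp <- parse_gcode(c("G1 X5 Y10", "G1 X35 Y10 E1"), printer_params())
#' G <- render_layer(tp, fr)
#' sum(G$mask) / fr$scale^2   # close to 30*1.5 + pi*0.75^2 mm2
#' @export
render_layer <- function(path, frame = frame_spec(),
                         width_mode = c("fixed", "model"), line_width = 1.5,
                         place = c("none", "center")) {
  if (inherits(path, "design_path")) path <- path$path
  stopifnot(inherits(path, "toolpath"), inherits(frame, "frame_spec"))
  width_mode <- match.arg(width_mode)
  place <- match.arg(place)
  if (width_mode == "fixed" && (!is_scalar_num(line_width) || line_width <= 0))
    pf_stop("bad_width", "fixed width mode requires a positive line width")
  seg <- path$segments[path$segments$extruding, , drop = FALSE]
  mask <- matrix(FALSE, frame$ny, frame$nx)
  if (!nrow(seg)) return(layer_image(mask, frame, "design"))

  if (place == "center") {
    ox <- frame$width_mm / 2 - mean(path$bbox[c("xmin", "xmax")])
    oy <- frame$height_mm / 2 - mean(path$bbox[c("ymin", "ymax")])
    seg$x1 <- seg$x1 + ox; seg$x2 <- seg$x2 + ox
    seg$y1 <- seg$y1 + oy; seg$y2 <- seg$y2 + oy
  }

  X <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  seg$w <- if (width_mode == "fixed") line_width
           else filament_width(seg$de, X, path$params)
  seg <- seg[!is.na(seg$w), , drop = FALSE]

  out <- which(seg$x1 - seg$w / 2 < 0 | seg$x2 + seg$w / 2 > frame$width_mm |
               seg$x2 - seg$w / 2 < 0 | seg$x1 + seg$w / 2 > frame$width_mm |
               seg$y1 - seg$w / 2 < 0 | seg$y2 + seg$w / 2 > frame$height_mm |
               seg$y2 - seg$w / 2 < 0 | seg$y1 + seg$w / 2 > frame$height_mm)
  if (length(out))
    pf_stop("placement", "segment %d [(%.1f,%.1f)-(%.1f,%.1f), w=%.2f] exceeds the %g x %g mm frame",
            out[1], seg$x1[out[1]], seg$y1[out[1]], seg$x2[out[1]], seg$y2[out[1]],
            seg$w[out[1]], frame$width_mm, frame$height_mm)

  layer_image(draw_segments(mask, seg, frame), frame, "design")
}

#' Design infill percentage
#'
#' Share of the design footprint occupied by rendered material:
#' 100 x (foreground pixels of G inside the footprint) / (footprint pixels).
#' The slicing software's nominal infill setting understates this because the
#' perimeter shell and the finite line width are not accounted for, which is
#' why the rendered layer image is the reference for porosity.
#'
#' @param G a `layer_image` (design).
#' @param region the design footprint: a logical mask matching the frame, or a
#'   polygon (two-column matrix, mm) which is filled on the frame raster.
#' @return infill percent.
#' @export
design_infill <- function(G, region) {
  stopifnot(inherits(G, "layer_image"))
  if (!is.logical(region) || is.null(dim(region)))
    region <- polygon_mask(region, G$frame)
  if (!identical(dim(region), dim(G$mask)))
    pf_stop("bad_mask", "region dimensions do not match the layer image")
  n <- sum(region)
  if (n == 0) pf_stop("empty_region", "design footprint region is empty")
  100 * sum(G$mask & region) / n
}

#' Design specification for the slicer emulation
#'
#' @param shape "block" (rectangular slab with shell + infill) or "outline"
#'   (closed outline path only, e.g. the deer-like silhouette).
#' @param dims block dimensions c(width, height) in mm.
#' @param pattern infill pattern, "rectilinear" or "honeycomb".
#' @param density infill density fraction in (0, 1]; 0 renders the shell only.
#' @param shells number of perimeter loops.
#' @param line_width rendered line width (mm).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(shape = c("block", "outline"), dims = c(50, 25),
                        pattern = c("rectilinear", "honeycomb"),
                        density = 0.2, shells = 1, line_width = 1.5) {
  shape <- match.arg(shape)
  pattern <- match.arg(pattern)
  if (!is.numeric(density) || length(density) != 1L || density < 0 || density > 1)
    pf_stop("bad_design", "density must be in [0, 1]")
  if (!is_scalar_num(line_width) || line_width <= 0)
    pf_stop("bad_design", "line width must be positive")
  if (shape == "block" && (length(dims) != 2L || any(dims <= 0)))
    pf_stop("bad_design", "block dims must be two positive lengths")
  structure(list(shape = shape, dims = dims, pattern = pattern,
                 density = density, shells = as.integer(shells),
                 line_width = line_width),
            class = "design_spec")
}

# Closed "deer-like" silhouette used for the outline design: body with leg
# notches plus a separate antler loop, giving two extrusion runs and a travel
# span between them (an ooze site). Local coordinates in mm, y up.
deer_outline <- function() {
  body <- rbind(
    c(4, 16),  c(2, 22),  c(6, 26),  c(20, 27), c(32, 25),
    c(38, 28), c(40, 36), c(44, 40), c(50, 40), c(52, 35),
    c(47, 34), c(45, 28), c(45, 20), c(44, 6),  c(40, 6),
    c(41, 17), c(36, 19), c(30, 17), c(29, 6),  c(25, 6),
    c(26, 16), c(14, 17), c(13, 6),  c(9, 6),   c(10, 16)
  )
  # rotate so the body run starts/stops at the head, near the antler loop:
  # the stop -> start travel span between the two runs stays short
  i <- which(body[, 1] == 44 & body[, 2] == 40)
  body <- body[c(i:nrow(body), seq_len(i - 1L)), ]
  antler <- rbind(c(45, 42), c(47, 48), c(49, 43))
  list(body = body, antler = antler)
}

#' Generate a slicer-equivalent design toolpath
#'
#' Emulates the sliced layer stack as seen from above. One or more perimeter
#' shells enclose the infill region; rectilinear infill is a crosshatch of
#' two perpendicular stripe families at centre pitch `w_sp / (2 density)`
#' (with `w_sp` the extrusion spacing of the line width at the layer height),
#' the top view of alternating-orientation layers interleaved at half pitch;
#' honeycomb infill is a full hexagonal wall grid whose pitch is solved so
#' that its material fraction equals the union of the three interlocking
#' hexagon offsets the layer cycle exposes. Extrusion distances are consistent
#' with the flattened-filament width model at the target line width.
#'
#' The design is centred in the frame; the returned ledger records the
#' start/stop points, the outer footprint polygon, and the infill region.
#'
#' @param spec a [design_spec()].
#' @param params a [printer_params()].
#' @param frame a [frame_spec()]; the design is centred in it.
#' @return an object of class `design_path`: list with `path` (the
#'   `toolpath`), `spec`, `frame`, `footprint` (outer polygon, mm),
#'   `region` (infill region polygon or NULL), `start_stop` (ledger data
#'   frame) and `n_runs`.
#' @examples
#' d <- generate_design_path(design_spec("block", density = 0.2),
#'                           frame = frame_spec(80, 50, 10))
#' G <- render_layer(d, d$frame)
#' design_infill(G, d$footprint)   # about 77%
#' @export
generate_design_path <- function(spec, params = printer_params(),
                                 frame = frame_spec()) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "printer_params"),
            inherits(frame, "frame_spec"))
  w <- spec$line_width
  if (w < params$nozzle_diameter)
    pf_warn("thin_line", "line width %.2f below nozzle diameter %.2f", w,
            params$nozzle_diameter)
  wsp <- extrusion_spacing(w, params)

  runs <- list()  # each: matrix of polyline vertices (mm), continuous extrusion

  if (spec$shape == "block") {
    W <- spec$dims[1]; Hd <- spec$dims[2]
    cx <- frame$width_mm / 2; cy <- frame$height_mm / 2
    x0 <- cx - W / 2; y0 <- cy - Hd / 2
    footprint <- rbind(c(x0, y0), c(x0 + W, y0), c(x0 + W, y0 + Hd), c(x0, y0 + Hd))
    # perimeter shells, outermost first
    for (k in seq_len(spec$shells)) {
      inset <- (k - 0.5) * w
      runs[[length(runs) + 1L]] <- rbind(
        c(x0 + inset, y0 + inset), c(x0 + W - inset, y0 + inset),
        c(x0 + W - inset, y0 + Hd - inset), c(x0 + inset, y0 + Hd - inset),
        c(x0 + inset, y0 + inset))
    }
    inset <- spec$shells * w
    region <- rbind(c(x0 + inset, y0 + inset), c(x0 + W - inset, y0 + inset),
                    c(x0 + W - inset, y0 + Hd - inset), c(x0 + inset, y0 + Hd - inset))
    rw <- W - 2 * inset; rh <- Hd - 2 * inset
    if (spec$density > 0 && rw > w && rh > w) {
      if (spec$pattern == "rectilinear") {
        p <- wsp / (2 * spec$density)
        if (p < w) {
          pf_warn("density_clamped",
                  "infill pitch %.2f below line width %.2f: clamped to solidity", p, w)
          p <- w
        }
        runs <- c(runs, rectilinear_runs(region, p, w))
      } else {
        FF <- min(1 - 1e-9, w * spec$density / wsp)
        target <- 1 - (1 - FF)^3
        pitch <- w / (1 - (1 - target)^(1 / 2))
        runs <- c(runs, honeycomb_runs(region, pitch, w))
      }
    }
  } else {
    sil <- deer_outline()
    all_xy <- rbind(sil$body, sil$antler)
    ox <- frame$width_mm / 2 - mean(range(all_xy[, 1]))
    oy <- frame$height_mm / 2 - mean(range(all_xy[, 2]))
    body <- sweep(sil$body, 2, c(-ox, -oy))
    antler <- sweep(sil$antler, 2, c(-ox, -oy))
    runs[[1]] <- rbind(body, body[1, , drop = FALSE])
    runs[[2]] <- rbind(antler, antler[1, , drop = FALSE])
    footprint <- body
    region <- NULL
  }

  path <- runs_to_toolpath(runs, w, params)
  structure(list(path = path, spec = spec, frame = frame,
                 footprint = footprint, region = region,
                 start_stop = detect_start_stop(path),
                 n_runs = length(runs)),
            class = "design_path")
}

#' @export
print.design_path <- function(x, ...) {
  cat(sprintf("Design path: %s", x$spec$shape))
  if (x$spec$shape == "block")
    cat(sprintf(" %g x %g mm, %s %.0f%% infill, %d shell(s)",
                x$spec$dims[1], x$spec$dims[2], x$spec$pattern,
                100 * x$spec$density, x$spec$shells))
  cat(sprintf("\n  %d extrusion runs, %d start/stop points\n",
              x$n_runs, nrow(x$start_stop)))
  invisible(x)
}

# Crosshatch stripe families across a rectangular region (region = 4x2 corner
# matrix, axis aligned). Stripe centrelines lie fully inside laterally; their
# endpoints sit on the region boundary so round caps overlap the shell.
rectilinear_runs <- function(region, pitch, w) {
  x0 <- min(region[, 1]); x1 <- max(region[, 1])
  y0 <- min(region[, 2]); y1 <- max(region[, 2])
  runs <- list()
  family <- function(lo, hi) {
    n <- floor((hi - lo - w) / pitch) + 1L
    if (n < 1L) return(numeric(0))
    mid <- (lo + hi) / 2
    mid + (seq_len(n) - (n + 1) / 2) * pitch
  }
  flip <- FALSE
  for (x in family(x0, x1)) {
    runs[[length(runs) + 1L]] <- if (flip) rbind(c(x, y1), c(x, y0))
                                 else rbind(c(x, y0), c(x, y1))
    flip <- !flip
  }
  for (y in family(y0, y1)) {
    runs[[length(runs) + 1L]] <- if (flip) rbind(c(x1, y), c(x0, y))
                                 else rbind(c(x0, y), c(x1, y))
    flip <- !flip
  }
  runs
}

# Full hexagonal wall grid (pointy-top cells; pitch = wall-to-wall distance)
# clipped to the rectangular region; each clipped edge is one extrusion run.
honeycomb_runs <- function(region, pitch, w) {
  x0 <- min(region[, 1]); x1 <- max(region[, 1])
  y0 <- min(region[, 2]); y1 <- max(region[, 2])
  a <- pitch / sqrt(3)  # hexagon side
  edges <- list()
  jmax <- ceiling((y1 - y0) / (1.5 * a)) + 1L
  imax <- ceiling((x1 - x0) / pitch) + 1L
  seen <- new.env(hash = TRUE)
  add_edge <- function(p, q) {
    key <- paste(round(c(pmin(p, q), pmax(p, q)) * 1e6), collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    cl <- clip_segment(p, q, x0, x1, y0, y1)
    if (!is.null(cl)) edges[[length(edges) + 1L]] <<- cl
  }
  for (j in -1:jmax) {
    cyj <- y0 + j * 1.5 * a
    offx <- if (j %% 2 == 0) 0 else pitch / 2
    for (i in -1:imax) {
      cxi <- x0 + offx + i * pitch
      v <- rbind(c(cxi, cyj + a), c(cxi + pitch / 2, cyj + a / 2),
                 c(cxi + pitch / 2, cyj - a / 2), c(cxi, cyj - a),
                 c(cxi - pitch / 2, cyj - a / 2), c(cxi - pitch / 2, cyj + a / 2))
      for (k in 1:6) add_edge(v[k, ], v[if (k == 6) 1 else k + 1, ])
    }
  }
  lapply(edges, function(e) rbind(e$p, e$q))
}

# Liang-Barsky clip of segment p->q to [x0,x1]x[y0,y1]; NULL if outside.
clip_segment <- function(p, q, x0, x1, y0, y1) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (side in 1:4) {
    pp <- switch(side, -d[1], d[1], -d[2], d[2])
    qq <- switch(side, p[1] - x0, x1 - p[1], p[2] - y0, y1 - p[2])
    if (pp == 0) { if (qq < 0) return(NULL) } else {
      r <- qq / pp
      if (pp < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else        { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  if (t1 - t0 < 1e-9) return(NULL)
  list(p = p + t0 * d, q = p + t1 * d)
}

# Turn extrusion runs (polylines) into a toolpath: travel moves connect
# consecutive runs, extrusion distances follow the width model.
runs_to_toolpath <- function(runs, w, params) {
  rows <- list()
  cur <- NULL; e_cum <- 0
  feed <- params$print_speed * 60
  for (run in runs) {
    if (nrow(run) < 2L) next
    if (!is.null(cur) && (cur[1] != run[1, 1] || cur[2] != run[1, 2])) {
      rows[[length(rows) + 1L]] <- c(cur[1], cur[2], run[1, 1], run[1, 2],
                                     params$layer_height, e_cum, e_cum, 0, feed)
    }
    for (k in seq_len(nrow(run) - 1L)) {
      X <- sqrt(sum((run[k + 1L, ] - run[k, ])^2))
      if (X == 0) next
      de <- extrusion_for_width(w, X, params)
      rows[[length(rows) + 1L]] <- c(run[k, 1], run[k, 2],
                                     run[k + 1L, 1], run[k + 1L, 2],
                                     params$layer_height, e_cum, e_cum + de,
                                     de, feed)
      e_cum <- e_cum + de
    }
    cur <- run[nrow(run), ]
  }
  if (!length(rows)) pf_stop("empty_toolpath", "design produced no extrusion")
  seg <- as.data.frame(do.call(rbind, rows))
  names(seg) <- c("x1", "y1", "x2", "y2", "z", "e1", "e2", "de", "f")
  seg$de_raw <- seg$de
  seg$extruding <- seg$de > 0
  seg <- seg[, c("x1", "y1", "x2", "y2", "z", "e1", "e2", "de", "de_raw",
                 "f", "extruding")]
  new_toolpath(seg, params)
}
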