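#' Estimate the registration shift between print and design
#'
#' Integer-pixel translation aligning the design layer image G to the
#' segmented print P. The default maximizes the binary cross-correlation
#' (computed by FFT) over shifts within `max_shift`; ties are broken toward
#' the smaller shift. The alternative equates the two centres of mass.
#' Sub-pixel registration is not attempted: binary masks make it ill-defined.
#'
#' @param P,G `layer_image` objects on the same frame.
#' @param method "xcorr" or "com" (centre of mass).
#' @param max_shift largest allowed |dx|, |dy| in px.
#' @return an object of class `registration_shift`: list with integer `dx`
#'   (+right), `dy` (+down, raster rows) and `method`. Shifting G by (dx, dy)
#'   aligns it to P.
#' @export
estimate_shift <- function(P, G, method = c("xcorr", "com"), max_shift = 100) {
  stopifnot(inherits(P, "layer_image"), inherits(G, "layer_image"))
  method <- match.arg(method)
  if (!identical(dim(P$mask), dim(G$mask)))
    pf_stop("dim_mismatch", "P and G must share the same frame raster")
  if (!any(P$mask) || !any(G$mask))
    pf_stop("registration", "registration requires non-empty masks")
  if (method == "com") {
    ip <- which(P$mask, arr.ind = TRUE); ig <- which(G$mask, arr.ind = TRUE)
    dy <- round(mean(ip[, 1]) - mean(ig[, 1]))
    dx <- round(mean(ip[, 2]) - mean(ig[, 2]))
  } else {
    p <- P$mask + 0; g <- G$mask + 0
    nr <- nrow(p); nc <- ncol(p)
    cc <- Re(stats::fft(stats::fft(p) * Conj(stats::fft(g)), inverse = TRUE)) /
      (nr * nc)
    # circular index k (0-based) corresponds to shift k, or k - n on wrap
    sh_r <- c(0:(nr - 1)); sh_r[sh_r > nr / 2] <- sh_r[sh_r > nr / 2] - nr
    sh_c <- c(0:(nc - 1)); sh_c[sh_c > nc / 2] <- sh_c[sh_c > nc / 2] - nc
    ok_r <- abs(sh_r) <= max_shift; ok_c <- abs(sh_c) <= max_shift
    sub <- cc[ok_r, ok_c, drop = FALSE]
    best <- max(sub)
    cand <- which(sub >= best - 1e-6, arr.ind = TRUE)
    dyv <- sh_r[ok_r][cand[, 1]]; dxv <- sh_c[ok_c][cand[, 2]]
    pick <- order(abs(dxv) + abs(dyv), abs(dyv), abs(dxv))[1]
    dy <- dyv[pick]; dx <- dxv[pick]
  }
  if (abs(dx) > max_shift || abs(dy) > max_shift)
    pf_stop("registration", "estimated shift (%d, %d) exceeds max_shift %d",
            dx, dy, max_shift)
  structure(list(dx = as.integer(dx), dy = as.integer(dy), method = method),
            class = "registration_shift")
}

#' @export
print.registration_shift <- function(x, ...) {
  cat(sprintf("Registration shift: dx=%d, dy=%d px (%s)\n", x$dx, x$dy, x$method))
  invisible(x)
}

#' Apply a registration shift to a layer image
#'
#' @param G a `layer_image`.
#' @param shift a `registration_shift`, or integer vector c(dx, dy).
#' @return the translated `layer_image` (zero fill at the borders).
#' @export
apply_shift <- function(G, shift) {
  stopifnot(inherits(G, "layer_image"))
  if (inherits(shift, "registration_shift")) shift <- c(shift$dx, shift$dy)
  layer_image(shift_mask(G$mask, shift[1], shift[2]), G$frame, G$role)
}

#' Over- and under-extrusion defect maps
#'
#' Bitwise set logic between the segmented print P and the (shifted) design G:
#' the under-extruded area is U = (P | G) xor P (designed positions lacking
#' material) and the over-extruded area is O = (P xor G) xor U (printed
#' material outside the design). On baked samples the same maps are read as
#' "incompletion from design" and "expansion from design".
#'
#' @param P,G `layer_image` objects on the same raster (G already registered).
#' @return an object of class `defect_maps`: list with logical matrices `O`,
#'   `U` and the pixel areas `area_P`, `area_G`, `area_O`, `area_U`.
#' @examples
#' fr <- frame_spec(3, 3, 1)
#' P <- layer_image(matrix(c(1,1,0, 0,0,0, 0,0,0), 3, byrow = TRUE) > 0, fr, "print")
#' G <- layer_image(matrix(c(0,1,1, 0,0,0, 0,0,0), 3, byrow = TRUE) > 0, fr)
#' m <- defect_maps(P, G)
#' which(m$O); which(m$U)
#' @export
defect_maps <- function(P, G) {
  stopifnot(inherits(P, "layer_image"), inherits(G, "layer_image"))
  p <- P$mask; g <- G$mask
  if (!identical(dim(p), dim(g)))
    pf_stop("dim_mismatch", "P and G must share the same frame raster")
  U <- xor(p | g, p)
  O <- xor(xor(p, g), U)
  structure(list(O = O, U = U,
                 area_P = sum(p), area_G = sum(g),
                 area_O = sum(O), area_U = sum(U),
                 frame = P$frame),
            class = "defect_maps")
}

#' @export
print.defect_maps <- function(x, ...) {
  cat(sprintf("Defect maps: |P|=%d, |G|=%d, |O|=%d, |U|=%d px\n",
              x$area_P, x$area_G, x$area_O, x$area_U))
  invisible(x)
}

#' Measured infill of a printed layer
#'
#' Filled pixels of the segmented print inside the design footprint divided by
#' the footprint area, as a percent. The footprint polygon is placed with the
#' registration shift so it tracks the print.
#'
#' @param P a `layer_image` (print).
#' @param footprint footprint polygon (two-column matrix, mm) or logical mask.
#' @param shift optional `registration_shift` or c(dx, dy) px applied to the
#'   footprint.
#' @return infill percent.
#' @export
measured_infill <- function(P, footprint, shift = c(0L, 0L)) {
  stopifnot(inherits(P, "layer_image"))
  region <- if (is.logical(footprint) && !is.null(dim(footprint))) footprint
            else polygon_mask(footprint, P$frame)
  if (inherits(shift, "registration_shift")) shift <- c(shift$dx, shift$dy)
  if (any(shift != 0)) region <- shift_mask(region, shift[1], shift[2])
  n <- sum(region)
  if (n == 0) pf_stop("empty_region", "design footprint region is empty")
  100 * sum(P$mask & region) / n
}

#' Whole-image over- and under-extrusion percentages
#'
#' Both are normalized by the design area |G| as a deliberate convention (the
#' source imagery never states a denominator): 0 percent is a perfect print
#' and values are comparable across designs. Reports carry the convention.
#'
#' @param maps a `defect_maps`.
#' @return named numeric vector c(over, under), percent of |G|.
#' @export
extrusion_percentages <- function(maps) {
  stopifnot(inherits(maps, "defect_maps"))
  if (maps$area_G == 0)
    pf_stop("empty_design", "design area |G| is zero")
  c(over = 100 * maps$area_O / maps$area_G,
    under = 100 * maps$area_U / maps$area_G)
}

# Per-tile sums of a logical/numeric matrix over g x g tiles (last row/column
# of tiles may be partial).
tile_sums <- function(m, g) {
  gr <- ceiling(seq_len(nrow(m)) / g)
  gc <- ceiling(seq_len(ncol(m)) / g)
  t(rowsum(t(rowsum(m + 0, gr, reorder = TRUE)), gc, reorder = TRUE))
}

#' Localized over-extrusion grid indices
#'
#' The image is tiled by g x g pixel grids and each grid n gets the index
#' i_over = sum(O_n) / (sum(P_n) + 1); the +1 guards grids with no printed
#' material. High indices flag grids where material sits outside the design.
#'
#' @param O logical defect mask (or `defect_maps`, whose O is used).
#' @param P logical print mask or `layer_image`.
#' @param g grid size in px (9 by default, the survey grid).
#' @return an object of class `grid_index_field`: list with matrix `index`
#'   (one cell per grid), `g`, and the tile sums `sum_O`, `sum_P`.
#' @export
grid_indices <- function(O, P, g = 9) {
  if (inherits(O, "defect_maps")) O <- O$O
  if (inherits(P, "layer_image")) P <- P$mask
  if (!is_scalar_num(g) || g < 1) pf_stop("bad_grid", "grid size must be >= 1")
  g <- as.integer(g)
  if (!identical(dim(O), dim(P)))
    pf_stop("dim_mismatch", "O and P must share dimensions")
  sO <- tile_sums(O, g); sP <- tile_sums(P, g)
  structure(list(index = sO / (sP + 1), g = g, sum_O = sO, sum_P = sP),
            class = "grid_index_field")
}

#' Percentile normalization of grid indices
#'
#' Maps a list of grid indices to `[0, 1]` with protection against extreme
#' values: indices above the 99th percentile q99 are clipped to 1, the rest
#' are scaled as (i - min I) / (q99 - min I). The percentile uses linear
#' interpolation; a constant field returns all zeros with a warning.
#'
#' @param I numeric vector or matrix of grid indices (a `grid_index_field` is
#'   accepted).
#' @return normalized values with the shape of the input; attribute `q99`
#'   carries the percentile used.
#' @export
normalize_indices <- function(I) {
  field <- NULL
  if (inherits(I, "grid_index_field")) { field <- I; I <- I$index }
  if (!length(I)) pf_stop("empty_index", "index list is empty")
  q99 <- stats::quantile(I, 0.99, names = FALSE, type = 7)
  lo <- min(I)
  if (q99 <= lo) {
    pf_warn("constant_field", "constant index field: normalized values set to 0")
    out <- I * 0
  } else {
    out <- (I - lo) / (q99 - lo)
    out[I > q99] <- 1
  }
  attr(out, "q99") <- q99
  out
}

# Grids ranking in the top `frac` share of the field by value.
top_grids <- function(values, frac = 0.1) {
  n <- length(values)
  k <- max(1L, floor(frac * n))
  ord <- order(values, decreasing = TRUE)
  sel <- logical(n); sel[ord[seq_len(k)]] <- TRUE
  if (!is.null(dim(values))) dim(sel) <- dim(values)
  sel
}

#' Assess layer-wise printing accuracy
#'
#' Runs the full pipeline: rectify and segment the photograph (when given a
#' raw scene), render the digital layer image from the design toolpath,
#' register the two, compute the defect maps and whole-image metrics, and
#' localize defects as a percentile-normalized, Gaussian-smoothed grid-index
#' heatmap. For baked samples set `stage = "baked"`: the same measurements are
#' reported as expansion/incompletion from design.
#'
#' @param photo the print: a raw color scene (array or PNG path), a
#'   `rectified_photo`, or an already segmented `layer_image` (role "print").
#' @param design the design: a `design_path`, a `toolpath`, or a G-code file
#'   path.
#' @param frame a [frame_spec()].
#' @param line_width rendered design line width (mm).
#' @param grid_px grid size for localization (px).
#' @param sigma_grid Gaussian smoothing sigma for the heatmap, in grid units.
#' @param registration "xcorr" or "com".
#' @param max_shift registration search radius (px).
#' @param stage "fresh" or "baked" (labels only; the measurements are
#'   identical).
#' @param params a [printer_params()] (used when parsing G-code).
#' @return an object of class `accuracy_report`.
#' @export
assess <- function(photo, design, frame = frame_spec(), line_width = 1.5,
                   grid_px = 9, sigma_grid = 2,
                   registration = c("xcorr", "com"), max_shift = 100,
                   stage = c("fresh", "baked"), params = printer_params()) {
  registration <- match.arg(registration)
  stage <- match.arg(stage)
  run_stage <- function(name, expr) {
    tryCatch(expr, printfid_error = function(e)
      pf_stop("stage", "[%s] %s", name, conditionMessage(e)))
  }

  footprint <- NULL; start_stop <- NULL
  if (is.character(design) && file.exists(design))
    design <- run_stage("parse", parse_gcode(design, params))
  if (inherits(design, "design_path")) {
    footprint <- design$footprint
    start_stop <- design$start_stop
    tp <- design$path
  } else if (inherits(design, "toolpath")) {
    tp <- design
    start_stop <- detect_start_stop(tp)
  } else pf_stop("bad_input", "design must be a design_path, toolpath or G-code file")

  P <- if (inherits(photo, "layer_image")) photo
       else if (inherits(photo, "rectified_photo")) run_stage("segment", segment(photo))
       else run_stage("segment", segment(run_stage("rectify", rectify(photo, frame = frame))))
  frame <- P$frame
  G <- run_stage("render", render_layer(tp, frame, "fixed", line_width))

  shift <- run_stage("register", estimate_shift(P, G, registration, max_shift))
  Gs <- apply_shift(G, shift)
  maps <- run_stage("defects", defect_maps(P, Gs))
  pct <- extrusion_percentages(maps)
  infill <- if (!is.null(footprint))
    measured_infill(P, footprint, shift) else NA_real_

  field <- grid_indices(maps$O, P$mask, grid_px)
  norm <- suppressWarnings(normalize_indices(field))
  heat <- gauss_smooth(matrix(norm, nrow(field$index)), sigma_grid)

  labels <- if (stage == "fresh") c(over = "over-extrusion %", under = "under-extrusion %")
            else c(over = "expansion from design %", under = "incompletion from design %")
  structure(list(
    stage = stage, labels = labels,
    infill = infill, over_pct = unname(pct["over"]), under_pct = unname(pct["under"]),
    shift = shift, maps = maps, P = P, G = Gs, field = field,
    normalized = matrix(as.numeric(norm), nrow(field$index)),
    heatmap = heat, start_stop = start_stop, frame = frame,
    areas_px = c(P = maps$area_P, G = maps$area_G, O = maps$area_O, U = maps$area_U),
    areas_mm2 = c(P = maps$area_P, G = maps$area_G, O = maps$area_O,
                  U = maps$area_U) / frame$scale^2,
    denominator = "design area |G|"
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Layer-wise printing accuracy (%s sample)\n", x$stage))
  if (!is.na(x$infill))
    cat(sprintf("  measured infill          %6.1f %%\n", x$infill))
  cat(sprintf("  %-24s %6.2f %%\n", x$labels["over"], x$over_pct))
  cat(sprintf("  %-24s %6.2f %%\n", x$labels["under"], x$under_pct))
  cat(sprintf("  registration shift       (%d, %d) px [%s]\n",
              x$shift$dx, x$shift$dy, x$shift$method))
  cat(sprintf("  areas |P|=%.0f |G|=%.0f |O|=%.0f |U|=%.0f mm2\n",
              x$areas_mm2["P"], x$areas_mm2["G"], x$areas_mm2["O"], x$areas_mm2["U"]))
  cat(sprintf("  percentages normalized by %s\n", x$denominator))
  invisible(x)
}

#' @export
summary.accuracy_report <- function(object, ...) {
  out <- data.frame(
    metric = c("infill", object$labels["over"], object$labels["under"],
               "shift dx", "shift dy"),
    value = c(object$infill, object$over_pct, object$under_pct,
              object$shift$dx, object$shift$dy),
    row.names = NULL)
  out
}

#' @export
plot.accuracy_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main, col) {
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = col, axes = FALSE,
                    main = main, asp = nrow(m) / ncol(m))
  }
  show(x$P$mask, "print P", c("grey15", "wheat"))
  show(x$G$mask, "design G (registered)", c("grey15", "skyblue"))
  ou <- x$maps$O + 2 * x$maps$U
  show(ou, "defects (red = over, yellow = under)",
       c("grey15", "red3", "gold", "orange"))
  show(x$heatmap, "normalized over-extrusion heatmap",
       grDevices::hcl.colors(32, "inferno"))
  invisible(x)
}
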