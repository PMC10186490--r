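#' Parse G-code into a metric toolpath
#'
#' Reads RepRap-flavour G-code (G0/G1 moves with X/Y/Z/E/F words) and returns
#' the ordered list of motion segments with reconstructed cumulative extrusion.
#' Modal state is tracked from the header: `G90`/`G91` switch absolute/relative
#' coordinates, `M82`/`M83` switch absolute/relative extrusion, `G92` resets
#' the logical position. Unspecified words inherit their modal values.
#'
#' Retraction is handled the way paste printers use it to delimit extrusion
#' runs: a negative extrusion move marks a stop, and the subsequent positive
#' "prime" up to the retracted amount does not count as deposition, so only
#' genuinely deposited material makes a segment extruding.
#'
#' Arc moves (`G2`/`G3`) are not supported and raise an error; other lines are
#' ignored.
#'
#' @param text a character vector of G-code lines, a single string with
#'   newlines, or a file path.
#' @param params a [printer_params()] object.
#' @return an object of class `toolpath`: a list with `segments` (data frame
#'   with columns x1, y1, x2, y2, z, e1, e2, de, f, extruding), `params` and
#'   the bounding box `bbox` in mm.
#' @seealso [detect_start_stop()], [filament_width()], [render_layer()]
#' @examples
#' gc <- c("G90", "M82", "G1 X0 Y0 F1200", "G1 X10 Y0 E0.5", "G1 X10 Y10 E1.0")
#' tp <- parse_gcode(gc, printer_params())
#' tp$segments
#' @export
parse_gcode <- function(text, params = printer_params()) {
  stopifnot(inherits(params, "printer_params"))
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else unlist(strsplit(text, "\n", fixed = TRUE))

  # strip comments and whitespace
  lines_raw <- lines
  lines <- sub(";.*$", "", lines)
  lines <- gsub("\\(.*?\\)", "", lines)  # inline parenthesis comments
  lines <- trimws(lines)

  abs_xyz <- TRUE; abs_e <- TRUE
  x <- y <- z <- 0; e <- 0        # logical (G92-settable) position
  e_cum <- 0                      # physical cumulative extrusion
  f <- NA_real_
  deficit <- 0                    # retracted length not yet re-primed
  seen_motion <- FALSE
  rows <- vector("list", length(lines))
  n_rows <- 0L

  word_val <- function(words, letter) {
    hit <- grep(paste0("^", letter), words, value = TRUE)
    if (!length(hit)) return(NA_real_)
    v <- suppressWarnings(as.numeric(sub(paste0("^", letter), "", hit[1])))
    if (is.na(v)) NaN else v  # NaN marks a present-but-malformed word
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    words <- strsplit(ln, "[ \t]+")[[1]]
    cmd <- toupper(words[1])
    if (cmd %in% c("G2", "G02", "G3", "G03"))
      pf_stop("arc_unsupported", "arc move (%s) at line %d is not supported", cmd, i)
    if (cmd %in% c("G90")) { abs_xyz <- TRUE; next }
    if (cmd %in% c("G91")) { abs_xyz <- FALSE; abs_e <- FALSE; next }
    if (cmd %in% c("M82")) { abs_e <- TRUE; next }
    if (cmd %in% c("M83")) { abs_e <- FALSE; next }
    if (cmd %in% c("G92")) {
      vx <- word_val(words, "X"); vy <- word_val(words, "Y")
      vz <- word_val(words, "Z"); ve <- word_val(words, "E")
      if (!is.na(vx)) x <- vx
      if (!is.na(vy)) y <- vy
      if (!is.na(vz)) z <- vz
      if (!is.na(ve)) e <- ve
      next
    }
    if (!(cmd %in% c("G0", "G00", "G1", "G01"))) next

    vx <- word_val(words, "X"); vy <- word_val(words, "Y")
    vz <- word_val(words, "Z"); ve <- word_val(words, "E")
    vf <- word_val(words, "F")
    if (any(is.nan(c(vx, vy, vz, ve, vf))))
      pf_stop("parse", "unparseable motion line %d: %s", i, lines_raw[i])
    if (!is.na(vf)) f <- vf

    nx <- if (is.na(vx)) x else if (abs_xyz) vx else x + vx
    ny <- if (is.na(vy)) y else if (abs_xyz) vy else y + vy
    nz <- if (is.na(vz)) z else if (abs_xyz) vz else z + vz
    de_raw <- if (is.na(ve)) 0 else if (abs_e) ve - e else ve
    if (!is.na(ve)) e <- if (abs_e) ve else e + ve

    # retraction bookkeeping: negative flow adds to the deficit, positive
    # flow first pays it back before depositing
    if (de_raw < 0) {
      dep <- 0
      deficit <- deficit - de_raw
    } else {
      dep <- max(0, de_raw - deficit)
      deficit <- max(0, deficit - de_raw)
    }
    seen_motion <- TRUE
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- c(x1 = x, y1 = y, x2 = nx, y2 = ny, z = nz,
                        e1 = e_cum, e2 = e_cum + dep, de_raw = de_raw, f = f)
    e_cum <- e_cum + dep
    x <- nx; y <- ny; z <- nz
  }

  if (!seen_motion)
    pf_stop("empty_toolpath", "no motion commands found in G-code input")

  seg <- as.data.frame(do.call(rbind, rows[seq_len(n_rows)]))
  seg$de <- seg$e2 - seg$e1
  moved <- (seg$x1 != seg$x2) | (seg$y1 != seg$y2)
  seg$extruding <- seg$de > 0 & moved
  seg <- seg[, c("x1", "y1", "x2", "y2", "z", "e1", "e2", "de", "de_raw",
                 "f", "extruding")]
  new_toolpath(seg, params)
}

new_toolpath <- function(segments, params) {
  ext <- segments[segments$extruding, , drop = FALSE]
  bbox <- if (nrow(ext))
    c(xmin = min(ext$x1, ext$x2), xmax = max(ext$x1, ext$x2),
      ymin = min(ext$y1, ext$y2), ymax = max(ext$y1, ext$y2))
  else c(xmin = NA_real_, xmax = NA_real_, ymin = NA_real_, ymax = NA_real_)
  structure(list(segments = segments, params = params, bbox = bbox),
            class = "toolpath")
}

#' @export
print.toolpath <- function(x, ...) {
  seg <- x$segments
  cat(sprintf("Toolpath: %d segments (%d extruding), E total %.2f mm\n",
              nrow(seg), sum(seg$extruding), max(seg$e2)))
  if (any(seg$extruding))
    cat(sprintf("  extrusion bbox [%.1f, %.1f] x [%.1f, %.1f] mm\n",
                x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

#' Serialize a toolpath back to G-code
#'
#' Emits absolute-coordinate, absolute-E G-code (`G90`/`M82` header) that
#' re-parses to the same segment table, including retraction events
#' (negative raw extrusion moves).
#'
#' @param path a `toolpath`.
#' @param file optional output file; if `NULL` the lines are returned.
#' @return character vector of G-code lines, invisibly when written to file.
#' @export
write_gcode <- function(path, file = NULL) {
  stopifnot(inherits(path, "toolpath"))
  seg <- path$segments
  fmt <- function(v) sub("\\.$", ".0", sub("0+$", "", sprintf("%.9f", v)))
  out <- c("G90", "M82")
  e_log <- 0
  prev <- NULL
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (is.null(prev) || prev$x2 != s$x1 || prev$y2 != s$y1 || prev$z != s$z)
      out <- c(out, sprintf("G92 X%s Y%s Z%s", fmt(s$x1), fmt(s$y1), fmt(s$z)))
    e_log <- e_log + s$de_raw
    ln <- sprintf("G1 X%s Y%s Z%s E%s", fmt(s$x2), fmt(s$y2), fmt(s$z), fmt(e_log))
    if (!is.na(s$f)) ln <- paste0(ln, " F", fmt(s$f))
    out <- c(out, ln)
    prev <- s
  }
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Dump a toolpath as CSV
#'
#' @param path a `toolpath`.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_toolpath_csv <- function(path, file) {
  stopifnot(inherits(path, "toolpath"))
  utils::write.csv(path$segments[, c("x1", "y1", "x2", "y2", "z", "de", "f",
                                     "extruding")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Detect start/stop points of continuous extrusion
#'
#' A maximal run of consecutive extruding segments gets a start point at its
#' first endpoint and a stop point at its last; travel moves and retractions
#' break runs. These are the locations where flow is started or stopped and
#' where ooze and start/stop over-extrusion blobs concentrate.
#'
#' @param path a `toolpath`.
#' @return data frame with columns `x`, `y` (mm), `kind` ("start"/"stop") and
#'   `run` (run index), in path order. Zero rows if nothing extrudes.
#' @export
detect_start_stop <- function(path) {
  stopifnot(inherits(path, "toolpath"))
  seg <- path$segments
  ext <- seg$extruding
  if (!any(ext))
    return(data.frame(x = numeric(0), y = numeric(0),
                      kind = character(0), run = integer(0)))
  r <- rle(ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- do.call(rbind, lapply(seq_along(runs), function(k) {
    i0 <- starts[runs[k]]; i1 <- ends[runs[k]]
    data.frame(x = c(seg$x1[i0], seg$x2[i1]),
               y = c(seg$y1[i0], seg$y2[i1]),
               kind = c("start", "stop"), run = k)
  }))
  rownames(out) <- NULL
  out
}

#' Flattened-filament width model
#'
#' Width of the deposited line between two path points, from conservation of
#' extrusion volume. A piston advance of `dE` in a syringe of bore `D` expels
#' a volume pi D^2 dE / 4, spread over the travelled length `X` at layer
#' height `H`. The flattened bead cross-section is a stadium (rectangle capped
#' by two semicircles of diameter H), with area W H - H^2 + pi H^2 / 4, giving
#'
#'   W = pi dE D^2 / (4 X H) + H (1 - pi/4)
#'
#' W is clamped below at H, the degenerate circular cross-section.
#'
#' @param de extrusion distance dE (mm), vectorized.
#' @param X travelled length (mm), vectorized.
#' @param params a [printer_params()].
#' @return widths in mm. `NA` where the width is undefined: `X == 0` with
#'   positive `de` is a blob deposit (flagged with a warning), negative `de`
#'   is a retraction.
#' @examples
#' filament_width(0.1, 10, printer_params(syringe_diameter = 20,
#'                                        layer_height = 1))  # ~3.356 mm
#' @export
filament_width <- function(de, X, params = printer_params()) {
  stopifnot(inherits(params, "printer_params"))
  n <- max(length(de), length(X))
  de <- rep_len(de, n); X <- rep_len(X, n)
  D <- params$syringe_diameter; H <- params$layer_height
  w <- rep(NA_real_, n)
  blob <- X == 0 & de > 0
  if (any(blob))
    pf_warn("blob_deposit", "%d zero-length deposit(s): width undefined (blob)",
            sum(blob))
  ok <- X > 0 & de >= 0
  w[ok] <- pmax(H, pi * de[ok] * D^2 / (4 * X[ok] * H) + H * (1 - pi / 4))
  w
}

# Inverse of the width model: extrusion distance laying a line of width w
# over length X. Used by the slicer emulation to make E consistent with the
# width model at the target line width.
extrusion_for_width <- function(w, X, params) {
  H <- params$layer_height; D <- params$syringe_diameter
  area <- w * H - H^2 + pi * H^2 / 4
  area * X / (pi * D^2 / 4)
}

# Extrusion spacing: centre-to-centre distance at which adjacent flattened
# beads of width w tile without gap or overlap of material (the rectangle
# part abuts, the semicircular caps interlock).
extrusion_spacing <- function(w, params) {
  w - params$layer_height * (1 - pi / 4)
}
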