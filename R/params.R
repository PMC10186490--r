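#' Printer parameters
#'
#' Geometry and kinematics of the paste extrusion printer needed by the
#' filament-width model and the slicer emulation. Defaults follow a
#' syringe-based food printer with a 1.2 mm nozzle printing at 20 mm/s with a
#' 2 mm retraction. The layer height defaults to the nozzle diameter, as is
#' common when laying soft dough beads; the syringe bore defaults to a typical
#' 30 mm food cartridge and should be set to the actual machine value whenever
#' quantitative extrusion distances matter.
#'
#' @param nozzle_diameter nozzle bore d (mm).
#' @param syringe_diameter syringe/cartridge bore D (mm); the extrusion
#'   distance E advances a piston of this diameter.
#' @param layer_height deposited layer height H (mm).
#' @param retraction_length piston retraction used to stop flow (mm).
#' @param print_speed nominal printing speed (mm/s).
#' @return an object of class `printer_params`.
#' @examples
#' printer_params()
#' @export
printer_params <- function(nozzle_diameter = 1.2,
                           syringe_diameter = 30,
                           layer_height = 1.2,
                           retraction_length = 2,
                           print_speed = 20) {
  vals <- c(nozzle_diameter = nozzle_diameter,
            syringe_diameter = syringe_diameter,
            layer_height = layer_height,
            retraction_length = retraction_length,
            print_speed = print_speed)
  if (!all(vapply(vals, is_scalar_num, logical(1))) || any(vals <= 0))
    pf_stop("bad_params", "printer parameters must be strictly positive scalars")
  if (nozzle_diameter >= syringe_diameter)
    pf_stop("bad_params", "nozzle diameter must be smaller than syringe diameter")
  structure(as.list(vals), class = "printer_params")
}

#' @export
print.printer_params <- function(x, ...) {
  cat("Printer parameters:\n")
  cat(sprintf("  nozzle d       %.2f mm\n", x$nozzle_diameter))
  cat(sprintf("  syringe D      %.2f mm\n", x$syringe_diameter))
  cat(sprintf("  layer height H %.2f mm\n", x$layer_height))
  cat(sprintf("  retraction     %.2f mm\n", x$retraction_length))
  cat(sprintf("  print speed    %.1f mm/s\n", x$print_speed))
  invisible(x)
}

#' Metric reference frame
#'
#' The calibration frame delimited by the four fiducial markers. The default
#' 240 x 150 mm frame at 10 px/mm yields a 2400 x 1500 px raster. Pixel
#' centres sit at (i + 0.5)/scale mm with half-open pixel indexing; printer
#' y-up coordinates map to raster rows top-down.
#'
#' @param width_mm,height_mm frame dimensions (mm).
#' @param scale raster resolution (px per mm).
#' @return an object of class `frame_spec` with pixel dimensions `nx`, `ny`.
#' @examples
#' frame_spec()           # the full calibration plate
#' frame_spec(80, 50, 5)  # a small frame for quick experiments
#' @export
frame_spec <- function(width_mm = 240, height_mm = 150, scale = 10) {
  if (!is_scalar_num(width_mm) || !is_scalar_num(height_mm) ||
      !is_scalar_num(scale) || width_mm <= 0 || height_mm <= 0 || scale <= 0)
    pf_stop("bad_frame", "frame dimensions and scale must be positive scalars")
  structure(list(width_mm = width_mm, height_mm = height_mm, scale = scale,
                 nx = as.integer(round(width_mm * scale)),
                 ny = as.integer(round(height_mm * scale))),
            class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("Frame %g x %g mm at %g px/mm (%d x %d px)\n",
              x$width_mm, x$height_mm, x$scale, x$nx, x$ny))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Convenience loader for YAML configuration (raster scale, grid size,
#' smoothing sigma, marker detection thresholds, registration options).
#' Unknown keys are kept as-is; missing keys fall back to the defaults used by
#' [assess()].
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) pf_stop("io", "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) pf_stop("bad_config", "config must be a YAML mapping")
  cfg
}
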