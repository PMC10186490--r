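test_that("a single segment renders as a stadium footprint", {
  fr <- frame_spec(40, 20, 10)
  # generic placement: band edges fall between pixel centres
  tp <- parse_gcode(c("M83", "G92 X5.03 Y10.03", "G1 X15.03 Y10.03 E1"))
  G <- render_layer(tp, fr, "fixed", 1.5)
  analytic <- 10 * 1.5 + pi * 0.75^2   # rectangle + two round caps
  expect_equal(sum(G$mask) / fr$scale^2, analytic, tolerance = 0.02)
  # oblique segment: same length, same area
  tp2 <- parse_gcode(c("M83", "G92 X5.03 Y5.03", sprintf("G1 X%.6f Y%.6f E1",
                                                   5.03 + 10 / sqrt(2), 5.03 + 10 / sqrt(2))))
  G2 <- render_layer(tp2, fr, "fixed", 1.5)
  expect_equal(sum(G2$mask), sum(G$mask), tolerance = 0.02 * sum(G$mask))
})

test_that("travel-only toolpaths render to an empty image", {
  fr <- frame_spec(40, 20, 5)
  tp <- parse_gcode("G1 X10 Y10")
  expect_equal(sum(render_layer(tp, fr)$mask), 0)
})

test_that("a closed rectangle perimeter renders as a band with the hole kept", {
  fr <- frame_spec(60, 40, 10)
  w <- 1.5
  tp <- parse_gcode(c("M83", "G92 X10 Y10", "G1 X50 Y10 E1", "G1 X50 Y30 E1",
                      "G1 X10 Y30 E1", "G1 X10 Y10 E1"))
  G <- render_layer(tp, fr, "fixed", w)
  # centreline rectangle 40 x 20; band area with rounded outer corners
  band <- (40 + w) * (20 + w) - (40 - w) * (20 - w) - 4 * (w / 2)^2 * (4 - pi) / 4
  expect_equal(sum(G$mask) / fr$scale^2, band, tolerance = 0.03 * band)
  # the middle stays open
  expect_false(G$mask[fr$ny / 2, fr$nx / 2])
})

test_that("rendering is deterministic and idempotent", {
  fr <- small_frame()
  d <- rl20_design()
  expect_identical(render_layer(d, fr)$mask, render_layer(d, fr)$mask)
})

test_that("model width mode draws segment widths from the volume balance", {
  fr <- frame_spec(40, 20, 10)
  p <- printer_params(syringe_diameter = 20, layer_height = 1)
  de <- printfid:::extrusion_for_width(2.5, 10, p)
  tp <- parse_gcode(c("M83", "G92 X5.03 Y10.03",
                      sprintf("G1 X15.03 Y10.03 E%.8f", de)), p)
  G <- render_layer(tp, fr, "model")
  analytic <- 10 * 2.5 + pi * 1.25^2
  expect_equal(sum(G$mask) / fr$scale^2, analytic, tolerance = 0.03)
})

test_that("out-of-frame toolpaths raise a placement error naming the segment", {
  fr <- frame_spec(20, 20, 5)
  tp <- parse_gcode(c("M83", "G1 X30 Y5 E1"))
  expect_error(render_layer(tp, fr), class = "printfid_placement")
  expect_error(render_layer(tp, fr), "segment 1")
})

test_that("design infill is exact on trivial regions", {
  fr <- frame_spec(20, 10, 10)
  full <- layer_image(matrix(TRUE, fr$ny, fr$nx), fr)
  region <- rbind(c(2, 2), c(18, 2), c(18, 8), c(2, 8))
  expect_equal(design_infill(full, region), 100)
  empty <- layer_image(matrix(FALSE, fr$ny, fr$nx), fr)
  expect_equal(design_infill(empty, region), 0)
  expect_error(design_infill(full, matrix(FALSE, fr$ny, fr$nx)),
               class = "printfid_empty_region")
})

test_that("rectilinear infill uses the extrusion-spacing pitch", {
  d <- rl20_design()
  seg <- d$path$segments
  # infill verticals span exactly the 22 mm infill region (shell sides are longer)
  vert <- seg[seg$extruding & seg$x1 == seg$x2 &
              abs(abs(seg$y2 - seg$y1) - 22) < 1e-6, ]
  xs <- sort(unique(round(vert$x1, 6)))
  p_expected <- printfid:::extrusion_spacing(1.5, d$path$params) / (2 * 0.2)
  expect_equal(diff(xs), rep(p_expected, length(xs) - 1), tolerance = 1e-6)
})

test_that("a fully dense rectilinear block is solid", {
  fr <- small_frame()
  expect_warning(
    d <- generate_design_path(design_spec("block", c(50, 25), "rectilinear", 1),
                              frame = fr),
    class = "printfid_density_clamped")
  G <- render_layer(d, fr)
  expect_gt(design_infill(G, d$footprint), 99)
})

test_that("zero-density block is the shell alone with one start/stop pair", {
  fr <- small_frame()
  d <- generate_design_path(design_spec("block", c(50, 25), density = 0),
                            frame = fr)
  expect_equal(d$n_runs, 1)
  expect_equal(nrow(d$start_stop), 2)
  G <- render_layer(d, fr)
  # shell band only: ~216 mm2 of 1250
  expect_equal(design_infill(G, d$footprint), 100 * 216 / 1250, tolerance = 0.05)
})

test_that("design infill is invariant under translation of the design", {
  fr <- frame_spec(80, 50, 10)
  make <- function(ox, oy) {
    gc <- c("M83", sprintf("G92 X%.1f Y%.1f", 10 + ox, 10 + oy),
            sprintf("G1 X%.1f Y%.1f E1", 30 + ox, 10 + oy),
            sprintf("G1 X%.1f Y%.1f E1", 30 + ox, 25 + oy),
            sprintf("G1 X%.1f Y%.1f E1", 10 + ox, 25 + oy),
            sprintf("G1 X%.1f Y%.1f E1", 10 + ox, 10 + oy))
    G <- render_layer(parse_gcode(gc), fr)
    fp <- rbind(c(10 + ox, 10 + oy), c(30 + ox, 10 + oy),
                c(30 + ox, 25 + oy), c(10 + ox, 25 + oy))
    design_infill(G, fp)
  }
  expect_equal(make(0, 0), make(17.3, 8.6), tolerance = 0.01)
})

test_that("honeycomb infill renders a hexagonal grid at the solved pitch", {
  fr <- small_frame()
  d <- generate_design_path(design_spec("block", c(50, 25), "honeycomb", 0.4),
                            frame = fr)
  G <- render_layer(d, fr)
  # material fraction inside the infill region tracks the analytic pitch law
  wsp <- printfid:::extrusion_spacing(1.5, d$path$params)
  FF <- 1.5 * 0.4 / wsp
  target <- 1 - (1 - FF)^3
  reg_mask <- printfid:::polygon_mask(d$region, fr)
  got <- sum(G$mask & reg_mask) / sum(reg_mask)
  expect_equal(got, target, tolerance = 0.04)
})
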