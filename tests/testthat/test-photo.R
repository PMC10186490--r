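test_that("ideal green disks are located to sub-pixel accuracy and ordered", {
  fr <- frame_spec(60, 40, 5)
  P <- layer_image(matrix(FALSE, fr$ny, fr$nx), fr, "print")
  ph <- simulate_photo(P, margin_mm = 10, seed = 3)
  mk <- find_markers(ph$scene)
  expect_identical(rownames(mk), c("TL", "TR", "BR", "BL"))
  expect_lt(max(abs(unclass(mk) - ph$ledger$markers_true)), 0.5)
})

test_that("missing or ambiguous markers raise detection errors", {
  fr <- frame_spec(60, 40, 5)
  P <- layer_image(matrix(FALSE, fr$ny, fr$nx), fr, "print")
  ph <- simulate_photo(P, margin_mm = 10, drop_marker = 2, seed = 3)
  err <- expect_error(find_markers(ph$scene), class = "printfid_marker_detection")
  expect_match(conditionMessage(err), "3")
  blank <- array(0.3, c(100, 100, 3))
  expect_error(find_markers(blank), class = "printfid_marker_detection")
})

test_that("rectifying an unwarped scene recovers the central crop", {
  fr <- frame_spec(60, 40, 5)
  d <- generate_design_path(design_spec("block", c(30, 15), density = 0),
                            frame = fr)
  G <- render_layer(d, fr)
  P <- layer_image(G$mask, fr, "print")
  ph <- simulate_photo(P, margin_mm = 10, seed = 1)
  rp <- rectify(ph$scene, frame = fr)
  expect_equal(dim(rp$gray), c(fr$ny, fr$nx))
  # interior of the rectified image matches the ideal crop almost exactly
  crop <- 0.2989 * ph$scene[, , 1] + 0.587 * ph$scene[, , 2] + 0.114 * ph$scene[, , 3]
  crop <- crop[50 + seq_len(fr$ny), 50 + seq_len(fr$nx)]
  inner <- 30:(fr$ny - 30)
  expect_lt(max(abs(rp$gray[inner, inner] - crop[inner, inner])), 0.02)
})

test_that("a known perspective warp is undone within a pixel", {
  fr <- frame_spec(60, 40, 5)
  d <- generate_design_path(design_spec("block", c(30, 15), "rectilinear", 0.4),
                            frame = fr)
  sim <- simulate_print(d, defect_spec(), fr)
  ph <- simulate_photo(sim$P, margin_mm = 10, warp = "perspective",
                       warp_mag = 0.04, seed = 11)
  rp <- rectify(ph$scene, frame = fr)
  P2 <- segment(rp)
  c1 <- colMeans(which(sim$P$mask, arr.ind = TRUE))
  c2 <- colMeans(which(P2$mask, arr.ind = TRUE))
  expect_lt(max(abs(c1 - c2)), 1)
})

test_that("a rotated marker set is deskewed", {
  fr <- frame_spec(60, 40, 5)
  # long thin bar whose axis angle is measurable by PCA
  tp <- parse_gcode(c("M83", "G92 X15 Y20", "G1 X45 Y20 E1"))
  P <- layer_image(render_layer(tp, fr, "fixed", 3)$mask, fr, "print")
  ph <- simulate_photo(P, margin_mm = 14, seed = 5)
  sc <- ph$scene
  nr <- nrow(sc); nc <- ncol(sc)
  th <- 20 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  ctr <- c(nc / 2, nr / 2)
  H <- rbind(cbind(R, ctr - R %*% ctr), c(0, 0, 1))
  rot <- sc
  for (ch in 1:3) rot[, , ch] <- printfid:::warp_image(sc[, , ch], H, nr, nc,
                                                       fill = 0.35)
  rp <- rectify(rot, frame = fr)
  P2 <- segment(rp)
  axis_angle <- function(m) {
    xy <- which(m, arr.ind = TRUE)
    v <- eigen(stats::cov(xy))$vectors[, 1]
    atan2(v[1], v[2])  # angle to the column (x) axis
  }
  a1 <- axis_angle(P$mask); a2 <- axis_angle(P2$mask)
  expect_lt(abs(a1 - a2) * 180 / pi, 0.5)
})

test_that("Otsu segmentation is exact on an ideal bimodal image", {
  fr <- frame_spec(40, 20, 5)
  truth <- matrix(FALSE, fr$ny, fr$nx)
  truth[30:70, 50:150] <- TRUE
  g <- matrix(50 / 255, fr$ny, fr$nx); g[truth] <- 200 / 255
  rp <- structure(list(gray = g, frame = fr, markers_px = NULL),
                  class = "rectified_photo")
  P <- segment(rp, exclude_radius_mm = 0, min_area = 0)
  expect_identical(P$mask, truth)
})

test_that("segmentation survives Gaussian noise with high overlap", {
  fr <- frame_spec(40, 20, 5)
  truth <- matrix(FALSE, fr$ny, fr$nx)
  truth[30:70, 50:150] <- TRUE
  set.seed(42)
  g <- matrix(50 / 255, fr$ny, fr$nx); g[truth] <- 200 / 255
  g <- matrix(pmin(1, pmax(0, g + rnorm(length(g), 0, 10 / 255))),
              fr$ny, fr$nx)
  rp <- structure(list(gray = g, frame = fr, markers_px = NULL),
                  class = "rectified_photo")
  P <- segment(rp, exclude_radius_mm = 0, min_area = 0)
  dice <- 2 * sum(P$mask & truth) / (sum(P$mask) + sum(truth))
  expect_gte(dice, 0.98)
})

test_that("segmentation is invariant to linear intensity scaling", {
  fr <- frame_spec(40, 20, 5)
  truth <- matrix(FALSE, fr$ny, fr$nx)
  truth[20:60, 40:120] <- TRUE
  set.seed(7)
  g <- matrix(0.2, fr$ny, fr$nx); g[truth] <- 0.8
  g <- g + rnorm(length(g), 0, 0.02)
  make <- function(gray) segment(structure(list(gray = gray, frame = fr,
                                                markers_px = NULL),
                                           class = "rectified_photo"),
                                 exclude_radius_mm = 0, min_area = 0)
  expect_identical(make(g)$mask, make(0.5 * g + 0.1)$mask)
})

test_that("uniform images raise a segmentation failure", {
  fr <- frame_spec(20, 10, 5)
  rp <- structure(list(gray = matrix(0.5, fr$ny, fr$nx), frame = fr,
                       markers_px = NULL), class = "rectified_photo")
  expect_error(segment(rp), class = "printfid_segmentation")
})

test_that("a defect-free simulated print matches the design area after the photo loop", {
  fr <- frame_spec(60, 40, 5)
  d <- generate_design_path(design_spec("block", c(30, 15), "rectilinear", 0.4),
                            frame = fr)
  sim <- simulate_print(d, defect_spec(), fr)
  ph <- simulate_photo(sim$P, margin_mm = 10, seed = 2)
  P2 <- segment(rectify(ph$scene, frame = fr))
  G <- render_layer(d, fr)
  expect_equal(sum(P2$mask), sum(G$mask), tolerance = 0.02 * sum(G$mask))
  dice <- 2 * sum(P2$mask & sim$P$mask) / (sum(P2$mask) + sum(sim$P$mask))
  expect_gte(dice, 0.99)
})
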