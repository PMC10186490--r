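fr3 <- frame_spec(3, 3, 1)
as_layer <- function(m, fr, role = "design") layer_image(m, fr, role)

test_that("defect maps reproduce the toy set-difference example", {
  # P occupies (row1,col1),(row1,col2); G occupies (row1,col2),(row1,col3)
  P <- matrix(FALSE, 3, 3); P[1, 1:2] <- TRUE
  G <- matrix(FALSE, 3, 3); G[1, 2:3] <- TRUE
  m <- defect_maps(as_layer(P, fr3, "print"), as_layer(G, fr3))
  expect_identical(which(m$O), which(P & !G))
  expect_identical(unname(which(m$O, arr.ind = TRUE)[1, ]), c(1L, 1L))
  expect_identical(unname(which(m$U, arr.ind = TRUE)[1, ]), c(1L, 3L))
})

test_that("edge cases: identical masks and empty design", {
  P <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  fr <- frame_spec(2, 2, 1)
  m <- defect_maps(as_layer(P, fr, "print"), as_layer(P, fr))
  expect_equal(m$area_O + m$area_U, 0)
  m2 <- defect_maps(as_layer(P, fr, "print"), as_layer(matrix(FALSE, 2, 2), fr))
  expect_identical(m2$O, P)
  expect_equal(m2$area_U, 0)
})

test_that("the OR/XOR composition equals brute-force set differences", {
  set.seed(101)
  for (rep in 1:300) {
    nr <- sample(2:32, 1); nc <- sample(2:32, 1)
    fr <- frame_spec(nc, nr, 1)
    P <- random_mask(nr, nc, runif(1, 0.1, 0.9))
    G <- random_mask(nr, nc, runif(1, 0.1, 0.9))
    m <- defect_maps(as_layer(P, fr, "print"), as_layer(G, fr))
    bf <- brute_defects(P, G)
    expect_identical(m$O, bf$O)
    expect_identical(m$U, bf$U)
    # conservation identity and exclusivity
    expect_identical(m$area_P - m$area_G, m$area_O - m$area_U)
    expect_false(any(m$O & m$U))
    expect_false(any(m$O & G))
    expect_false(any(m$U & P))
  }
})

test_that("cross-correlation registration matches the exhaustive oracle", {
  set.seed(202)
  fr <- frame_spec(40, 30, 1)
  base <- matrix(FALSE, 30, 40)
  base[8:20, 10:30] <- random_mask(13, 21, 0.6)
  for (rep in 1:10) {
    dx <- sample(-6:6, 1); dy <- sample(-6:6, 1)
    P <- as_layer(printfid:::shift_mask(base, dx, dy), fr, "print")
    G <- as_layer(base, fr)
    sh <- estimate_shift(P, G, "xcorr", max_shift = 8)
    expect_equal(c(sh$dx, sh$dy), c(dx, dy))
    expect_equal(c(sh$dx, sh$dy), brute_shift(P$mask, G$mask, 8))
  }
})

test_that("identical masks register at zero shift and empty masks error", {
  fr <- frame_spec(20, 20, 1)
  m <- random_mask(20, 20, 0.5)
  sh <- estimate_shift(as_layer(m, fr, "print"), as_layer(m, fr))
  expect_equal(c(sh$dx, sh$dy), c(0, 0))
  expect_error(estimate_shift(as_layer(matrix(FALSE, 20, 20), fr, "print"),
                              as_layer(m, fr)),
               class = "printfid_registration")
})

test_that("centre-of-mass registration recovers pure translations", {
  fr <- frame_spec(40, 30, 1)
  base <- matrix(FALSE, 30, 40)
  base[10:18, 12:26] <- TRUE
  P <- as_layer(printfid:::shift_mask(base, 5, -3), fr, "print")
  sh <- estimate_shift(P, as_layer(base, fr), "com")
  expect_equal(c(sh$dx, sh$dy), c(5, -3))
})

test_that("translating the print moves the shift and leaves defect areas alone", {
  fr <- frame_spec(50, 40, 1)
  set.seed(9)
  G <- matrix(FALSE, 40, 50); G[12:28, 15:35] <- random_mask(17, 21, 0.5)
  P0 <- printfid:::shift_mask(G, 1, 0)  # a baseline defect: 1 px offset print
  s0 <- estimate_shift(as_layer(P0, fr, "print"), as_layer(G, fr))
  m0 <- defect_maps(as_layer(P0, fr, "print"),
                    apply_shift(as_layer(G, fr), s0))
  for (ab in list(c(3, 2), c(-4, 5))) {
    P <- printfid:::shift_mask(P0, ab[1], ab[2])
    s <- estimate_shift(as_layer(P, fr, "print"), as_layer(G, fr))
    expect_equal(c(s$dx - s0$dx, s$dy - s0$dy), ab)
    m <- defect_maps(as_layer(P, fr, "print"), apply_shift(as_layer(G, fr), s))
    expect_equal(m$area_O, m0$area_O)
    expect_equal(m$area_U, m0$area_U)
  }
})

test_that("measured infill counts print pixels inside the shifted footprint", {
  fr <- frame_spec(20, 10, 10)
  fp <- rbind(c(5, 2), c(15, 2), c(15, 8), c(5, 8))
  full <- matrix(TRUE, fr$ny, fr$nx)
  expect_equal(measured_infill(as_layer(full, fr, "print"), fp), 100)
  upper <- matrix(FALSE, fr$ny, fr$nx); upper[1:(fr$ny / 2), ] <- TRUE
  expect_equal(measured_infill(as_layer(upper, fr, "print"), fp), 50,
               tolerance = 0.02)
})

test_that("infill of a defect-free print equals the design infill", {
  fr <- small_frame()
  d <- rl20_design()
  sim <- simulate_print(d, defect_spec(), fr)
  G <- render_layer(d, fr)
  di <- design_infill(G, d$footprint)
  mi <- measured_infill(sim$P, d$footprint)
  expect_equal(mi, di, tolerance = 1 / di)  # within one point
})

test_that("extrusion percentages follow the |G| convention", {
  maps <- structure(list(area_G = 1000, area_O = 150, area_U = 50),
                    class = "defect_maps")
  expect_equal(extrusion_percentages(maps), c(over = 15, under = 5))
  maps$area_G <- 0
  expect_error(extrusion_percentages(maps), class = "printfid_empty_design")
})

test_that("grid indices implement sum(O)/(sum(P)+1) per tile", {
  O <- matrix(FALSE, 6, 6); P <- matrix(FALSE, 6, 6)
  O[1:3, 1:3] <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 3)
  P[1:3, 1:3] <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), 3)
  f <- grid_indices(O, P, 3)
  expect_equal(f$index[1, 1], 8 / (3 + 1))
  expect_equal(f$index[2, 2], 0)           # empty grid
  O2 <- matrix(FALSE, 3, 3); O2[1:5] <- TRUE
  f2 <- grid_indices(O2, matrix(FALSE, 3, 3), 3)
  expect_equal(f2$index[1, 1], 5)          # the +1 guards empty print grids
  expect_error(grid_indices(O, P, 0), class = "printfid_bad_grid")
})

test_that("grid indices match a straightforward double-loop reference", {
  set.seed(33)
  O <- random_mask(25, 31, 0.2); P <- random_mask(25, 31, 0.5)
  g <- 9
  f <- grid_indices(O, P, g)
  for (gr in seq_len(nrow(f$index))) for (gc in seq_len(ncol(f$index))) {
    rows <- ((gr - 1) * g + 1):min(gr * g, 25)
    cols <- ((gc - 1) * g + 1):min(gc * g, 31)
    expect_equal(f$index[gr, gc],
                 sum(O[rows, cols]) / (sum(P[rows, cols]) + 1))
  }
})

test_that("percentile normalization clips extremes and anchors the minimum", {
  I <- c(rep(1, 99), 10)   # one extreme value 10x the bulk
  out <- normalize_indices(I)
  q99 <- unname(quantile(I, 0.99))
  expect_equal(attr(out, "q99"), q99)
  expect_equal(out[100], 1)               # above q99 -> 1
  expect_equal(out[1], 0)                 # minimum -> 0
  I2 <- c(0, 2, 5, 5, 3)
  out2 <- normalize_indices(I2)
  q <- unname(quantile(I2, 0.99))
  expect_equal(as.numeric(out2[2]), (2 - 0) / (q - 0))
  expect_warning(z <- normalize_indices(rep(2, 10)),
                 class = "printfid_constant_field")
  expect_true(all(z == 0))
})

test_that("assess on a defect-free fixture reports near-zero defects", {
  fr <- small_frame()
  d <- rl20_design()
  sim <- simulate_print(d, defect_spec(), fr)
  rep <- assess(sim$P, d, fr)
  expect_lt(rep$over_pct, 1)
  expect_lt(rep$under_pct, 1)
  expect_equal(c(rep$shift$dx, rep$shift$dy), c(0, 0))
  expect_equal(unname(rep$areas_px["P"] - rep$areas_px["G"]),
               unname(rep$areas_px["O"] - rep$areas_px["U"]))
  s <- summary(rep)
  expect_true(is.data.frame(s) && nrow(s) == 5)
})

test_that("uniform thinning yields spatially uniform under-extrusion", {
  fr <- small_frame()
  d <- rl20_design()
  sim <- simulate_print(d, defect_spec(thinning_mm = 0.2), fr)
  rep <- assess(sim$P, d, fr)
  expect_gt(rep$under_pct, 0)
  # coefficient of variation of per-grid under fractions over the design area
  U <- rep$maps$U
  sU <- printfid:::tile_sums(U, 9)
  sG <- printfid:::tile_sums(rep$G$mask, 9)
  frac <- sU[sG > 40] / sG[sG > 40]
  expect_lt(sd(frac) / mean(frac), 1)
})

test_that("stage labels switch between fresh and baked wording", {
  fr <- frame_spec(40, 25, 5)
  d <- generate_design_path(design_spec("block", c(20, 10), density = 0),
                            frame = fr)
  sim <- simulate_print(d, defect_spec(swell_mm = 0.3), fr)
  rep <- assess(sim$P, d, fr, stage = "baked")
  expect_match(unname(rep$labels["over"]), "expansion")
  expect_match(unname(rep$labels["under"]), "incompletion")
  expect_output(print(rep), "expansion from design")
})
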