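#' Defect specification for simulated prints
#'
#' Parameterizes the defect taxonomy observed on printed cookie layers:
#' global die-swell (wider beads everywhere), uniform under-extrusion
#' (thinner beads), over-extrusion blobs at start/stop points, ooze filaments
#' along the travel spans between a stop and the next start, and a global
#' misposition shift (relaxation/shrink).
#'
#' @param swell_mm global half-width increase (mm).
#' @param thinning_mm global half-width decrease (mm); mutually exclusive with
#'   swell.
#' @param blob_radius_mm radius of start/stop over-extrusion blobs (mm).
#' @param blob_sites which ledger sites get blobs: "stop", "start", "all", or
#'   an integer count sampled from the stop points.
#' @param ooze_width_mm width of ooze bands along stop-to-start travel (mm).
#' @param n_ooze number of travel spans oozing (`Inf` = all).
#' @param shift_mm global misposition c(dx, dy) in mm (frame axes: +x right,
#'   +y up).
#' @param seed RNG seed for site sampling.
#' @return an object of class `defect_spec`.
#' @export
defect_spec <- function(swell_mm = 0, thinning_mm = 0, blob_radius_mm = 0,
                        blob_sites = "stop", ooze_width_mm = 0, n_ooze = Inf,
                        shift_mm = c(0, 0), seed = 1) {
  if (swell_mm < 0 || thinning_mm < 0 || blob_radius_mm < 0 || ooze_width_mm < 0)
    pf_stop("bad_defects", "defect magnitudes must be non-negative")
  if (swell_mm > 0 && thinning_mm > 0)
    pf_stop("bad_defects", "swell and thinning cannot both be positive")
  structure(list(swell_mm = swell_mm, thinning_mm = thinning_mm,
                 blob_radius_mm = blob_radius_mm, blob_sites = blob_sites,
                 ooze_width_mm = ooze_width_mm, n_ooze = n_ooze,
                 shift_mm = rep_len(shift_mm, 2), seed = seed),
            class = "defect_spec")
}

# Euclidean dilation/erosion of a logical mask by r pixels, via EBImage's
# distance transform (exact disk structuring element).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(!mask)))))
  d <= r + 1e-9
}
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask)))))
  d > r + 1e-9
}

#' Simulate a printed layer with injected defects
#'
#' Builds the segmented-print mask P from the rendered design G by applying
#' the defect spec in mask space: morphological half-width change for
#' swell/thinning, disks stamped at start/stop sites, ooze bands along the
#' travel polylines between a stop and the next start, then an integer-pixel
#' misposition shift. Working in mask space makes the ground-truth ledger
#' exact: the ledger's O/U masks satisfy O = P \ G and U = G \ P by
#' construction (on the unshifted raster).
#'
#' @param design a `design_path` from [generate_design_path()].
#' @param defects a [defect_spec()].
#' @param frame a [frame_spec()].
#' @param line_width rendered line width (mm).
#' @return an object of class `sim_print`: list with `P` (`layer_image`,
#'   shifted), `G` (`layer_image`), and `ledger` (exact O/U masks, expected
#'   over/under percentages, defect site coordinates in mm and px, shift in
#'   px, seed).
#' @export
simulate_print <- function(design, defects = defect_spec(),
                           frame = frame_spec(), line_width = 1.5) {
  stopifnot(inherits(design, "design_path"), inherits(defects, "defect_spec"))
  G <- render_layer(design, frame, "fixed", line_width)
  s <- frame$scale
  mask <- G$mask
  set.seed(defects$seed)

  if (defects$swell_mm > 0) mask <- dilate_mask(mask, defects$swell_mm * s)
  if (defects$thinning_mm > 0) mask <- erode_mask(mask, defects$thinning_mm * s)

  blob_xy <- NULL
  if (defects$blob_radius_mm > 0) {
    ss <- design$start_stop
    sites <- if (is.numeric(defects$blob_sites)) {
      stops <- ss[ss$kind == "stop", , drop = FALSE]
      stops[sample(nrow(stops), min(nrow(stops), defects$blob_sites)), , drop = FALSE]
    } else switch(defects$blob_sites,
      all = ss,
      start = ss[ss$kind == "start", , drop = FALSE],
      stop = ss[ss$kind == "stop", , drop = FALSE])
    if (nrow(sites)) {
      blob_xy <- sites[, c("x", "y")]
      disks <- data.frame(x1 = sites$x, y1 = sites$y, x2 = sites$x, y2 = sites$y,
                          w = 2 * defects$blob_radius_mm)
      mask <- draw_segments(mask, disks, frame)
    }
  }

  ooze_xy <- NULL
  if (defects$ooze_width_mm > 0) {
    seg <- design$path$segments
    travel <- which(!seg$extruding & seg$de_raw == 0 &
                    (seg$x1 != seg$x2 | seg$y1 != seg$y2))
    # keep travel spans that connect two extrusion runs
    travel <- travel[travel > 1 & travel < nrow(seg)]
    if (length(travel) && is.finite(defects$n_ooze) &&
        defects$n_ooze < length(travel))
      travel <- sort(sample(travel, defects$n_ooze))
    if (length(travel)) {
      bands <- data.frame(x1 = seg$x1[travel], y1 = seg$y1[travel],
                          x2 = seg$x2[travel], y2 = seg$y2[travel],
                          w = defects$ooze_width_mm)
      ooze_xy <- data.frame(x = (bands$x1 + bands$x2) / 2,
                            y = (bands$y1 + bands$y2) / 2)
      mask <- draw_segments(mask, bands, frame)
    }
  }

  O <- mask & !G$mask
  U <- G$mask & !mask
  shift_px <- round(defects$shift_mm * s)   # frame mm axes: y up
  shift_raster <- c(dx = shift_px[1], dy = -shift_px[2])
  P <- shift_mask(mask, shift_raster["dx"], shift_raster["dy"])

  ledger <- list(
    O = O, U = U,
    expected_over_pct = 100 * sum(O) / sum(G$mask),
    expected_under_pct = 100 * sum(U) / sum(G$mask),
    blob_sites_mm = blob_xy, ooze_sites_mm = ooze_xy,
    shift_px = shift_raster, defects = defects, seed = defects$seed)
  structure(list(P = layer_image(P, frame, "print"), G = G, ledger = ledger),
            class = "sim_print")
}

#' @export
print.sim_print <- function(x, ...) {
  cat(sprintf("Simulated print: over %.2f%%, under %.2f%% (ledger), shift (%d, %d) px\n",
              x$ledger$expected_over_pct, x$ledger$expected_under_pct,
              x$ledger$shift_px["dx"], x$ledger$shift_px["dy"]))
  invisible(x)
}

#' Simulate a photographed scene of a printed layer
#'
#' Renders the print mask as a top-view color photograph: bright dough on a
#' darker plate, four green fiducial disks at the frame corners, an optional
#' projective warp (known homography, recorded in the ledger) and Gaussian
#' pixel noise. Deterministic for a given seed.
#'
#' @param P a `layer_image` (print).
#' @param margin_mm plate margin around the frame.
#' @param marker_radius_mm fiducial disk radius.
#' @param warp "identity" or "perspective" (random quadrilateral jitter of
#'   `warp_mag` fraction of the frame diagonal).
#' @param warp_mag perspective jitter magnitude.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param drop_marker optional marker index (1-4) to omit, for failure-path
#'   tests.
#' @param seed RNG seed.
#' @param object_level,background_level scene intensities.
#' @return an object of class `sim_photo`: list with `scene` (array
#'   rows x cols x 3) and `ledger` (true marker centres in scene px, the
#'   homography applied, margin, frame).
#' @export
simulate_photo <- function(P, margin_mm = 15, marker_radius_mm = 4,
                           warp = c("identity", "perspective"),
                           warp_mag = 0.03, noise_sd = 0, drop_marker = NULL,
                           seed = 1, object_level = 0.85,
                           background_level = 0.35) {
  stopifnot(inherits(P, "layer_image"))
  warp <- match.arg(warp)
  fr <- P$frame; s <- fr$scale; m <- margin_mm
  nr <- round((fr$height_mm + 2 * m) * s); nc <- round((fr$width_mm + 2 * m) * s)
  set.seed(seed)

  gray <- matrix(background_level, nr, nc)
  r0 <- round(m * s); c0 <- round(m * s)
  obj <- P$mask
  gray[r0 + seq_len(fr$ny), c0 + seq_len(fr$nx)][obj] <- object_level
  scene <- array(rep(gray, 3), c(nr, nc, 3))

  # frame-corner positions in scene px (x = col, y = row): TL, TR, BR, BL
  corners <- rbind(c(c0 + 0.5, r0 + 0.5),
                   c(c0 + fr$nx - 0.5, r0 + 0.5),
                   c(c0 + fr$nx - 0.5, r0 + fr$ny - 0.5),
                   c(c0 + 0.5, r0 + fr$ny - 0.5))
  marker_rgb <- c(0.20, 0.80, 0.25)
  rad <- marker_radius_mm * s
  keep <- setdiff(1:4, drop_marker)
  for (i in keep) {
    cc <- corners[i, ]
    rows <- max(1, floor(cc[2] - rad)):min(nr, ceiling(cc[2] + rad))
    cols <- max(1, floor(cc[1] - rad)):min(nc, ceiling(cc[1] + rad))
    d2 <- outer((rows - cc[2])^2, (cols - cc[1])^2, "+")
    for (ch in 1:3) {
      blk <- scene[rows, cols, ch]
      blk[d2 <= rad^2] <- marker_rgb[ch]
      scene[rows, cols, ch] <- blk
    }
  }

  H <- diag(3)
  markers_true <- corners
  if (warp == "perspective") {
    diag_px <- sqrt(nr^2 + nc^2)
    src <- rbind(c(1, 1), c(nc, 1), c(nc, nr), c(1, nr))
    dst <- src + matrix(stats::runif(8, -warp_mag, warp_mag) * diag_px, 4, 2)
    H <- homography_from_points(src, dst)
    for (ch in 1:3)
      scene[, , ch] <- warp_image(scene[, , ch], H, nr, nc,
                                  fill = background_level)
    markers_true <- apply_homography(H, corners)
  }
  if (noise_sd > 0) {
    scene <- scene + stats::rnorm(length(scene), 0, noise_sd)
    scene[scene < 0] <- 0; scene[scene > 1] <- 1
  }
  structure(list(scene = scene,
                 ledger = list(markers_true = markers_true[keep, , drop = FALSE],
                               homography = H, margin_mm = m, frame = fr,
                               seed = seed)),
            class = "sim_photo")
}

#' Simulate click-survey responses
#'
#' Generates a survey table over a set of evaluated images with a configured
#' inverse association between marks and ratings. Click counts per respondent
#' rise with the image's defect load (3 plus a binomial draw); click positions
#' concentrate near the supplied defect sites with uniform background clicks.
#' Per-image mean ratings are built from the standardized expected mark
#' totals plus a deterministic orthogonal appeal component scaled so the
#' image-level Pearson correlation between total marks and mean rating equals
#' `target_r` analytically; respondent-level rating noise averages out.
#'
#' @param defect_sites list (one element per image) of data frames with click
#'   attractor coordinates `x`, `y` in image px; empty data frames mean a
#'   defect-free image (uniform clicks).
#' @param image_size c(width, height) of the evaluated images in px.
#' @param n_respondents respondents completing the survey.
#' @param target_r target marks/rating Pearson correlation (negative).
#' @param rating_centre,rating_spread location/scale of per-image mean ratings.
#' @param rating_noise_sd respondent-level rating noise.
#' @param click_jitter_sd click scatter around a defect site (px).
#' @param p_near probability a click targets a defect site rather than
#'   background.
#' @param seed RNG seed.
#' @return long-format response data frame (`participant`, `image`, `rating`,
#'   `x`, `y`) with attribute `targets` (list with `target_r`, per-image
#'   expected marks and mean ratings).
#' @export
simulate_survey <- function(defect_sites, image_size = c(500, 310),
                            n_respondents = 100, target_r = -0.86,
                            rating_centre = 60, rating_spread = 12,
                            rating_noise_sd = 8, click_jitter_sd = 6,
                            p_near = 0.8, seed = 1) {
  n_img <- length(defect_sites)
  if (n_img < 1L) pf_stop("bad_input", "need at least one image ledger")
  set.seed(seed)
  loads <- vapply(defect_sites, function(d) if (is.null(d)) 0 else nrow(d), numeric(1))
  span <- diff(range(loads))
  p_click <- if (span > 0) 0.9 * (loads - min(loads)) / span else rep(0.5, n_img)
  exp_marks <- n_respondents * (3 + 7 * p_click)

  if (stats::sd(exp_marks) > 0 && n_img >= 3) {
    sz <- as.numeric(scale(exp_marks))
    tvec <- (-1)^seq_len(n_img)                     # deterministic appeal pattern
    tvec <- tvec - mean(tvec) - sz * sum(tvec * sz) / sum(sz * sz)
    if (sum(tvec^2) > 0) tvec <- tvec / stats::sd(tvec) else tvec <- rep(0, n_img)
    cshare <- sqrt(max(0, 1 / target_r^2 - 1))
    mu <- rating_centre + rating_spread * (sign(target_r) * sz + cshare * tvec) /
      sqrt(1 + cshare^2)
  } else {
    mu <- rep(rating_centre, n_img)
  }

  rows <- vector("list", n_img * n_respondents)
  k <- 0L
  for (i in seq_len(n_img)) {
    sites <- defect_sites[[i]]
    has_sites <- !is.null(sites) && nrow(sites) > 0
    for (p in seq_len(n_respondents)) {
      nclk <- 3L + stats::rbinom(1L, 7L, p_click[i])
      near <- has_sites & (stats::runif(nclk) < p_near)
      x <- y <- numeric(nclk)
      if (any(near)) {
        j <- sample.int(nrow(sites), sum(near), replace = TRUE)
        x[near] <- sites$x[j] + stats::rnorm(sum(near), 0, click_jitter_sd)
        y[near] <- sites$y[j] + stats::rnorm(sum(near), 0, click_jitter_sd)
      }
      x[!near] <- stats::runif(sum(!near), 0, image_size[1])
      y[!near] <- stats::runif(sum(!near), 0, image_size[2])
      x <- pmin(pmax(x, 0), image_size[1])
      y <- pmin(pmax(y, 0), image_size[2])
      rating <- round(min(100, max(0, mu[i] + stats::rnorm(1, 0, rating_noise_sd))))
      k <- k + 1L
      rows[[k]] <- data.frame(participant = sprintf("p%03d", p),
                              image = sprintf("img%02d", i),
                              rating = rating, x = x, y = y)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "targets") <- list(target_r = target_r, expected_marks = exp_marks,
                               expected_mean_rating = mu, loads = loads)
  out
}
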