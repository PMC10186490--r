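# Shared fixtures built in code. Small frames keep the raster work light;
# the block designs use 10 px/mm (1 px = 0.1 mm) so sub-millimetre defects
# stay resolvable.

small_frame <- function() frame_spec(80, 50, 10)

rl20_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_design_path(design_spec("block", c(50, 25),
                                                 "rectilinear", 0.2),
                                     frame = small_frame())
    cache
  }
})

deer_design <- local({
  cache <- NULL
  function(frame = frame_spec(80, 60, 10)) {
    if (is.null(cache))
      cache <<- generate_design_path(design_spec("outline"), frame = frame)
    cache
  }
})

# Random logical mask with a given fill probability.
random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Brute-force per-pixel set differences, the oracle for the bitwise defect
# logic: loops over pixels, no vectorized set operations.
brute_defects <- function(P, G) {
  O <- U <- matrix(FALSE, nrow(P), ncol(P))
  for (r in seq_len(nrow(P))) for (c in seq_len(ncol(P))) {
    if (P[r, c] && !G[r, c]) O[r, c] <- TRUE
    if (G[r, c] && !P[r, c]) U[r, c] <- TRUE
  }
  list(O = O, U = U)
}

# Exhaustive-search registration oracle on small masks.
brute_shift <- function(P, G, max_shift) {
  best <- -Inf; best_s <- c(0L, 0L)
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    sc <- sum(P & printfid:::shift_mask(G, dx, dy))
    if (sc > best || (sc == best && sum(abs(c(dx, dy))) < sum(abs(best_s)))) {
      best <- sc; best_s <- c(dx, dy)
    }
  }
  best_s
}

# Independent width oracle: solve the volume balance numerically instead of
# using the closed form.
oracle_width <- function(de, X, D, H) {
  vol <- pi * D^2 * de / 4
  f <- function(W) (W * H - H^2 + pi * H^2 / 4) * X - vol
  stats::uniroot(f, c(H, H + 1e6), tol = 1e-12)$root
}

stadium_area <- function(W, H) W * H - H^2 + pi * H^2 / 4
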