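#' Validate click-survey responses
#'
#' Screens one row per click (long format: `participant`, `image`, `rating`,
#' `x`, `y`) against the survey protocol: a rating between 0 and 100, between
#' 3 and 10 clicks per participant-image pair, and clicks inside the displayed
#' image. Wide tables with x1, y1, ..., x10, y10 columns are reshaped first.
#'
#' @param rows data frame of responses (long or wide).
#' @param image_size c(width, height) of the displayed image in px, used for
#'   the bounds check; `NULL` skips it.
#' @param min_clicks,max_clicks click count limits per response.
#' @return list with `valid` (long data frame of accepted clicks) and
#'   `rejected` (data frame of participant-image pairs with a `reason` code:
#'   "min-clicks", "max-clicks", "rating-range" or "out-of-bounds").
#' @export
validate_responses <- function(rows, image_size = NULL,
                               min_clicks = 3, max_clicks = 10) {
  rows <- as.data.frame(rows)
  if (!all(c("participant", "image", "rating") %in% names(rows)))
    pf_stop("bad_table", "responses need participant, image and rating columns")
  if (!all(c("x", "y") %in% names(rows))) rows <- survey_wide_to_long(rows)

  key <- paste(rows$participant, rows$image, sep = "\r")
  reasons <- character(0); rej_keys <- character(0)
  keep <- rep(TRUE, nrow(rows))
  for (k in unique(key)) {
    idx <- which(key == k)
    rating <- rows$rating[idx[1]]
    n <- length(idx)
    reason <- NULL
    if (!is.finite(rating) || rating < 0 || rating > 100) reason <- "rating-range"
    else if (n < min_clicks) reason <- "min-clicks"
    else if (n > max_clicks) reason <- "max-clicks"
    else if (!is.null(image_size) &&
             any(rows$x[idx] < 0 | rows$x[idx] > image_size[1] |
                 rows$y[idx] < 0 | rows$y[idx] > image_size[2]))
      reason <- "out-of-bounds"
    if (!is.null(reason)) {
      keep[idx] <- FALSE
      reasons <- c(reasons, reason); rej_keys <- c(rej_keys, k)
    }
  }
  rejected <- if (length(rej_keys)) {
    parts <- do.call(rbind, strsplit(rej_keys, "\r", fixed = TRUE))
    data.frame(participant = parts[, 1], image = parts[, 2], reason = reasons)
  } else data.frame(participant = character(0), image = character(0),
                    reason = character(0))
  list(valid = rows[keep, , drop = FALSE], rejected = rejected)
}

survey_wide_to_long <- function(rows) {
  xcols <- grep("^x[0-9]+$", names(rows), value = TRUE)
  if (!length(xcols))
    pf_stop("bad_table", "no click columns found (need x/y or x1,y1,...)")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    xs <- unlist(rows[i, xcols]); ys <- unlist(rows[i, sub("^x", "y", xcols)])
    ok <- !is.na(xs) & !is.na(ys)
    if (!any(ok)) return(NULL)
    data.frame(participant = rows$participant[i], image = rows$image[i],
               rating = rows$rating[i], x = as.numeric(xs[ok]),
               y = as.numeric(ys[ok]))
  })
  do.call(rbind, out)
}

#' Click-frequency heatmap for one image
#'
#' Clicks are counted within g x g pixel grids and the counts are passed
#' through a Gaussian filter to smooth the frequency distribution across
#' neighbouring grids, matching how the survey marks are visualized.
#'
#' @param responses validated long-format clicks for a single image.
#' @param image_size c(width, height) of the clicked image in px.
#' @param g grid size in px.
#' @param sigma Gaussian sigma in grid units.
#' @return an object of class `click_heatmap`: list with `counts` (grid
#'   matrix, rows = y), `smoothed`, `g`, `n_respondents`, `n_clicks`.
#' @export
click_heatmap <- function(responses, image_size, g = 9, sigma = 1.5) {
  responses <- as.data.frame(responses)
  if (!nrow(responses)) pf_stop("empty_survey", "no responses for this image")
  if (length(unique(responses$image)) > 1L)
    pf_stop("bad_table", "click_heatmap expects responses for a single image")
  ngx <- ceiling(image_size[1] / g); ngy <- ceiling(image_size[2] / g)
  gx <- pmin(ngx, pmax(1L, ceiling(responses$x / g)))
  gy <- pmin(ngy, pmax(1L, ceiling(responses$y / g)))
  counts <- matrix(0, ngy, ngx)
  for (i in seq_along(gx)) counts[gy[i], gx[i]] <- counts[gy[i], gx[i]] + 1
  structure(list(counts = counts, smoothed = gauss_smooth(counts, sigma),
                 g = g, image = responses$image[1],
                 n_respondents = length(unique(responses$participant)),
                 n_clicks = nrow(responses)),
            class = "click_heatmap")
}

#' @export
print.click_heatmap <- function(x, ...) {
  cat(sprintf("Click heatmap (image %s): %d clicks from %d respondents on %d x %d grids\n",
              x$image, x$n_clicks, x$n_respondents, ncol(x$counts), nrow(x$counts)))
  invisible(x)
}

#' Rating-versus-marks association
#'
#' Pearson correlation between the number of inaccurate positions marked and
#' the accuracy rating. Per image (default): total clicks versus mean rating
#' across the images; per response: click count versus rating across
#' individual participant-image records.
#'
#' @param responses validated long-format clicks across several images.
#' @param per "image" or "response".
#' @return Pearson r.
#' @export
rating_mark_correlation <- function(responses, per = c("image", "response")) {
  per <- match.arg(per)
  responses <- as.data.frame(responses)
  if (per == "image") {
    marks <- tapply(responses$x, responses$image, length)
    rate <- tapply(responses$rating, responses$image, mean)
    if (length(marks) < 3L)
      pf_stop("correlation", "need at least 3 images")
  } else {
    key <- interaction(responses$participant, responses$image, drop = TRUE)
    marks <- tapply(responses$x, key, length)
    rate <- tapply(responses$rating, key, function(v) v[1])
  }
  if (stats::sd(marks) == 0 || stats::sd(rate) == 0)
    pf_stop("correlation", "zero variance in marks or ratings")
  unname(stats::cor(as.numeric(marks), as.numeric(rate)))
}

#' Read a survey CSV
#'
#' @param path CSV file, long (`participant,image,rating,x,y`) or wide
#'   (`participant,image,rating,x1,y1,...`).
#' @return long-format data frame.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) pf_stop("io", "survey file not found: %s", path)
  rows <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(rows))) rows <- survey_wide_to_long(rows)
  rows
}
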