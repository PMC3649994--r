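#' Detect aggregates in a background-subtracted frame
#'
#' Multiscale difference-of-Gaussians (DoG) blob detection over the expected
#' diameter range, with intensity-weighted subpixel centroid refinement.
#' A candidate is kept when its DoG response exceeds `threshold_snr` times a
#' robust (MAD-based) estimate of the response noise at that scale; nearby
#' candidates are merged by non-maximum suppression across space and scale.
#'
#' @param frame Background-subtracted 2D frame (matrix).
#' @param pixel_size Pixel size, um/px.
#' @param min_diameter_um,max_diameter_um Expected diameter range of the
#'   rendered spots (object FWHM convolved with the PSF), um.
#' @param threshold_snr Detection threshold in robust noise units.
#' @param noise_sd Robust estimate of the pixel noise sd used for the
#'   photometric peak cut; estimated from the frame when `NULL`.
#' @param frame_index Frame number stored in the output (1-based).
#' @return A data frame (class `netrack_detections`) with columns
#'   `frame`, `y_um`, `x_um`, `peak`, `diameter_um`, `scale_sigma_px`,
#'   sorted by descending peak intensity. Empty on blank frames.
#' @examples
#' f <- matrix(0, 48, 48)
#' detect_aggregates(f, 0.107)   # no spots -> zero rows
#' @export
detect_aggregates <- function(frame, pixel_size,
                              min_diameter_um = 0.5, max_diameter_um = 2.0,
                              threshold_snr = 3, noise_sd = NULL,
                              frame_index = 1L) {
  if (!is.matrix(frame)) stop_invalid("'frame' must be a matrix")
  check_number(pixel_size, "pixel_size", positive = TRUE)
  if (min_diameter_um >= max_diameter_um)
    stop_invalid("'min_diameter_um' must be below 'max_diameter_um'")
  H <- nrow(frame); W <- ncol(frame)
  empty <- data.frame(frame = integer(), y_um = numeric(), x_um = numeric(),
                      peak = numeric(), diameter_um = numeric(),
                      scale_sigma_px = numeric(), class = character())
  class(empty) <- c("netrack_detections", "data.frame")
  if (all(frame <= 0)) return(empty)
  if (is.null(noise_sd)) {
    # background-subtracted frames are clipped at 0, so estimate the noise
    # scale from the positive residuals of the blank majority of pixels
    pos <- frame[frame > 0]
    noise_sd <- if (length(pos) > 20) 1.8 * stats::median(pos) else stats::sd(frame)
  }

  sig_min <- (min_diameter_um / 2.355) / pixel_size
  sig_max <- (max_diameter_um / 2.355) / pixel_size
  k <- 2^(1 / 3)
  n_scales <- max(2L, ceiling(log(sig_max / sig_min) / log(k)) + 1L)
  sigmas <- sig_min * k^(0:(n_scales - 1))

  blurs <- lapply(c(sigmas, sigmas[n_scales] * k), function(s)
    gaussian_blur(frame, s))
  cands <- list()
  for (i in seq_len(n_scales)) {
    dog <- blurs[[i]] - blurs[[i + 1L]]
    noise <- stats::mad(dog)
    if (noise <= 0) noise <- stats::sd(dog)
    if (noise <= 0) next
    thr <- 2.5 * noise   # permissive candidate cut; photometric cut follows
    # 3x3 local maxima above threshold (border-1 excluded)
    core <- dog[2:(H - 1), 2:(W - 1)]
    is_max <- core >= thr
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      is_max <- is_max & (core >= dog[2:(H - 1) + dy, 2:(W - 1) + dx])
    }
    hits <- which(is_max, arr.ind = TRUE)
    if (nrow(hits)) {
      cands[[length(cands) + 1L]] <- data.frame(
        y = hits[, 1] + 1L, x = hits[, 2] + 1L,
        sigma = sigmas[i],
        response = dog[cbind(hits[, 1] + 1L, hits[, 2] + 1L)])
    }
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(-cand$response), , drop = FALSE]

  # non-maximum suppression across space and scale
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- cand[keep, , drop = FALSE]
      lim <- pmax(prev$sigma, cand$sigma[i]) * 1.7
      d2 <- (prev$y - cand$y[i])^2 + (prev$x - cand$x[i])^2
      if (any(d2 < lim^2)) ok <- FALSE
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]

  # photometric cut: local peak must clear the pixel-noise floor
  peak33 <- vapply(seq_len(nrow(cand)), function(i) {
    yy <- max(1, cand$y[i] - 1):min(H, cand$y[i] + 1)
    xx <- max(1, cand$x[i] - 1):min(W, cand$x[i] + 1)
    max(frame[yy, xx])
  }, numeric(1))
  cand <- cand[peak33 >= threshold_snr * noise_sd, , drop = FALSE]
  peak33 <- peak33[peak33 >= threshold_snr * noise_sd]
  if (!nrow(cand)) return(empty)

  # subpixel centroid: intensity-weighted mean in a scale-matched window,
  # iterated twice to re-centre
  yc <- cand$y; xc <- cand$x
  ys <- as.numeric(yc); xs <- as.numeric(xc)
  for (i in seq_along(yc)) {
    r <- max(2L, ceiling(1.5 * cand$sigma[i]))
    cy <- ys[i]; cx <- xs[i]
    for (it in 1:2) {
      yy <- max(1, round(cy) - r):min(H, round(cy) + r)
      xx <- max(1, round(cx) - r):min(W, round(cx) + r)
      wts <- frame[yy, xx, drop = FALSE]
      if (sum(wts) <= 0) break
      cy <- sum(outer(yy, rep(1, length(xx))) * wts) / sum(wts)
      cx <- sum(outer(rep(1, length(yy)), xx) * wts) / sum(wts)
    }
    ys[i] <- cy; xs[i] <- cx
  }
  peak <- peak33

  out <- data.frame(
    frame = as.integer(frame_index),
    y_um = (ys - 1) * pixel_size,
    x_um = (xs - 1) * pixel_size,
    peak = peak,
    diameter_um = NA_real_,
    scale_sigma_px = cand$sigma)
  out <- out[order(-out$peak), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(nrow(out)))
    out$diameter_um[i] <- measure_diameter(frame, out[i, ], pixel_size)
  out$class <- classify_aggregate(out$diameter_um)
  class(out) <- c("netrack_detections", "data.frame")
  out
}

#' Measure an aggregate diameter as the FWHM-equivalent circle
#'
#' The diameter is the equivalent-circle diameter of the connected pixel
#' region around the peak whose (background-subtracted) intensity exceeds
#' half the peak value. For a Gaussian spot of sd sigma px this recovers the
#' FWHM, 2.355 sigma, and is invariant to intensity rescaling.
#'
#' @param frame Background-subtracted frame (matrix).
#' @param detection One detection row (needs `y_um`, `x_um`).
#' @param pixel_size Pixel size, um/px.
#' @return Diameter in um. Regions touching the image border are still
#'   measured but flagged with attribute `border = TRUE`.
#' @export
measure_diameter <- function(frame, detection, pixel_size) {
  H <- nrow(frame); W <- ncol(frame)
  py <- round(detection$y_um / pixel_size) + 1L
  px <- round(detection$x_um / pixel_size) + 1L
  if (py < 1L || py > H || px < 1L || px > W)
    stop_invalid("detection centroid outside frame", "netrack_invalid_input")
  # climb to the local peak in a 3x3 neighbourhood (centroid may sit between
  # pixels)
  for (it in 1:3) {
    yy <- max(1, py - 1):min(H, py + 1)
    xx <- max(1, px - 1):min(W, px + 1)
    sub <- frame[yy, xx, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ny <- yy[ij[1]]; nx <- xx[ij[2]]
    if (ny == py && nx == px) break
    py <- ny; px <- nx
  }
  half <- frame[py, px] / 2
  if (half <= 0) return(structure(pixel_size, border = FALSE))
  # BFS over 4-connected pixels >= half-max
  visited <- matrix(FALSE, H, W)
  queue <- matrix(c(py, px), ncol = 2)
  visited[py, px] <- TRUE
  area <- 0L
  border <- FALSE
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    area <- area + 1L
    y <- cur[1]; x <- cur[2]
    if (y == 1L || y == H || x == 1L || x == W) border <- TRUE
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ny <- y + d[1]; nx <- x + d[2]
      if (ny < 1L || ny > H || nx < 1L || nx > W) next
      if (visited[ny, nx]) next
      if (frame[ny, nx] >= half) {
        visited[ny, nx] <- TRUE
        queue <- rbind(queue, c(ny, nx))
      }
    }
  }
  structure(2 * sqrt(area / pi) * pixel_size, border = border)
}

#' Classify an aggregate as focus or patch by diameter
#'
#' Aggregates smaller than the threshold diameter are foci (single
#' chromosome-end attachments); aggregates at or above it are patches
#' (multiple attachments). The boundary value itself is assigned to
#' the patch class (half-open convention: focus d < t, patch d >= t).
#'
#' @param diameter_um Aggregate diameter, um (> 0).
#' @param threshold_um Class boundary, um (default 1.1).
#' @return `"focus"` or `"patch"` (vectorised).
#' @examples
#' classify_aggregate(c(1.0, 1.1, 1.2))
#' @export
classify_aggregate <- function(diameter_um, threshold_um = 1.1) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop_invalid("'diameter_um' must be positive", "netrack_invalid_input")
  check_number(threshold_um, "threshold_um", positive = TRUE)
  ifelse(diameter_um < threshold_um, "focus", "patch")
}

#' Detect aggregates in every frame of a movie
#'
#' Convenience wrapper running [subtract_background()] (optional) and
#' [detect_aggregates()] per frame.
#'
#' @param m A 2D [movie()] (typically registered).
#' @param subtract Logical; subtract the smooth background first.
#' @param ... Passed to [detect_aggregates()].
#' @return A `netrack_detections` data frame over all frames.
#' @export
detect_movie <- function(m, subtract = TRUE, ...) {
  stopifnot(inherits(m, "netrack_movie"))
  if (has_z(m)) stop_invalid("detect_movie expects a projected 2D movie")
  nf <- dim(m$data)[1]
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- m$data[f, , ]
    noise_sd <- stats::mad(fr)   # robust: puncta occupy few pixels
    if (subtract) fr <- subtract_background(fr, pixel_size = m$pixel_size)
    res[[f]] <- detect_aggregates(fr, m$pixel_size, frame_index = f,
                                  noise_sd = noise_sd, ...)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("netrack_detections", "data.frame")
  out
}
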