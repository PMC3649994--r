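#' Per-interval projected speeds of one track
#'
#' Speeds are Euclidean displacements of the projected (y, x) positions per
#' elapsed time, in nm/s. By default only consecutive-frame intervals are
#' used; intervals spanning closed gaps divide the displacement by the
#' elapsed time and are included only when `include_gaps = TRUE`.
#'
#' @param track Data frame with `frame`, `y_um`, `x_um` for one track.
#' @param frame_interval_s Frame interval, s.
#' @param include_gaps Include gap-spanning intervals.
#' @return Numeric vector of speeds (nm/s); empty for single-point tracks.
#' @examples
#' tr <- data.frame(frame = 1:3, y_um = c(0, 0.2, 0.4), x_um = 0)
#' step_speeds(tr, 5)   # 200 nm per 5 s = 40 nm/s
#' @export
step_speeds <- function(track, frame_interval_s = 5, include_gaps = FALSE) {
  check_number(frame_interval_s, "frame_interval_s", positive = TRUE)
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L) return(numeric(0))
  dfr <- diff(track$frame)
  dy <- diff(track$y_um) * 1000   # um -> nm
  dx <- diff(track$x_um) * 1000
  sp <- sqrt(dy^2 + dx^2) / (dfr * frame_interval_s)
  if (!include_gaps) sp <- sp[dfr == 1L]
  sp
}

#' Pooled projected-speed distribution with threshold fractions
#'
#' Pools interval speeds across tracks and reports the fraction of
#' intervals strictly above 40 nm/s and at or above 160 nm/s (the
#' conventions used when contrasting motor-driven and residual movement:
#' "above 40 nm/s" is read strictly, "160 nm/s and higher" inclusively),
#' plus a normalised histogram.
#'
#' @param tracks A `netrack_tracks` object, or a data frame with `track_id`,
#'   `frame`, `y_um`, `x_um`.
#' @param frame_interval_s Frame interval, s (taken from the object when
#'   available).
#' @param thresholds Two thresholds, nm/s: the first applied strictly (>),
#'   the second inclusively (>=).
#' @param bin_width Histogram bin width, nm/s.
#' @param include_gaps Include gap-spanning intervals in the pool.
#' @param per_track Pool per-track mean speeds instead of per-interval
#'   speeds (whether published threshold fractions are per interval or per
#'   track is ambiguous; per interval is the default).
#' @return A list of class `netrack_speed_distribution`: `speeds`,
#'   `fraction_above` (named, e.g. `">40"`, `">=160"`), `bin_edges`,
#'   `density` (fractions summing to 1), `n_intervals`.
#' @export
speed_distribution <- function(tracks, frame_interval_s = NULL,
                               thresholds = c(40, 160), bin_width = 20,
                               include_gaps = FALSE, per_track = FALSE) {
  df <- if (inherits(tracks, "netrack_tracks")) tracks$tracks else tracks
  if (is.null(frame_interval_s))
    frame_interval_s <- if (inherits(tracks, "netrack_tracks"))
      tracks$params$frame_interval_s else 5
  if (!nrow(df)) stop_invalid("no detections to compute speeds from",
                              "netrack_invalid_input")
  by_track <- lapply(split(df, df$track_id), step_speeds,
                     frame_interval_s = frame_interval_s,
                     include_gaps = include_gaps)
  speeds <- if (per_track)
    unlist(lapply(by_track, function(s) if (length(s)) mean(s) else NULL),
           use.names = FALSE)
  else unlist(by_track, use.names = FALSE)
  if (!length(speeds)) stop_invalid("no linked intervals (all tracks length 1)",
                                    "netrack_invalid_input")
  frac <- c(mean(speeds > thresholds[1]), mean(speeds >= thresholds[2]))
  names(frac) <- c(paste0(">", thresholds[1]), paste0(">=", thresholds[2]))
  edges <- seq(0, max(speeds) + bin_width, by = bin_width)
  dens <- as.vector(table(cut(speeds, edges, right = FALSE,
                              include.lowest = TRUE))) / length(speeds)
  structure(list(speeds = speeds, fraction_above = frac, bin_edges = edges,
                 density = dens, n_intervals = length(speeds),
                 thresholds = thresholds),
            class = "netrack_speed_distribution")
}

#' @export
print.netrack_speed_distribution <- function(x, ...) {
  cat(sprintf("Projected speeds: %d intervals, median %.1f nm/s\n",
              x$n_intervals, stats::median(x$speeds)))
  cat(sprintf("  fraction %s nm/s: %.1f%%; fraction %s nm/s: %.2f%%\n",
              names(x$fraction_above)[1], 100 * x$fraction_above[1],
              names(x$fraction_above)[2], 100 * x$fraction_above[2]))
  invisible(x)
}

#' Arc coverage of a track on the nuclear circumference
#'
#' Expresses a track's total projected path length as the angle (degrees) it
#' would subtend if travelled along the nuclear circumference: `arc =
#' path / (2 pi R) * 360`. Larger angles therefore indicate larger distance
#' travelled; the measure is additive under track concatenation and
#' invariant to rigid rotation about the nucleus centre.
#'
#' @param track Data frame with `frame`, `y_um`, `x_um` for one track.
#' @param geometry A [nucleus_geometry()].
#' @return Arc in degrees (0 for stationary or single-point tracks).
#' @examples
#' g <- nucleus_geometry(radius = 2)
#' tr <- data.frame(frame = 1:2, y_um = c(0, 2 * pi * 2), x_um = 0)
#' arc_coverage(tr, g)   # one full circumference = 360 degrees
#' @export
arc_coverage <- function(track, geometry) {
  if (!inherits(geometry, "netrack_nucleus_geometry") || geometry$radius <= 0)
    stop_invalid("valid nucleus geometry with positive radius required",
                 "netrack_invalid_geometry")
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L) return(0)
  path <- sum(sqrt(diff(track$y_um)^2 + diff(track$x_um)^2))
  path / (2 * pi * geometry$radius) * 360
}

#' Kinematics summary for one nucleus
#'
#' Per-track arc coverage plus pooled projected-speed threshold fractions
#' for all tracks passing the minimum-length filter.
#'
#' @param tracks A `netrack_tracks` object or track data frame.
#' @param geometry A [nucleus_geometry()].
#' @param min_track_length Minimum detections per track (free parameter;
#'   default 10 frames).
#' @param frame_interval_s Frame interval, s.
#' @return A list of class `netrack_kinematics_summary`: `arcs` (named by
#'   track), `mean_arc`, `max_arc`, `min_arc`, `fraction_above`, `n_tracks`,
#'   `n_intervals`, `empty`.
#' @export
summarize_nucleus <- function(tracks, geometry, min_track_length = 10L,
                              frame_interval_s = NULL) {
  df <- if (inherits(tracks, "netrack_tracks")) tracks$tracks else tracks
  if (is.null(frame_interval_s))
    frame_interval_s <- if (inherits(tracks, "netrack_tracks"))
      tracks$params$frame_interval_s else 5
  keep <- names(which(table(df$track_id) >= min_track_length))
  df <- df[df$track_id %in% keep, , drop = FALSE]
  if (!nrow(df)) {
    out <- list(arcs = numeric(0), mean_arc = NA_real_, max_arc = NA_real_,
                min_arc = NA_real_, fraction_above = c(`>40` = NA_real_,
                                                       `>=160` = NA_real_),
                n_tracks = 0L, n_intervals = 0L, empty = TRUE)
    class(out) <- "netrack_kinematics_summary"
    return(out)
  }
  arcs <- vapply(split(df, df$track_id), arc_coverage, numeric(1),
                 geometry = geometry)
  sd_ <- speed_distribution(df, frame_interval_s = frame_interval_s)
  out <- list(arcs = arcs, mean_arc = mean(arcs), max_arc = max(arcs),
              min_arc = min(arcs), fraction_above = sd_$fraction_above,
              n_tracks = length(arcs), n_intervals = sd_$n_intervals,
              empty = FALSE)
  class(out) <- "netrack_kinematics_summary"
  out
}

#' @export
print.netrack_kinematics_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Kinematics summary: no qualifying tracks\n")
    return(invisible(x))
  }
  cat(sprintf("Kinematics: %d tracks, mean arc %.0f deg (min %.0f, max %.0f)\n",
              x$n_tracks, x$mean_arc, x$min_arc, x$max_arc))
  cat(sprintf("  %s nm/s: %.1f%%; %s nm/s: %.2f%%\n",
              names(x$fraction_above)[1], 100 * x$fraction_above[1],
              names(x$fraction_above)[2], 100 * x$fraction_above[2]))
  invisible(x)
}

# Bresenham line rasterisation between two pixel coordinates (1-based).
raster_segment <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- if (y0 < y1) 1L else -1L
  sx <- if (x0 < x1) 1L else -1L
  err <- dx - dy
  pts <- matrix(NA_integer_, dx + dy + 1L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(y0, x0)
    if (y0 == y1 && x0 == x1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; y0 <- y0 + sy }
  }
  pts[seq_len(i), , drop = FALSE]
}

#' Track overlap fraction on the pixel grid
#'
#' Rasterises each track as a 1-px-wide polyline and reports the fraction
#' of visited pixels that are visited by at least two different tracks —
#' the quantity behind the qualitative contrast between extensively
#' overlapping wild-type-like tracks and mutually avoiding mutant-like ones.
#'
#' @param tracks A `netrack_tracks` object or track data frame.
#' @param pixel_size Raster pixel size, um/px.
#' @return Overlap fraction in `[0, 1]` (0 with a warning for < 2 tracks).
#' @export
track_overlap_map <- function(tracks, pixel_size = 0.107) {
  df <- if (inherits(tracks, "netrack_tracks")) tracks$tracks else tracks
  check_number(pixel_size, "pixel_size", positive = TRUE)
  ids <- unique(df$track_id)
  if (length(ids) < 2L) {
    warning("fewer than 2 tracks; overlap undefined, returning 0")
    return(0)
  }
  visited <- list()
  for (id in ids) {
    tr <- df[df$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    py <- round(tr$y_um / pixel_size)
    px <- round(tr$x_um / pixel_size)
    pix <- character(0)
    if (nrow(tr) == 1L) {
      pix <- paste(py, px)
    } else {
      for (i in seq_len(nrow(tr) - 1L)) {
        seg <- raster_segment(py[i], px[i], py[i + 1L], px[i + 1L])
        pix <- c(pix, paste(seg[, 1], seg[, 2]))
      }
    }
    visited[[as.character(id)]] <- unique(pix)
  }
  all_pix <- unlist(visited, use.names = FALSE)
  tab <- table(all_pix)
  sum(tab >= 2L) / length(tab)
}
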