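#' Calibrated movie container
#'
#' @param data Numeric array, either `frames x z x y x x` (TZYX) or
#'   `frames x y x x` (TYX). Intensities must be non-negative.
#' @param pixel_size Pixel size, um/px.
#' @param z_spacing Section spacing, um (ignored for 2D movies).
#' @param frame_interval Frame interval, s.
#' @return An object of class `netrack_movie`.
#' @export
movie <- function(data, pixel_size, z_spacing = 1, frame_interval = 5) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop_invalid("'data' must be a TZYX (4D) or TYX (3D) array")
  if (any(data < 0)) stop_invalid("movie intensities must be >= 0")
  check_number(pixel_size, "pixel_size", positive = TRUE)
  check_number(z_spacing, "z_spacing", positive = TRUE)
  check_number(frame_interval, "frame_interval", positive = TRUE)
  structure(list(data = data, pixel_size = pixel_size, z_spacing = z_spacing,
                 frame_interval = frame_interval),
            class = "netrack_movie")
}

#' @export
print.netrack_movie <- function(x, ...) {
  d <- dim(x$data)
  if (length(d) == 4L)
    cat(sprintf("Movie: %d frames x %d z x %d x %d px (TZYX), %g um/px, %g um z, %g s/frame\n",
                d[1], d[2], d[3], d[4], x$pixel_size, x$z_spacing, x$frame_interval))
  else
    cat(sprintf("Movie: %d frames x %d x %d px (TYX), %g um/px, %g s/frame\n",
                d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

n_frames <- function(m) dim(m$data)[1]
has_z <- function(m) length(dim(m$data)) == 4L

# Render one 3D Gaussian spot into a [z, y, x] frame array (in place-style).
# Positions in um relative to the image origin (top-left, z of first plane).
render_spot <- function(arr, y0, x0, z0, photons, sxy, sz,
                        pixel_size, z_spacing, z0_um) {
  dz <- dim(arr)[1]; H <- dim(arr)[2]; W <- dim(arr)[3]
  yc <- y0 / pixel_size + 1    # 1-based fractional pixel index
  xc <- x0 / pixel_size + 1
  ry <- ceiling(4 * sxy / pixel_size)
  ys <- max(1, floor(yc - ry)):min(H, ceiling(yc + ry))
  xs <- max(1, floor(xc - ry)):min(W, ceiling(xc + ry))
  if (!length(ys) || !length(xs)) return(arr)
  zs_um <- z0_um + (seq_len(dz) - 1) * z_spacing
  gy <- stats::dnorm((ys - 1) * pixel_size, y0, sxy) * pixel_size
  gx <- stats::dnorm((xs - 1) * pixel_size, x0, sxy) * pixel_size
  gz <- stats::dnorm(zs_um, z0, sz) * z_spacing
  patch <- outer(gy, gx) * photons
  for (k in seq_len(dz)) {
    if (gz[k] < 1e-12) next
    arr[k, ys, xs] <- arr[k, ys, xs] + patch * gz[k]
  }
  arr
}

#' Simulate a nuclear-envelope movie with ground truth
#'
#' Renders seeded synthetic SUN-1::GFP-like time-lapse z-stacks. Each nucleus
#' occupies its own square tile; aggregates move on the envelope sphere under
#' `model` (see [simulate_motion_track()]), fuse when their 3D separation
#' drops below the model's fusion radius (volumes add), and split at the
#' model's split rate (volume halves). Aggregates are rendered as 3D
#' Gaussians whose photon count is proportional to aggregate volume and
#' decays with the bleaching half-life; Poisson shot noise and a Gaussian
#' read-noise floor are added on top of a constant camera background.
#'
#' @param config A [sim_config()].
#' @param model A [motion_model()], or a preset name accepted by
#'   [motion_preset()] (a preset also supplies the aggregate census).
#' @return A list of class `netrack_simulation` with elements `movie`
#'   (a [movie()]) and `truth` (ground truth: `tracks`, `events`, `nuclei`,
#'   `drift_px` data frames).
#' @examples
#' sim <- simulate_ne_movie(sim_config(frames = 10, seed = 2), "wt")
#' sim$movie
#' head(sim$truth$tracks)
#' @export
simulate_ne_movie <- function(config, model = "wt") {
  stopifnot(inherits(config, "netrack_sim_config"))
  if (is.character(model)) {
    preset <- motion_preset(model)
    model <- preset$model
    config$aggregates_per_nucleus <- preset$n_aggregates
    config$aggregate_diameter <- preset$diameter_range_um
  }
  stopifnot(inherits(model, "netrack_motion_model"))

  R <- config$nucleus_radius
  margin <- 0.8
  tile_um <- 2 * (R + margin)
  tile_px <- ceiling(tile_um / config$pixel_size)
  ncol_t <- ceiling(sqrt(config$n_nuclei))
  nrow_t <- ceiling(config$n_nuclei / ncol_t)
  H <- nrow_t * tile_px
  W <- ncol_t * tile_px
  nz <- config$z_planes
  # z planes straddle the nucleus centre (z = 0)
  z0_um <- -((nz - 1) / 2) * config$z_spacing
  sz_psf <- 2 * config$psf_sigma   # axial PSF ~2x lateral

  nuc_seeds <- derive_seeds(config$seed, config$n_nuclei)
  frames <- config$frames
  dt <- config$frame_interval

  data <- array(0, c(frames, nz, H, W))
  all_tracks <- list()
  all_events <- list()
  nuclei <- data.frame(nucleus_id = integer(), center_y_um = numeric(),
                       center_x_um = numeric(), radius_um = numeric())
  next_track_id <- 1L
  clipped <- FALSE

  for (nuc in seq_len(config$n_nuclei)) {
    set.seed(nuc_seeds[nuc])
    tr_row <- (nuc - 1) %/% ncol_t
    tr_col <- (nuc - 1) %% ncol_t
    cy <- (tr_row + 0.5) * tile_px * config$pixel_size
    cx <- (tr_col + 0.5) * tile_px * config$pixel_size
    nuclei <- rbind(nuclei, data.frame(
      nucleus_id = nuc, center_y_um = cy, center_x_um = cx, radius_um = R))

    n_agg <- if (config$aggregates_per_nucleus[1] == config$aggregates_per_nucleus[2])
      config$aggregates_per_nucleus[1]
    else sample(config$aggregates_per_nucleus[1]:config$aggregates_per_nucleus[2], 1L)

    # initial placement: keep aggregates apart so t = 0 is not mid-fusion
    min_sep <- max(1.5 * model$fusion_radius, 0.8)
    agg <- list()
    for (a in seq_len(n_agg)) {
      for (try in 1:300) {
        p <- random_unit_vector()
        ok <- all(vapply(agg, function(o)
          sqrt(sum((o$st$p * R - p * R)^2)) >= min_sep, logical(1)))
        if (ok || try == 300) break
      }
      d <- stats::runif(1, config$aggregate_diameter[1], config$aggregate_diameter[2])
      agg[[a]] <- list(id = next_track_id, st = new_motion_state(model, p),
                       diameter = d, active = TRUE)
      next_track_id <- next_track_id + 1L
    }

    rec <- list()   # per-frame observation rows
    events <- list()
    for (f in seq_len(frames)) {
      t_now <- (f - 1) * dt
      if (f > 1) {
        for (a in seq_along(agg)) if (agg[[a]]$active)
          agg[[a]]$st <- step_motion(agg[[a]]$st, model, R, dt)
        # fusion: any active pair closer than fusion_radius in 3D
        if (model$fusion_radius > 0) {
          repeat {
            act <- which(vapply(agg, `[[`, logical(1), "active"))
            fused <- FALSE
            if (length(act) >= 2) {
              for (i in act) {
                for (j in act) {
                  if (j <= i) next
                  dist3 <- sqrt(sum((agg[[i]]$st$p * R - agg[[j]]$st$p * R)^2))
                  if (dist3 < model$fusion_radius) {
                    big <- if (agg[[i]]$diameter >= agg[[j]]$diameter) i else j
                    sml <- if (big == i) j else i
                    agg[[big]]$diameter <-
                      (agg[[big]]$diameter^3 + agg[[sml]]$diameter^3)^(1 / 3)
                    agg[[sml]]$active <- FALSE
                    events[[length(events) + 1L]] <- data.frame(
                      nucleus_id = nuc, frame = f, type = "fusion",
                      track_id = agg[[sml]]$id, partner_id = agg[[big]]$id)
                    fused <- TRUE
                    break
                  }
                }
                if (fused) break
              }
            }
            if (!fused) break
          }
        }
        # splitting
        if (model$split_rate > 0) {
          act <- which(vapply(agg, `[[`, logical(1), "active"))
          for (i in act) {
            if (stats::runif(1) < 1 - exp(-model$split_rate * dt)) {
              d_new <- agg[[i]]$diameter / 2^(1 / 3)
              agg[[i]]$diameter <- d_new
              b <- tangent_basis(agg[[i]]$st$p)
              off <- 1.2 * max(model$fusion_radius, 0.2) / R
              phi <- stats::runif(1, 0, 2 * pi)
              p_new <- agg[[i]]$st$p + off * (cos(phi) * b$e1 + sin(phi) * b$e2)
              p_new <- p_new / sqrt(sum(p_new^2))
              child <- list(id = next_track_id,
                            st = new_motion_state(model, p_new),
                            diameter = d_new, active = TRUE)
              next_track_id <- next_track_id + 1L
              agg[[length(agg) + 1L]] <- child
              events[[length(events) + 1L]] <- data.frame(
                nucleus_id = nuc, frame = f, type = "split",
                track_id = child$id, partner_id = agg[[i]]$id)
            }
          }
        }
      }
      for (a in seq_along(agg)) {
        if (!agg[[a]]$active) next
        pos <- agg[[a]]$st$p * R
        rec[[length(rec) + 1L]] <- data.frame(
          nucleus_id = nuc, track_id = agg[[a]]$id, frame = f, t_s = t_now,
          y_um = cy + pos[1], x_um = cx + pos[2], z_um = pos[3],
          diameter_um = agg[[a]]$diameter,
          state = agg[[a]]$st$state)
      }
    }
    if (length(rec)) all_tracks[[nuc]] <- do.call(rbind, rec)
    if (length(events)) all_events[[nuc]] <- do.call(rbind, events)
  }

  empty_tracks <- data.frame(nucleus_id = integer(), track_id = integer(),
                             frame = integer(), t_s = numeric(),
                             y_um = numeric(), x_um = numeric(),
                             z_um = numeric(), diameter_um = numeric(),
                             state = character())
  tracks <- if (length(all_tracks)) do.call(rbind, all_tracks) else empty_tracks
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(nucleus_id = integer(), frame = integer(), type = character(),
               track_id = integer(), partner_id = integer())
  rownames(events) <- NULL

  # stage drift (random walk), applied to the rendered positions only:
  # ground-truth coordinates stay in the drift-free frame-0 system
  set.seed(derive_seeds(config$seed + 104729, 1L))
  drift <- matrix(0, frames, 2)
  if (config$drift_sigma_px > 0 && frames > 1) {
    steps <- matrix(stats::rnorm(2 * (frames - 1), 0, config$drift_sigma_px),
                    frames - 1, 2)
    drift[-1, ] <- apply(steps, 2, cumsum)
  }

  # render + noise (one RNG stream for the whole rendering pass)
  fov_y <- (H - 1) * config$pixel_size
  fov_x <- (W - 1) * config$pixel_size
  for (f in seq_len(frames)) {
    fr <- array(0, c(nz, H, W))
    rows <- tracks[tracks$frame == f, , drop = FALSE]
    if (nrow(rows)) {
      for (r in seq_len(nrow(rows))) {
        d <- rows$diameter_um[r]
        bleach <- if (is.finite(config$bleach_halflife))
          2^(-rows$t_s[r] / config$bleach_halflife) else 1
        photons <- config$photon_budget * d^3 * bleach
        s_obj <- d / 2.355
        sxy <- sqrt(config$psf_sigma^2 + s_obj^2)
        szz <- sqrt(sz_psf^2 + s_obj^2)
        ry <- rows$y_um[r] + drift[f, 1] * config$pixel_size
        rx <- rows$x_um[r] + drift[f, 2] * config$pixel_size
        if (ry < 0 || ry > fov_y || rx < 0 || rx > fov_x) clipped <- TRUE
        fr <- render_spot(fr, ry, rx, rows$z_um[r], photons, sxy, szz,
                          config$pixel_size, config$z_spacing, z0_um)
      }
    }
    data[f, , , ] <- fr
  }
  if (isTRUE(config$shot_noise %||% TRUE)) {
    noisy <- stats::rpois(length(data), data + config$noise_floor) +
      stats::rnorm(length(data), 0, config$read_noise)
    data <- array(pmax(noisy, 0), dim(data))
  } else {
    data <- data + config$noise_floor
  }
  if (clipped)
    warning("one or more aggregates rendered outside the field of view were clipped")

  structure(list(
    movie = movie(data, config$pixel_size, config$z_spacing, config$frame_interval),
    truth = list(tracks = tracks, events = events, nuclei = nuclei,
                 drift_px = data.frame(frame = seq_len(frames),
                                       dy_px = drift[, 1], dx_px = drift[, 2])),
    config = config, model = model
  ), class = "netrack_simulation")
}

# --- I/O --------------------------------------------------------------------

#' Write a movie as multi-page TIFF with a JSON calibration sidecar
#'
#' Pages are ordered frame-major (all z of frame 1, then frame 2, ...).
#' Intensities are stored as 32-bit floats scaled into `[0, 1]`; the scale
#' factor is recorded in the sidecar so [read_movie()] restores counts.
#'
#' @param m A [movie()].
#' @param path Output TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @return Invisibly, the sidecar path.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "netrack_movie"))
  d <- dim(m$data)
  scale <- max(m$data, 1e-12)
  pages <- list()
  if (has_z(m)) {
    for (f in seq_len(d[1])) for (k in seq_len(d[2]))
      pages[[length(pages) + 1L]] <- m$data[f, k, , ] / scale
  } else {
    for (f in seq_len(d[1])) pages[[length(pages) + 1L]] <- m$data[f, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    pixel_size_um = m$pixel_size, z_spacing_um = m$z_spacing,
    frame_interval_s = m$frame_interval,
    n_frames = d[1], n_z = if (has_z(m)) d[2] else 1L,
    intensity_scale = scale, axes = if (has_z(m)) "TZYX" else "TYX"
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path with an adjacent `.json` calibration sidecar.
#' @return A [movie()].
#' @export
read_movie <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_invalid("calibration sidecar not found")
  cal <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  nf <- cal$n_frames; nz <- cal$n_z
  if (length(pages) != nf * nz) stop_invalid("page count does not match sidecar")
  if (nz > 1) {
    data <- array(0, c(nf, nz, H, W))
    i <- 1L
    for (f in seq_len(nf)) for (k in seq_len(nz)) {
      data[f, k, , ] <- pages[[i]] * cal$intensity_scale
      i <- i + 1L
    }
  } else {
    data <- array(0, c(nf, H, W))
    for (f in seq_len(nf)) data[f, , ] <- pages[[f]] * cal$intensity_scale
  }
  movie(data, cal$pixel_size_um, cal$z_spacing_um, cal$frame_interval_s)
}

#' Write ground-truth tracks to CSV
#'
#' Columns: `nucleus_id, track_id, frame, t_s, y_um, x_um, z_um, diameter_um, state`.
#'
#' @param truth The `truth` element of a [simulate_ne_movie()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracks = file.path(dir, "ground_truth_tracks.csv"),
             events = file.path(dir, "ground_truth_events.csv"),
             nuclei = file.path(dir, "nuclei.csv"))
  utils::write.csv(truth$tracks, paths["tracks"], row.names = FALSE)
  utils::write.csv(truth$events, paths["events"], row.names = FALSE)
  utils::write.csv(truth$nuclei, paths["nuclei"], row.names = FALSE)
  invisible(paths)
}
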