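#' Run the tracking pipeline on a movie
#'
#' Chains the analysis stages: maximum-intensity projection (for z-stacks),
#' drift registration, background subtraction, per-frame detection,
#' per-nucleus track linking with fusion/split annotation, and kinematics
#' summaries. Detections are assigned to the nucleus whose centre is
#' nearest, within `radius + assign_margin_um`.
#'
#' @param x A `netrack_simulation` (nuclei geometry taken from ground
#'   truth) or a [movie()] with `nuclei` supplied.
#' @param nuclei Data frame with `nucleus_id`, `center_y_um`,
#'   `center_x_um`, `radius_um` (required for plain movies).
#' @param register Estimate and undo per-frame drift. Off by default:
#'   drift registration needs static image structure (other nuclei, gut
#'   autofluorescence) to lock onto, which real fields provide but
#'   single-nucleus synthetic scenes of moving puncta do not — there the
#'   correlation peak chases the aggregates themselves.
#' @param min_diameter_um,max_diameter_um Detection scale range, um.
#' @param threshold_snr Detection threshold (robust noise units).
#' @param max_disp_um,max_gap_frames Linking gate and gap tolerance.
#' @param merge_dist_um Fusion/split association distance, um.
#' @param min_track_length Minimum track length for kinematics.
#' @param assign_margin_um Extra margin for nucleus assignment, um.
#' @return A list of class `netrack_analysis`: `detections`, `shifts`,
#'   `per_nucleus` (per nucleus: `tracks`, `summary`, `geometry`),
#'   `pooled_tracks` (track table with nucleus-disambiguated ids), and
#'   `params`.
#' @export
track_movie <- function(x, nuclei = NULL, register = FALSE,
                        min_diameter_um = 0.5, max_diameter_um = 2.2,
                        threshold_snr = 3,
                        max_disp_um = 1.5, max_gap_frames = 2L,
                        merge_dist_um = 0.5, min_track_length = 10L,
                        assign_margin_um = 0.5) {
  if (inherits(x, "netrack_simulation")) {
    m <- x$movie
    if (is.null(nuclei)) nuclei <- x$truth$nuclei
  } else m <- x
  stopifnot(inherits(m, "netrack_movie"))
  if (is.null(nuclei))
    stop_invalid("nucleus geometry table required for plain movies")

  if (has_z(m)) m <- max_project(m)
  shifts <- NULL
  if (register && n_frames(m) >= 2L) {
    reg <- register_frames(m)
    m <- reg$movie
    shifts <- reg$shifts
  }
  det <- detect_movie(m, subtract = TRUE,
                      min_diameter_um = min_diameter_um,
                      max_diameter_um = max_diameter_um,
                      threshold_snr = threshold_snr)

  # assign detections to nuclei
  det$nucleus_id <- NA_integer_
  if (nrow(det)) {
    d2 <- outer(det$y_um, nuclei$center_y_um, "-")^2 +
          outer(det$x_um, nuclei$center_x_um, "-")^2
    nearest <- max.col(-d2)
    lim <- (nuclei$radius_um[nearest] + assign_margin_um)^2
    ok <- d2[cbind(seq_len(nrow(det)), nearest)] <= lim
    det$nucleus_id[ok] <- nuclei$nucleus_id[nearest[ok]]
  }

  per_nucleus <- list()
  pooled <- list()
  offset <- 0L
  for (i in seq_len(nrow(nuclei))) {
    nid <- nuclei$nucleus_id[i]
    dn <- det[!is.na(det$nucleus_id) & det$nucleus_id == nid, , drop = FALSE]
    trk <- link_tracks(dn, max_disp_um = max_disp_um,
                       max_gap_frames = max_gap_frames,
                       frame_interval_s = m$frame_interval)
    trk <- annotate_fusion_splitting(trk, merge_dist_um = merge_dist_um)
    geom <- nucleus_geometry(nuclei$center_y_um[i], nuclei$center_x_um[i],
                             nuclei$radius_um[i])
    summ <- summarize_nucleus(trk, geom, min_track_length = min_track_length)
    per_nucleus[[as.character(nid)]] <-
      list(tracks = trk, summary = summ, geometry = geom)
    if (nrow(trk$tracks)) {
      p <- trk$tracks
      p$track_id <- p$track_id + offset
      offset <- offset + max(trk$tracks$track_id)
      p$nucleus_id <- nid
      pooled[[length(pooled) + 1L]] <- p
    }
  }
  pooled <- if (length(pooled)) do.call(rbind, pooled) else det[0, ]
  structure(list(detections = det, shifts = shifts,
                 per_nucleus = per_nucleus, pooled_tracks = pooled,
                 frame_interval_s = m$frame_interval,
                 params = list(min_diameter_um = min_diameter_um,
                               max_diameter_um = max_diameter_um,
                               threshold_snr = threshold_snr,
                               max_disp_um = max_disp_um,
                               max_gap_frames = max_gap_frames,
                               merge_dist_um = merge_dist_um,
                               min_track_length = min_track_length)),
            class = "netrack_analysis")
}

#' @export
print.netrack_analysis <- function(x, ...) {
  cat(sprintf("Pipeline analysis: %d detections, %d nuclei\n",
              nrow(x$detections), length(x$per_nucleus)))
  for (nid in names(x$per_nucleus)) {
    s <- x$per_nucleus[[nid]]$summary
    if (isTRUE(s$empty)) cat(sprintf("  nucleus %s: no qualifying tracks\n", nid))
    else cat(sprintf("  nucleus %s: %d tracks, mean arc %.0f deg\n",
                     nid, s$n_tracks, s$mean_arc))
  }
  invisible(x)
}

#' Pooled genotype-level kinematics from an analysis
#'
#' Pools tracks across nuclei (tracks keep nucleus-disambiguated ids),
#' returning the pooled speed distribution and the per-track arcs measured
#' against each track's own nucleus geometry.
#'
#' @param analysis A `netrack_analysis` from [track_movie()].
#' @param min_track_length Minimum detections per track.
#' @return A list with `speed` (a `netrack_speed_distribution`), `arcs`,
#'   `mean_arc`, `n_tracks`.
#' @export
pool_kinematics <- function(analysis, min_track_length = 10L) {
  stopifnot(inherits(analysis, "netrack_analysis"))
  arcs <- numeric(0)
  speeds_pool <- list()
  for (nid in names(analysis$per_nucleus)) {
    pn <- analysis$per_nucleus[[nid]]
    df <- pn$tracks$tracks
    keep <- names(which(table(df$track_id) >= min_track_length))
    df <- df[df$track_id %in% keep, , drop = FALSE]
    if (!nrow(df)) next
    arcs <- c(arcs, vapply(split(df, df$track_id), arc_coverage, numeric(1),
                           geometry = pn$geometry))
    speeds_pool[[nid]] <- unlist(lapply(split(df, df$track_id), step_speeds,
                                        frame_interval_s = analysis$frame_interval_s),
                                 use.names = FALSE)
  }
  speeds <- unlist(speeds_pool, use.names = FALSE)
  if (!length(speeds))
    return(list(speed = NULL, arcs = arcs, mean_arc = NA_real_, n_tracks = 0L))
  frac <- c(`>40` = mean(speeds > 40), `>=160` = mean(speeds >= 160))
  list(speed = structure(list(speeds = speeds, fraction_above = frac,
                              n_intervals = length(speeds),
                              thresholds = c(40, 160)),
                         class = "netrack_speed_distribution"),
       arcs = arcs, mean_arc = mean(arcs), n_tracks = length(arcs))
}

#' Ground-truth kinematics from a simulation
#'
#' Computes the same projected-speed fractions and arcs as the pipeline,
#' but directly from the simulated (noise-free) aggregate positions — the
#' oracle against which pipeline recovery is judged.
#'
#' @param sim A `netrack_simulation`.
#' @param min_track_length Minimum frames per ground-truth track.
#' @return A list with `fraction_above`, `speeds`, `arcs`, `mean_arc`.
#' @export
ground_truth_kinematics <- function(sim, min_track_length = 10L) {
  stopifnot(inherits(sim, "netrack_simulation"))
  tr <- sim$truth$tracks
  keep <- names(which(table(tr$track_id) >= min_track_length))
  tr <- tr[tr$track_id %in% keep, , drop = FALSE]
  dtf <- sim$config$frame_interval
  speeds <- unlist(lapply(split(tr, tr$track_id), step_speeds,
                          frame_interval_s = dtf), use.names = FALSE)
  arcs <- vapply(split(tr, tr$track_id), function(t1) {
    nuc <- sim$truth$nuclei[sim$truth$nuclei$nucleus_id == t1$nucleus_id[1], ]
    arc_coverage(t1, nucleus_geometry(nuc$center_y_um, nuc$center_x_um,
                                      nuc$radius_um))
  }, numeric(1))
  list(fraction_above = c(`>40` = mean(speeds > 40),
                          `>=160` = mean(speeds >= 160)),
       speeds = speeds, arcs = arcs, mean_arc = mean(arcs))
}

# Match detections to ground-truth positions frame by frame (one-to-one,
# nearest-first within `match_radius_px`). Returns recall and precision.
detection_performance <- function(detections, truth_tracks, pixel_size,
                                  match_radius_px = 2) {
  lim <- match_radius_px * pixel_size
  tp <- 0L
  n_truth <- nrow(truth_tracks)
  n_det <- nrow(detections)
  for (f in sort(unique(truth_tracks$frame))) {
    gt <- truth_tracks[truth_tracks$frame == f, , drop = FALSE]
    de <- detections[detections$frame == f, , drop = FALSE]
    if (!nrow(de)) next
    d <- sqrt(outer(gt$y_um, de$y_um, "-")^2 + outer(gt$x_um, de$x_um, "-")^2)
    repeat {
      if (!length(d) || min(d) > lim) break
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      tp <- tp + 1L
      d <- d[-ij[1], -ij[2], drop = FALSE]
    }
  }
  list(recall = tp / n_truth, precision = tp / n_det,
       n_truth = n_truth, n_detections = n_det, true_positives = tp)
}
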