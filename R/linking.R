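# Exact linear-sum assignment (Hungarian algorithm, O(n^3) shortest
# augmenting path formulation). `cost` must be square with finite entries;
# use a large sentinel for forbidden pairings. Returns, for each row, the
# assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- Inf
  u <- numeric(n + 1)       # row potentials, index i+1 (i = 0 virtual)
  v <- numeric(n + 1)       # column potentials, index j+1 (j = 0 virtual)
  p <- integer(n + 1)       # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

# Optimal gated frame-to-frame matching between track heads and detections.
# Returns list(track_to_det, cost): for each of n tracks the matched
# detection index (NA if unmatched). Unmatched tracks/detections pay gate^2.
match_frame <- function(track_pos, det_pos, gate) {
  n <- nrow(track_pos); m <- nrow(det_pos)
  if (n == 0L && m == 0L)
    return(list(track_to_det = integer(0), cost = 0))
  BIG <- 1e9
  gate2 <- gate^2
  size <- n + m
  cost <- matrix(BIG, size, size)
  if (n > 0L && m > 0L) {
    d2 <- outer(track_pos[, 1], det_pos[, 1], "-")^2 +
          outer(track_pos[, 2], det_pos[, 2], "-")^2
    d2[d2 > gate2] <- BIG
    # deterministic tie-break: prefer lexicographically smallest (track, det)
    eps <- 1e-9 * gate2
    tie <- outer(seq_len(n), seq_len(m), function(i, j) i * (m + 1) + j)
    cost[1:n, 1:m] <- d2 + eps * tie / (n * (m + 1) + m + 1)
  }
  if (n > 0L) for (i in seq_len(n)) cost[i, m + i] <- gate2      # track miss
  if (m > 0L) for (j in seq_len(m)) cost[n + j, j] <- gate2      # new track
  if (n > 0L && m > 0L) cost[(n + 1):size, (m + 1):size] <- 0    # slack
  a <- solve_assignment(cost)
  t2d <- rep(NA_integer_, n)
  total <- 0
  for (i in seq_len(n)) {
    j <- a[i]
    if (j <= m && cost[i, j] < BIG / 2) {
      t2d[i] <- j
      total <- total + (track_pos[i, 1] - det_pos[j, 1])^2 +
                        (track_pos[i, 2] - det_pos[j, 2])^2
    } else total <- total + gate2
  }
  if (m > 0L) total <- total + gate2 * sum(!(seq_len(m) %in% t2d))
  list(track_to_det = t2d, cost = total)
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame linking by exact minimal-cost assignment (squared
#' displacement) under a hard distance gate, with gap closing: a track that
#' misses detections remains eligible for matching for up to
#' `max_gap_frames` frames before it is closed. Unmatched detections start
#' new tracks.
#'
#' The default gate of 1.5 um per 5 s interval (300 nm/s) sits comfortably
#' above the ~190 nm/s dynein-driven speed so the fast tail of the speed
#' distribution is not truncated.
#'
#' @param detections A `netrack_detections` data frame (columns `frame`,
#'   `y_um`, `x_um`, and optionally `diameter_um`, `peak`).
#' @param max_disp_um Gate distance per linking step, um.
#' @param max_gap_frames Maximum number of consecutive missed frames.
#' @param frame_interval_s Frame interval, s (stored in the output).
#' @return An object of class `netrack_tracks`: a list with `tracks` (data
#'   frame adding `track_id` and `gap` — `gap = TRUE` marks a detection
#'   whose link to the previous one spans skipped frames), and `params`.
#' @export
link_tracks <- function(detections, max_disp_um = 1.5, max_gap_frames = 2L,
                        frame_interval_s = 5) {
  check_number(max_disp_um, "max_disp_um", positive = TRUE)
  check_number(max_gap_frames, "max_gap_frames", nonneg = TRUE, integer = TRUE)
  if (!all(c("frame", "y_um", "x_um") %in% names(detections)))
    stop_invalid("detections need columns frame, y_um, x_um")
  det <- as.data.frame(detections)
  det <- det[order(det$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  det$gap <- FALSE
  if (!nrow(det)) {
    return(structure(list(tracks = det,
                          params = list(max_disp_um = max_disp_um,
                                        max_gap_frames = max_gap_frames,
                                        frame_interval_s = frame_interval_s)),
                     class = "netrack_tracks"))
  }
  frames_present <- sort(unique(det$frame))
  f_min <- min(frames_present); f_max <- max(frames_present)

  active <- data.frame(track_id = integer(), y = numeric(), x = numeric(),
                       last_frame = integer(), missed = integer())
  next_id <- 1L
  for (f in f_min:f_max) {
    rows <- which(det$frame == f)
    m <- length(rows)
    n <- nrow(active)
    t2d <- rep(NA_integer_, n)
    if (m > 0L || n > 0L) {
      t2d <- match_frame(
        cbind(active$y, active$x),
        if (m) cbind(det$y_um[rows], det$x_um[rows]) else matrix(0, 0, 2),
        max_disp_um)$track_to_det
    }
    matched_dets <- integer(0)
    if (n > 0L) {
      for (i in seq_len(n)) {
        j <- t2d[i]
        if (!is.na(j)) {
          r <- rows[j]
          det$track_id[r] <- active$track_id[i]
          det$gap[r] <- active$missed[i] > 0L
          active$y[i] <- det$y_um[r]
          active$x[i] <- det$x_um[r]
          active$last_frame[i] <- f
          active$missed[i] <- 0L
          matched_dets <- c(matched_dets, j)
        } else {
          active$missed[i] <- active$missed[i] + 1L
        }
      }
      active <- active[active$missed <= max_gap_frames, , drop = FALSE]
    }
    if (m > 0L) {
      for (j in setdiff(seq_len(m), matched_dets)) {
        r <- rows[j]
        det$track_id[r] <- next_id
        active <- rbind(active, data.frame(
          track_id = next_id, y = det$y_um[r], x = det$x_um[r],
          last_frame = f, missed = 0L))
        next_id <- next_id + 1L
      }
    }
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  structure(list(tracks = det,
                 params = list(max_disp_um = max_disp_um,
                               max_gap_frames = max_gap_frames,
                               frame_interval_s = frame_interval_s)),
            class = "netrack_tracks")
}

#' @export
print.netrack_tracks <- function(x, ...) {
  n <- length(unique(x$tracks$track_id))
  cat(sprintf("Linked tracks: %d tracks over %d detections\n",
              n, nrow(x$tracks)))
  if (!is.null(x$events) && nrow(x$events))
    cat(sprintf("  events: %d fusion, %d split\n",
                sum(x$events$type == "fusion"), sum(x$events$type == "split")))
  invisible(x)
}

#' Annotate fusion and splitting events on linked tracks
#'
#' A track that ends next to a continuing track is recorded as a fusion
#' into that track; a track that starts next to an already-running track is
#' recorded as a split from it. "Next to" means within `merge_dist_um` of
#' the partner's position on the event frame.
#'
#' @param tracks A `netrack_tracks` object from [link_tracks()].
#' @param merge_dist_um Association distance, um.
#' @param min_track_frames Tracks shorter than this are treated as noise
#'   fragments and neither emit nor receive events.
#' @param rebirth_window Frames to scan for a detection-dropout rebirth: a
#'   track end followed shortly by a new track at the same place is a
#'   dropout, not a fusion (and symmetrically for splits).
#' @return The same object with an `events` data frame added
#'   (`frame`, `type` in `{"fusion", "split"}`, `track_id`, `partner_id`).
#' @export
annotate_fusion_splitting <- function(tracks, merge_dist_um = 0.5,
                                      min_track_frames = 3L,
                                      rebirth_window = 6L) {
  stopifnot(inherits(tracks, "netrack_tracks"))
  check_number(merge_dist_um, "merge_dist_um", positive = TRUE)
  df <- tracks$tracks
  events <- list()
  if (nrow(df)) {
    len <- table(df$track_id)
    ids <- as.integer(names(len)[len >= min_track_frames])
    first_frame <- tapply(df$frame, df$track_id, min)
    last_frame <- tapply(df$frame, df$track_id, max)
    f_min <- min(df$frame); f_max <- max(df$frame)
    pos_at <- function(id, f) {
      r <- df[df$track_id == id & df$frame == f, , drop = FALSE]
      if (nrow(r)) c(r$y_um[1], r$x_um[1]) else NULL
    }
    near_birth <- function(p, f0, window, exclude) {
      # does any track (not `exclude`) start within `window` frames after
      # f0, within merge distance of p?
      for (other in ids) {
        if (other %in% exclude) next
        ff2 <- first_frame[[as.character(other)]]
        if (ff2 > f0 && ff2 <= f0 + window) {
          q <- pos_at(other, ff2)
          if (!is.null(q) && sqrt(sum((p - q)^2)) <= merge_dist_um)
            return(TRUE)
        }
      }
      FALSE
    }
    near_death <- function(p, f0, window, exclude) {
      for (other in ids) {
        if (other %in% exclude) next
        lf2 <- last_frame[[as.character(other)]]
        if (lf2 < f0 && lf2 >= f0 - window) {
          q <- pos_at(other, lf2)
          if (!is.null(q) && sqrt(sum((p - q)^2)) <= merge_dist_um)
            return(TRUE)
        }
      }
      FALSE
    }
    for (id in ids) {
      lf <- last_frame[[as.character(id)]]
      if (lf < f_max) {                     # candidate fusion: early death
        p_end <- pos_at(id, lf)
        best <- NULL; best_d <- Inf
        for (other in ids) {
          if (other == id) next
          if (last_frame[[as.character(other)]] <= lf) next  # must continue
          # partner position on the death frame or the one after
          for (fp in c(lf, lf + 1L)) {
            q <- pos_at(other, fp)
            if (is.null(q)) next
            d <- sqrt(sum((p_end - q)^2))
            if (d <= merge_dist_um && d < best_d) { best <- other; best_d <- d }
          }
        }
        if (!is.null(best) &&
            !near_birth(p_end, lf, rebirth_window, c(id, best)))
          events[[length(events) + 1L]] <- data.frame(
            frame = as.integer(lf), type = "fusion",
            track_id = id, partner_id = best)
      }
      ff <- first_frame[[as.character(id)]]
      if (ff > f_min) {                     # candidate split: late birth
        p_start <- pos_at(id, ff)
        best <- NULL; best_d <- Inf
        for (other in ids) {
          if (other == id) next
          if (first_frame[[as.character(other)]] >= ff) next  # must pre-exist
          for (fp in c(ff, ff - 1L)) {
            q <- pos_at(other, fp)
            if (is.null(q)) next
            d <- sqrt(sum((p_start - q)^2))
            if (d <= merge_dist_um && d < best_d) { best <- other; best_d <- d }
          }
        }
        if (!is.null(best) &&
            !near_death(p_start, ff, rebirth_window, c(id, best)))
          events[[length(events) + 1L]] <- data.frame(
            frame = as.integer(ff), type = "split",
            track_id = id, partner_id = best)
      }
    }
  }
  tracks$events <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(), type = character(),
               track_id = integer(), partner_id = integer())
  tracks$params$merge_dist_um <- merge_dist_um
  tracks
}

#' Write a track table to CSV
#'
#' Columns: `track_id, frame, t_s, y_um, x_um, diameter_um, gap, event`.
#'
#' @param tracks A `netrack_tracks` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "netrack_tracks"))
  df <- tracks$tracks
  df$t_s <- (df$frame - 1) * tracks$params$frame_interval_s
  df$event <- ""
  if (!is.null(tracks$events) && nrow(tracks$events)) {
    for (i in seq_len(nrow(tracks$events))) {
      ev <- tracks$events[i, ]
      sel <- df$track_id == ev$track_id & df$frame == ev$frame
      df$event[sel] <- ev$type
    }
  }
  cols <- intersect(c("track_id", "frame", "t_s", "y_um", "x_um",
                      "diameter_um", "peak", "gap", "event"), names(df))
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}
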