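#' Run a reproducible end-to-end analysis
#'
#' Executes simulate -> project/register -> detect -> track -> kinematics
#' for each configured condition, writing per-stage artifacts and a
#' manifest with content hashes. Identical configuration and seed produce
#' identical outputs.
#'
#' @param config A YAML file path or a list with elements:
#'   `seed` (root seed), `out_dir`, and `conditions` — a list of blocks
#'   with `name`, `preset` (see [motion_preset()]), and optional
#'   [sim_config()] overrides (`n_nuclei`, `frames`, ...). An optional
#'   `stages` vector (`"simulate"`, `"track"`) restricts execution.
#' @return The manifest (invisibly also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop_invalid("config needs 'out_dir'")
  if (is.null(config$conditions)) stop_invalid("config needs 'conditions'")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "track")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed, stages = stages, conditions = list())
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    name <- cond$name %||% paste0("condition", ci)
    cdir <- file.path(out_dir, name)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)

    sc_args <- cond[setdiff(names(cond), c("name", "preset"))]
    sc_args$seed <- as.integer(seed + 1000L * ci)
    cfg <- do.call(sim_config, sc_args)
    sim <- simulate_ne_movie(cfg, cond$preset %||% "wt")

    files <- character(0)
    if ("simulate" %in% stages) {
      write_movie(sim$movie, file.path(cdir, "movie.tif"))
      write_ground_truth(sim$truth, cdir)
      files <- c(files, file.path(cdir, c("movie.tif", "movie.tif.json",
                                          "ground_truth_tracks.csv",
                                          "ground_truth_events.csv",
                                          "nuclei.csv")))
    }
    summary_list <- NULL
    if ("track" %in% stages) {
      an <- track_movie(sim)
      utils::write.csv(an$detections, file.path(cdir, "detections.csv"),
                       row.names = FALSE)
      pooled <- an$pooled_tracks
      utils::write.csv(pooled, file.path(cdir, "tracks.csv"), row.names = FALSE)
      pk <- pool_kinematics(an)
      summary_list <- list(
        condition = name,
        n_tracks = pk$n_tracks,
        mean_arc_deg = pk$mean_arc,
        fraction_above_40 = if (is.null(pk$speed)) NA else
          unname(pk$speed$fraction_above[1]),
        fraction_ge_160 = if (is.null(pk$speed)) NA else
          unname(pk$speed$fraction_above[2]),
        per_nucleus = lapply(an$per_nucleus, function(pn) {
          s <- pn$summary
          if (isTRUE(s$empty)) list(note = "no qualifying tracks")
          else list(n_tracks = s$n_tracks, mean_arc = s$mean_arc,
                    max_arc = s$max_arc, min_arc = s$min_arc)
        }))
      jsonlite::write_json(summary_list, file.path(cdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, file.path(cdir, c("detections.csv", "tracks.csv",
                                          "summary.json")))
    }
    manifest$conditions[[name]] <- list(
      name = name, preset = cond$preset %||% "wt", dir = cdir,
      seed = sc_args$seed,
      files = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))),
      summary = summary_list)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render per-condition movement report panels
#'
#' For each condition in a manifest, draws the three standard movement
#' panels — track map, arc fan, and projected-speed distribution — into one
#' PNG per condition, with axes shared across conditions for comparability.
#'
#' @param manifest A manifest list from [run_pipeline()] or the path to a
#'   written `manifest.json`.
#' @param out_dir Output directory (defaults next to the manifest files).
#' @return Data frame listing the panels written (`condition`, `file`);
#'   conditions lacking tracking output are reported with a warning.
#' @export
render_report <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) {
    out_dir <- out_dir %||% dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  rows <- list()
  # shared axes: max arc across conditions
  arc_max <- 10
  speed_max <- 200
  track_data <- list()
  for (cond in manifest$conditions) {
    tf <- file.path(cond$dir, "tracks.csv")
    nf <- file.path(cond$dir, "nuclei.csv")
    if (!file.exists(tf)) {
      warning(sprintf("condition '%s': no tracking output; skipped", cond$name))
      next
    }
    tracks <- utils::read.csv(tf)
    nuclei <- if (file.exists(nf)) utils::read.csv(nf) else NULL
    track_data[[cond$name]] <- list(tracks = tracks, nuclei = nuclei,
                                    dir = cond$dir,
                                    summary = cond$summary)
    s <- cond$summary
    if (!is.null(s$per_nucleus)) {
      arcs <- unlist(lapply(s$per_nucleus, function(x) x$max_arc))
      if (length(arcs)) arc_max <- max(arc_max, arcs, na.rm = TRUE)
    }
  }
  od <- out_dir %||% "."
  for (name in names(track_data)) {
    td <- track_data[[name]]
    file <- file.path(od, paste0("report_", name, ".png"))
    grDevices::png(file, width = 1500, height = 500, res = 110)
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    tracks <- td$tracks
    # panel 1: track map
    graphics::plot(NA, xlim = range(tracks$x_um), ylim = rev(range(tracks$y_um)),
                   xlab = "x (um)", ylab = "y (um)",
                   main = paste(name, "- track map"), asp = 1)
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, ]
      graphics::lines(tr$x_um, tr$y_um,
                      col = grDevices::hcl.colors(32, "Dark 3")[id %% 32 + 1])
    }
    if (!is.null(td$nuclei))
      graphics::symbols(td$nuclei$center_x_um, td$nuclei$center_y_um,
                        circles = td$nuclei$radius_um, inches = FALSE,
                        add = TRUE, fg = "grey50")
    # panel 2: arc fan
    graphics::plot(NA, xlim = c(-1, 1), ylim = c(0, 1.05), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = paste(name, "- arc coverage"))
    arcs <- numeric(0)
    if (!is.null(td$summary$per_nucleus)) {
      # draw one arc per track using per-nucleus stored arcs when present
      pn <- td$summary$per_nucleus
      arcs <- unlist(lapply(pn, function(x) x$mean_arc))
    }
    th0 <- pi / 2
    k <- 0
    for (a in arcs) {
      if (is.null(a) || is.na(a)) next
      k <- k + 1
      r <- 1 - 0.08 * (k - 1)
      ang <- seq(th0, th0 - min(a, 360) * pi / 180, length.out = 100)
      graphics::lines(r * cos(ang), r * sin(ang), lwd = 2,
                      col = grDevices::hcl.colors(8, "Dark 3")[k %% 8 + 1])
    }
    # panel 3: speed distribution
    sp <- numeric(0)
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, ]
      sp <- c(sp, step_speeds(tr, manifest_interval(td)))
    }
    if (length(sp)) {
      h <- graphics::hist(pmin(sp, speed_max), breaks = seq(0, speed_max, 10),
                          plot = FALSE)
      graphics::plot(h$mids, 100 * h$counts / sum(h$counts), type = "l",
                     xlab = "projected speed (nm/s)", ylab = "% of intervals",
                     main = paste(name, "- speeds"), xlim = c(0, speed_max))
      graphics::abline(v = c(40, 160), lty = 2, col = "grey50")
    } else {
      graphics::plot.new()
      graphics::title(main = "no qualifying tracks")
    }
    grDevices::dev.off()
    rows[[length(rows) + 1L]] <- data.frame(condition = name, file = file)
  }
  if (!length(rows)) {
    warning("no conditions with tracking output; empty report")
    return(data.frame(condition = character(), file = character()))
  }
  do.call(rbind, rows)
}

manifest_interval <- function(td) {
  if (!is.null(td$tracks$t_s) && nrow(td$tracks) > 1) {
    dtv <- diff(sort(unique(td$tracks$t_s)))
    if (length(dtv)) return(min(dtv))
  }
  5
}
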