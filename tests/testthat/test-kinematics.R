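g2 <- nucleus_geometry(radius = 2)

test_that("step speeds are displacement over elapsed time in nm/s", {
  still <- data.frame(frame = 1:5, y_um = 1, x_um = 1)
  expect_equal(step_speeds(still, 5), rep(0, 4))
  tr40 <- data.frame(frame = 1:4, y_um = cumsum(c(0, rep(0.2, 3))), x_um = 0)
  expect_equal(step_speeds(tr40, 5), rep(40, 3))
  tr190 <- data.frame(frame = 1:2, y_um = c(0, 0.95), x_um = 0)
  expect_equal(step_speeds(tr190, 5), 190)
  expect_equal(step_speeds(still[1, ], 5), numeric(0))
  # gap intervals are excluded by default, included on request
  gap <- data.frame(frame = c(1, 2, 4), y_um = c(0, 0.2, 0.6), x_um = 0)
  expect_equal(step_speeds(gap, 5), 40)
  expect_equal(step_speeds(gap, 5, include_gaps = TRUE), c(40, 40))
})

test_that("threshold fractions follow the strict/inclusive conventions", {
  df <- data.frame(track_id = 1, frame = 1:4,
                   y_um = cumsum(c(0, 0.15, 0.25, 0.85)), x_um = 0)
  sd_ <- speed_distribution(df, frame_interval_s = 5)
  expect_equal(unname(sd_$fraction_above[1]), 2 / 3)   # {30,50,170} > 40
  expect_equal(unname(sd_$fraction_above[2]), 1 / 3)   # >= 160
  # all speeds exactly 40 -> strictly-above fraction is 0
  # (0.25 um per 6.25 s = 40 nm/s, all binary-exact)
  df40 <- data.frame(track_id = 1, frame = 1:5,
                     y_um = (0:4) * 0.25, x_um = 0)
  sd40 <- speed_distribution(df40, frame_interval_s = 6.25)
  expect_equal(unname(sd40$fraction_above[1]), 0)
  # histogram mass sums to 1
  expect_equal(sum(sd_$density), 1)
  # fraction above is non-increasing in the threshold
  sp <- sd_$speeds
  fr <- vapply(seq(0, 200, 10), function(t) mean(sp > t), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(speed_distribution(df[0, ]), class = "netrack_invalid_input")
  # per-track pooling option: track means {40, 170} instead of intervals
  df2 <- rbind(data.frame(track_id = 1, frame = 1:3,
                          y_um = cumsum(c(0, 0.15, 0.25)), x_um = 0),
               data.frame(track_id = 2, frame = 1:2,
                          y_um = c(0, 0.85), x_um = 0))
  sdt <- speed_distribution(df2, frame_interval_s = 5, per_track = TRUE)
  expect_equal(unname(sdt$fraction_above), c(1 / 2, 1 / 2))
})

test_that("arc coverage converts path length to circumference angle", {
  expect_equal(arc_coverage(data.frame(frame = 1:3, y_um = 1, x_um = 1), g2), 0)
  # one full circumference = 360 degrees
  full <- data.frame(frame = 1:2, y_um = c(0, 2 * pi * 2), x_um = 0)
  expect_equal(arc_coverage(full, g2), 360)
  # constant angular speed 0.1 deg/s for 900 s = 90 degrees
  tt <- seq(0, 900, 5)
  ang <- 0.1 * tt * pi / 180
  circ <- data.frame(frame = seq_along(tt), y_um = 2 * cos(ang),
                     x_um = 2 * sin(ang))
  expect_equal(arc_coverage(circ, g2), 90, tolerance = 1e-4)
  expect_error(arc_coverage(full, structure(list(center = c(y = 0, x = 0),
                                                 radius = 0),
                                            class = "netrack_nucleus_geometry")),
               class = "netrack_invalid_geometry")
})

test_that("arc coverage is invariant to rigid rotation about the centre", {
  set.seed(5)
  tr <- data.frame(frame = 1:20, y_um = cumsum(stats::rnorm(20, 0, 0.1)),
                   x_um = cumsum(stats::rnorm(20, 0, 0.1)))
  a0 <- arc_coverage(tr, g2)
  th <- 1.1
  rot <- data.frame(frame = tr$frame,
                    y_um = cos(th) * tr$y_um - sin(th) * tr$x_um,
                    x_um = sin(th) * tr$y_um + cos(th) * tr$x_um)
  expect_equal(arc_coverage(rot, g2), a0, tolerance = 1e-10)
})

test_that("nucleus summaries aggregate per-track arcs correctly", {
  # three tracks with path lengths chosen to give arcs 10, 20, 90 degrees
  path_for <- function(deg) deg / 360 * 2 * pi * 2
  mk <- function(id, deg) data.frame(track_id = id, frame = 1:10,
                                     y_um = seq(0, path_for(deg), length.out = 10),
                                     x_um = id)
  df <- rbind(mk(1, 10), mk(2, 20), mk(3, 90))
  s <- summarize_nucleus(df, g2, min_track_length = 10)
  expect_equal(s$mean_arc, 40, tolerance = 1e-10)
  expect_equal(s$max_arc, 90, tolerance = 1e-10)
  expect_equal(s$min_arc, 10, tolerance = 1e-10)
  expect_equal(s$n_tracks, 3L)
  # single track: mean = max = min
  s1 <- summarize_nucleus(mk(1, 50), g2, min_track_length = 10)
  expect_equal(s1$mean_arc, s1$max_arc)
  expect_equal(s1$mean_arc, s1$min_arc)
  # nothing qualifying -> flagged empty summary
  s0 <- summarize_nucleus(mk(1, 50)[1:3, ], g2, min_track_length = 10)
  expect_true(s0$empty)
})

test_that("projection can only shorten speeds; in-plane motion keeps them", {
  # processive motion along the equator (in the imaging plane): projected
  # median within [0.9 v, v]
  v <- 150; dt <- 5; R <- 2
  tt <- seq(0, 900, dt)
  ang <- (v / 1000) * tt / R
  tr <- data.frame(frame = seq_along(tt), y_um = R * cos(ang),
                   x_um = R * sin(ang))
  med <- stats::median(step_speeds(tr, dt))
  expect_gte(med, 0.9 * v)
  expect_lte(med, v * (1 + 1e-12))
  # an arbitrarily oriented great circle can only project to slower speeds
  m <- motion_model(run_speed = v, pause_fraction = 0, diffusion_coeff = 0,
                    run_persistence = 1e9)
  sim_tr <- simulate_motion_track(m, g2, 900, dt, seed = 8)
  sp3 <- step_speeds(data.frame(frame = seq_len(nrow(sim_tr)),
                                y_um = sim_tr$y_um, x_um = sim_tr$x_um), dt)
  expect_true(all(sp3 <= v * (1 + 1e-9)))
})

test_that("track overlap fraction matches hand-rastered cases", {
  px <- 0.1
  a <- data.frame(track_id = 1, frame = 1:2, y_um = c(0, 0), x_um = c(0, 1))
  b <- a; b$track_id <- 2
  expect_equal(track_overlap_map(rbind(a, b), px), 1)
  c2 <- data.frame(track_id = 2, frame = 1:2, y_um = c(1, 1), x_um = c(0, 1))
  expect_equal(track_overlap_map(rbind(a, c2), px), 0)
  # perpendicular crossing: horizontal 11 px, vertical 11 px, sharing 1 px
  h <- data.frame(track_id = 1, frame = 1:2, y_um = c(0, 0), x_um = c(0, 1))
  v <- data.frame(track_id = 2, frame = 1:2, y_um = c(-0.5, 0.5),
                  x_um = c(0.5, 0.5))
  expect_equal(track_overlap_map(rbind(h, v), px), 1 / 21)
  expect_warning(o <- track_overlap_map(a, px), "fewer than 2")
  expect_equal(o, 0)
})
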