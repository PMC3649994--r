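test_that("movie dimensions and calibration follow the configuration", {
  cfg <- sim_config(frames = 12, z_planes = 5, seed = 1)
  sim <- simulate_ne_movie(cfg, "wt")
  d <- dim(sim$movie$data)
  expect_equal(d[1], 12L)
  expect_equal(d[2], 5L)
  expect_equal(sim$movie$pixel_size, cfg$pixel_size)
  expect_equal(sim$movie$frame_interval, cfg$frame_interval)
  expect_true(all(sim$movie$data >= 0))
  expect_true(all(sim$truth$tracks$frame %in% 1:12))
})

test_that("a configuration without aggregates yields pure noise", {
  cfg <- sim_config(frames = 6, aggregates_per_nucleus = 0, seed = 2,
                    noise_floor = 50)
  sim <- simulate_ne_movie(cfg, motion_model())
  expect_equal(nrow(sim$truth$tracks), 0L)
  expect_equal(mean(sim$movie$data), 50, tolerance = 0.02)
})

test_that("a stationary aggregate renders at a fixed voxel", {
  cfg <- sim_config(frames = 8, aggregates_per_nucleus = 1, seed = 5,
                    photon_budget = 2e5, bleach_halflife = 1e9,
                    noise_floor = 0, read_noise = 0, shot_noise = FALSE)
  sim <- simulate_ne_movie(cfg, motion_model(run_speed = 0, diffusion_coeff = 0))
  argmaxes <- vapply(seq_len(8), function(f)
    which.max(sim$movie$data[f, , , ]), integer(1))
  expect_true(all(argmaxes == argmaxes[1]))
})

test_that("rendered peak intensity matches the analytic single-spot render", {
  cfg <- sim_config(frames = 20, aggregates_per_nucleus = 1, seed = 9,
                    aggregate_diameter = c(1, 1), bleach_halflife = 1e9,
                    shot_noise = FALSE)
  sim <- simulate_ne_movie(cfg, motion_model(run_speed = 0, diffusion_coeff = 0))
  tr <- sim$truth$tracks[1, ]
  # analytic render of one voxel-sampled 3D Gaussian at the truth position
  d <- tr$diameter_um
  s_obj <- d / 2.355
  sxy <- sqrt(cfg$psf_sigma^2 + s_obj^2)
  szz <- sqrt((2 * cfg$psf_sigma)^2 + s_obj^2)
  photons <- cfg$photon_budget * d^3
  py <- tr$y_um / cfg$pixel_size
  px <- tr$x_um / cfg$pixel_size
  nz <- cfg$z_planes
  zs <- (seq_len(nz) - 1 - (nz - 1) / 2) * cfg$z_spacing
  gy <- stats::dnorm(round(py) * cfg$pixel_size, tr$y_um, sxy) * cfg$pixel_size
  gx <- stats::dnorm(round(px) * cfg$pixel_size, tr$x_um, sxy) * cfg$pixel_size
  gz <- max(stats::dnorm(zs, tr$z_um, szz)) * cfg$z_spacing
  analytic_peak <- photons * gy * gx * gz
  measured <- max(sim$movie$data[1, , , ]) - cfg$noise_floor
  expect_equal(measured, analytic_peak, tolerance = 1e-9)
  # with shot noise on, the measured peak-to-background ratio stays within
  # 20% of the analytic value and sits in the intended SNR regime
  cfg2 <- sim_config(frames = 20, aggregates_per_nucleus = 1, seed = 9,
                     aggregate_diameter = c(1, 1), bleach_halflife = 1e9)
  sim2 <- simulate_ne_movie(cfg2, motion_model(run_speed = 0,
                                               diffusion_coeff = 0))
  # read the known peak voxel (a global max over Poisson voxels is biased)
  zi <- which.max(stats::dnorm(zs, tr$z_um, szz))
  measured2 <- mean(sim2$movie$data[, zi, round(py) + 1, round(px) + 1]) -
    cfg2$noise_floor
  expect_equal(measured2, analytic_peak, tolerance = 0.2)
  expect_gt(measured2 / sqrt(cfg2$noise_floor + cfg2$read_noise^2), 5)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(frames = 6, seed = 33)
  a <- simulate_ne_movie(cfg, "spd3")
  b <- simulate_ne_movie(cfg, "spd3")
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$tracks, b$truth$tracks)
})

test_that("fusion and split logs are consistent with track topology", {
  cfg <- sim_config(frames = 60, seed = 4, aggregates_per_nucleus = 4)
  m <- motion_model(run_speed = 190, pause_fraction = 0.3,
                    diffusion_coeff = 1e-3, fusion_radius = 0.6,
                    split_rate = 5e-3)
  sim <- simulate_ne_movie(cfg, m)
  ev <- sim$truth$events
  tr <- sim$truth$tracks
  expect_gt(nrow(ev), 0)   # this configuration interacts frequently
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    this <- tr[tr$track_id == e$track_id, ]
    partner <- tr[tr$track_id == e$partner_id, ]
    if (e$type == "fusion") {
      # the dying track's last observation is the frame before the merge,
      # and the surviving partner is present at the merge frame
      expect_equal(max(this$frame), e$frame - 1L)
      expect_true(e$frame %in% partner$frame)
    } else {
      expect_equal(min(this$frame), e$frame)
      expect_true((e$frame - 1L) %in% partner$frame ||
                  e$frame %in% partner$frame)
    }
  }
})

test_that("movies survive a TIFF + sidecar round trip", {
  cfg <- sim_config(frames = 4, z_planes = 3, seed = 6)
  sim <- simulate_ne_movie(cfg, "wt")
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie(sim$movie, path)
  back <- read_movie(path)
  expect_equal(dim(back$data), dim(sim$movie$data))
  expect_equal(back$pixel_size, sim$movie$pixel_size)
  scale <- max(sim$movie$data)
  expect_lt(max(abs(back$data - sim$movie$data)) / scale, 1e-6)
  # 2D movies round-trip too
  proj <- max_project(sim$movie)
  path2 <- file.path(withr::local_tempdir(), "proj.tif")
  write_movie(proj, path2)
  back2 <- read_movie(path2)
  expect_equal(length(dim(back2$data)), 3L)
  expect_lt(max(abs(back2$data - proj$data)) / scale, 1e-6)
})
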