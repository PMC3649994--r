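det_df <- function(frame, y, x) data.frame(frame = frame, y_um = y, x_um = x)

test_that("one detection per frame links into a single track", {
  det <- det_df(1:10, seq(0, 0.9, 0.1), rep(1, 10))
  trk <- link_tracks(det, max_disp_um = 0.5)
  expect_equal(length(unique(trk$tracks$track_id)), 1L)
  expect_equal(sort(trk$tracks$frame), 1:10)
})

test_that("two stationary well-separated spots never swap tracks", {
  det <- rbind(det_df(rep(1:20, each = 1), rep(1, 20), rep(1, 20)),
               det_df(1:20, rep(4, 20), rep(4, 20)))
  set.seed(1)
  det$y_um <- det$y_um + stats::rnorm(40, 0, 0.02)
  det$x_um <- det$x_um + stats::rnorm(40, 0, 0.02)
  trk <- link_tracks(det, max_disp_um = 1)
  expect_equal(length(unique(trk$tracks$track_id)), 2L)
  for (id in unique(trk$tracks$track_id)) {
    tr <- trk$tracks[trk$tracks$track_id == id, ]
    expect_lt(diff(range(tr$y_um)), 0.2)   # stayed on one spot
  }
})

test_that("frame-pair matching equals exhaustive minimal-cost assignment", {
  set.seed(99)
  gate <- 1
  for (rep in 1:300) {
    n <- sample(0:4, 1); m <- sample(0:4, 1)
    p1 <- matrix(stats::runif(2 * n, 0, 3), ncol = 2)
    p2 <- matrix(stats::runif(2 * m, 0, 3), ncol = 2)
    got <- netrack:::match_frame(p1, p2, gate)$cost
    want <- brute_force_match_cost(p1, p2, gate)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("constructed small-jitter scenes reproduce the brute-force links", {
  set.seed(7)
  # 3 spots x 4 frames with jitter far below spacing: links must follow
  # each spot (the unique optimum)
  base <- cbind(c(0, 2, 4), c(0, 2, 0))
  det <- NULL
  for (f in 1:4)
    det <- rbind(det, det_df(rep(f, 3),
                             base[, 1] + stats::rnorm(3, 0, 0.05),
                             base[, 2] + stats::rnorm(3, 0, 0.05)))
  # shuffle within frames: linking must be order invariant
  for (perm in 1:3) {
    idx <- unlist(lapply(split(seq_len(nrow(det)), det$frame), sample))
    trk <- link_tracks(det[idx, ], max_disp_um = 1)
    expect_equal(length(unique(trk$tracks$track_id)), 3L)
    for (id in unique(trk$tracks$track_id)) {
      tr <- trk$tracks[trk$tracks$track_id == id, ]
      expect_equal(nrow(tr), 4L)
      expect_lt(diff(range(tr$y_um)), 0.3)
    }
  }
})

test_that("every detection belongs to exactly one track", {
  set.seed(13)
  det <- NULL
  for (f in 1:8)
    det <- rbind(det, det_df(rep(f, 4), stats::runif(4, 0, 5),
                             stats::runif(4, 0, 5)))
  trk <- link_tracks(det, max_disp_um = 1.5)
  expect_equal(nrow(trk$tracks), nrow(det))
  expect_false(any(is.na(trk$tracks$track_id)))
  key <- paste(trk$tracks$frame, trk$tracks$y_um, trk$tracks$x_um)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("gap closing bridges short dropouts and flags the interval", {
  det <- det_df(c(1, 2, 4, 5), c(0, 0.1, 0.3, 0.4), rep(1, 4))
  trk <- link_tracks(det, max_disp_um = 0.5, max_gap_frames = 2)
  expect_equal(length(unique(trk$tracks$track_id)), 1L)
  expect_true(trk$tracks$gap[trk$tracks$frame == 4])
  # beyond the gap tolerance the track is closed and a new one starts
  trk2 <- link_tracks(det_df(c(1, 2, 6), c(0, 0.1, 0.2), rep(1, 3)),
                      max_disp_um = 0.5, max_gap_frames = 2)
  expect_equal(length(unique(trk2$tracks$track_id)), 2L)
})

test_that("converging tracks are annotated as fusion, diverging as split", {
  # two tracks converge onto one surviving detection sequence
  det <- rbind(det_df(1:6, rep(0, 6), seq(0, 0.5, 0.1)),
               det_df(1:3, c(1.5, 1.0, 0.5), c(0, 0.1, 0.2)))
  trk <- annotate_fusion_splitting(link_tracks(det, max_disp_um = 0.8),
                                   merge_dist_um = 0.6)
  expect_equal(sum(trk$events$type == "fusion"), 1L)
  # one track emits a second one mid-movie
  det2 <- rbind(det_df(1:6, rep(0, 6), seq(0, 0.5, 0.1)),
                det_df(4:6, c(0.3, 0.8, 1.3), c(0.3, 0.35, 0.4)))
  trk2 <- annotate_fusion_splitting(link_tracks(det2, max_disp_um = 0.8),
                                    merge_dist_um = 0.6)
  expect_equal(sum(trk2$events$type == "split"), 1L)
})

test_that("pipeline fusion counts track the simulated event log", {
  # pooled over seeds, the detected fusion count stays within +/-20% of
  # the ground-truth count for clean, bright movies
  k_true <- 0L; k_det <- 0L
  for (s in 1:10) {
    cfg <- sim_config(frames = 100, seed = s, aggregates_per_nucleus = 5,
                      aggregate_diameter = c(0.7, 0.9), photon_budget = 5e4)
    m <- motion_model(run_speed = 60, run_persistence = 10,
                      diffusion_coeff = 2e-3, pause_fraction = 0.7,
                      fusion_radius = 0.5, split_rate = 0)
    sim <- simulate_ne_movie(cfg, m)
    an <- track_movie(sim, threshold_snr = 5, min_diameter_um = 0.4,
                      max_diameter_um = 1.8)
    k_true <- k_true + sum(sim$truth$events$type == "fusion")
    for (nid in names(an$per_nucleus))
      k_det <- k_det +
        sum(an$per_nucleus[[nid]]$tracks$events$type == "fusion")
  }
  expect_gt(k_true, 5)
  expect_lte(abs(k_det - k_true) / k_true, 0.2)
})

test_that("always-resolved ground-truth tracks are recovered by the linker", {
  # pooled over seeds: aggregates that never close within the optical
  # merge distance keep their identity end to end; encounters reset
  # identity for any gated linker, so conflated tracks are not assessable
  rec <- 0L; tot <- 0L
  for (s in 1:16) {
    cfg <- sim_config(frames = 60, seed = s, aggregates_per_nucleus = 3,
                      aggregate_diameter = c(0.55, 0.8), photon_budget = 5e4)
    m <- motion_model(run_speed = 60, run_persistence = 20,
                      diffusion_coeff = 4e-4, pause_fraction = 0.5,
                      fusion_radius = 0.3, split_rate = 0)
    sim <- simulate_ne_movie(cfg, m)
    an <- track_movie(sim, threshold_snr = 5, min_diameter_um = 0.4,
                      max_diameter_um = 1.2)
    tr <- track_recovery(an$pooled_tracks, sim$truth$tracks)
    rec <- rec + tr$n_recovered; tot <- tot + tr$n_assessable
  }
  expect_gte(tot, 4L)
  expect_gte(rec / tot, 0.9)
})
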