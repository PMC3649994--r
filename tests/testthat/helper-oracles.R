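# Independent oracles and fixture builders used across the suite.

# Render a 2D frame of Gaussian spots analytically (amplitude = peak counts).
render_frame <- function(H, W, spots, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(0, H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  for (i in seq_len(nrow(spots))) {
    f <- f + spots$amp[i] *
      exp(-((ys - spots$y[i])^2 + (xs - spots$x[i])^2) / (2 * spots$sigma[i]^2))
  }
  if (noise_sd > 0) f <- f + matrix(rnorm(H * W, 0, noise_sd), H, W)
  f
}

# Exhaustive minimal-cost gated matching between two point sets.
# Cost model: matched pair d^2 (only if d <= gate), every unmatched point
# on either side pays gate^2. Returns the minimal total cost.
brute_force_match_cost <- function(p1, p2, gate) {
  n <- nrow(p1); m <- nrow(p2)
  gate2 <- gate^2
  best <- Inf
  recurse <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n) {
      total <- cost + gate2 * sum(!used)
      if (total < best) best <<- total
      return()
    }
    # leave track i unmatched
    recurse(i + 1L, used, cost + gate2)
    if (m > 0) {
      for (j in which(!used)) {
        d2 <- sum((p1[i, ] - p2[j, ])^2)
        if (d2 <= gate2) {
          used2 <- used; used2[j] <- TRUE
          recurse(i + 1L, used2, cost + d2)
        }
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0)
  best
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities <= observed's).
fisher_enum_p <- function(a, n_a, b, n_b) {
  k <- a + b                      # total paired
  probs <- vapply(max(0, k - n_b):min(k, n_a), function(x)
    stats::dhyper(x, n_a, n_b, k), numeric(1))
  p_obs <- stats::dhyper(a, n_a, n_b, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments:
# P(|W - mu| >= |w_obs - mu|) over all choose(N, n1) subsets.
mw_enum_p <- function(a, b) {
  vals <- c(a, b)
  N <- length(vals); n1 <- length(a)
  ranks <- rank(vals)
  mu <- n1 * (N + 1) / 2
  w_obs <- sum(ranks[seq_len(n1)])
  subsets <- utils::combn(N, n1)
  ws <- apply(subsets, 2, function(idx) sum(ranks[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Fraction of ground-truth tracks recovered by the pipeline. Tracks
# fragment when aggregates transiently overlap in projection (live-imaging
# track counts routinely exceed aggregate counts for this reason), so a
# truth track counts as recovered when >= `frac` of its frames carry a
# detection within `radius_um` that belongs to a pipeline track whose
# dominant truth correspondence is that same truth track.
track_recovery <- function(pipeline_tracks, truth_tracks, radius_um = 0.214,
                           frac = 0.8, min_len = 10L,
                           resolve_um = 0.65, resolve_frac = 1.0) {
  truth_ids <- names(which(table(truth_tracks$track_id) >= min_len))
  # only always-resolved tracks are assessable: once two spots close within
  # the optical merge distance their projected identity is lost to any
  # gated nearest-neighbour linker (no motion-model prediction), exactly as
  # fusion redefines aggregate identity in the real movies
  truth_ids <- Filter(function(tid) {
    gt <- truth_tracks[truth_tracks$track_id == as.integer(tid), ]
    ok <- vapply(seq_len(nrow(gt)), function(i) {
      others <- truth_tracks[truth_tracks$frame == gt$frame[i] &
                             truth_tracks$track_id != gt$track_id[i], ]
      !nrow(others) ||
        min(sqrt((others$y_um - gt$y_um[i])^2 +
                 (others$x_um - gt$x_um[i])^2)) > resolve_um
    }, logical(1))
    mean(ok) >= resolve_frac
  }, truth_ids)
  if (!length(truth_ids))
    return(list(rate = NA_real_, n_recovered = 0L, n_assessable = 0L))
  # dominant truth id per pipeline track
  dom <- list()
  for (pid in unique(pipeline_tracks$track_id)) {
    pt <- pipeline_tracks[pipeline_tracks$track_id == pid, ]
    votes <- integer(0)
    for (i in seq_len(nrow(pt))) {
      gt_f <- truth_tracks[truth_tracks$frame == pt$frame[i], ]
      if (!nrow(gt_f)) next
      d <- sqrt((gt_f$y_um - pt$y_um[i])^2 + (gt_f$x_um - pt$x_um[i])^2)
      j <- which.min(d)
      if (d[j] <= radius_um)
        votes <- c(votes, gt_f$track_id[j])
    }
    dom[[as.character(pid)]] <- if (length(votes))
      as.integer(names(which.max(table(votes)))) else NA_integer_
  }
  rec <- vapply(truth_ids, function(tid) {
    gt <- truth_tracks[truth_tracks$track_id == as.integer(tid), ]
    covered <- 0L
    for (i in seq_len(nrow(gt))) {
      pt_f <- pipeline_tracks[pipeline_tracks$frame == gt$frame[i], ]
      if (!nrow(pt_f)) next
      d <- sqrt((pt_f$y_um - gt$y_um[i])^2 + (pt_f$x_um - gt$x_um[i])^2)
      ok <- d <= radius_um &
        vapply(pt_f$track_id, function(p)
          identical(dom[[as.character(p)]], as.integer(tid)), logical(1))
      if (any(ok)) covered <- covered + 1L
    }
    covered / nrow(gt) >= frac
  }, logical(1))
  list(rate = mean(rec), n_recovered = sum(rec), n_assessable = length(rec))
}
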