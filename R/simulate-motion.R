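#' Nucleus geometry for projection-based measurements
#'
#' @param center_y,center_x Projected nucleus centre, um.
#' @param radius Nuclear radius, um.
#' @return An object of class `netrack_nucleus_geometry`.
#' @export
nucleus_geometry <- function(center_y = 0, center_x = 0, radius = 2) {
  check_number(radius, "radius", positive = TRUE)
  check_number(center_y, "center_y")
  check_number(center_x, "center_x")
  structure(list(center = c(y = center_y, x = center_x), radius = radius),
            class = "netrack_nucleus_geometry")
}

# --- internal sphere helpers ------------------------------------------------

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v * v))
    if (n > 1e-12) return(v / n)
  }
}

# Orthonormal tangent basis at unit vector p.
tangent_basis <- function(p) {
  a <- if (abs(p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * p) * p
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(p[2] * e1[3] - p[3] * e1[2],
          p[3] * e1[1] - p[1] * e1[3],
          p[1] * e1[2] - p[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

random_tangent <- function(p) {
  b <- tangent_basis(p)
  phi <- stats::runif(1, 0, 2 * pi)
  cos(phi) * b$e1 + sin(phi) * b$e2
}

# One aggregate's motion state: unit position, unit tangent, run/pause flag.
new_motion_state <- function(model, p = NULL) {
  if (is.null(p)) p <- random_unit_vector()
  state <- if (stats::runif(1) < model$pause_fraction) "pause" else "run"
  list(p = p, dir = random_tangent(p), state = state)
}

# Advance one time step on the unit sphere; returns updated state.
# Radius enters through the angular step (linear speed / radius).
step_motion <- function(st, model, radius, dt) {
  stay_run <- exp(-dt / model$run_persistence)
  pf <- model$pause_fraction
  stay_pause <- if (pf >= 1) 1 else if (pf <= 0) 0 else {
    max(0, 1 - (1 - pf) * (1 - stay_run) / pf)
  }
  # state transition at step boundary; a fresh run gets a fresh direction
  if (st$state == "run") {
    if (stats::runif(1) > stay_run) st$state <- "pause"
  } else {
    if (stats::runif(1) > stay_pause) {
      st$state <- "run"
      st$dir <- random_tangent(st$p)
    }
  }
  if (st$state == "run" && model$run_speed > 0) {
    theta <- (model$run_speed / 1000) * dt / radius  # nm/s -> um/s
    p_new <- cos(theta) * st$p + sin(theta) * st$dir
    st$dir <- -sin(theta) * st$p + cos(theta) * st$dir
    st$p <- p_new / sqrt(sum(p_new^2))
  } else if (st$state == "pause" && model$diffusion_coeff > 0) {
    b <- tangent_basis(st$p)
    s <- sqrt(2 * model$diffusion_coeff * dt)
    d <- stats::rnorm(1, 0, s) * b$e1 + stats::rnorm(1, 0, s) * b$e2
    p_new <- st$p + d / radius
    st$p <- p_new / sqrt(sum(p_new^2))
    st$dir <- random_tangent(st$p)
  }
  st
}

#' Simulate one aggregate track on the nuclear envelope
#'
#' Generates a sphere-constrained trajectory alternating processive
#' great-circle runs with slow-diffusion dwells, sampled every `dt` seconds.
#'
#' @param model A [motion_model()].
#' @param geometry A [nucleus_geometry()]; the track lives on the sphere of
#'   that radius centred on the projected centre (z centred on 0).
#' @param duration Total duration, s.
#' @param dt Sampling interval, s.
#' @param seed Integer seed; fixed seed gives a bit-identical track.
#' @return A data frame with columns `t_s`, `y_um`, `x_um`, `z_um`, `state`.
#'   Positions satisfy |distance to centre - radius| < 1e-6 um at every step.
#' @examples
#' g <- nucleus_geometry(radius = 2)
#' tr <- simulate_motion_track(motion_model(), g, duration = 60, dt = 5, seed = 1)
#' head(tr)
#' @export
simulate_motion_track <- function(model, geometry, duration, dt, seed = 1L) {
  stopifnot(inherits(model, "netrack_motion_model"),
            inherits(geometry, "netrack_nucleus_geometry"))
  check_number(dt, "dt", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  if (duration < dt) stop_invalid("'duration' must be >= 'dt'")
  set.seed(as.integer(seed))
  R <- geometry$radius
  n <- floor(duration / dt) + 1L
  st <- new_motion_state(model)
  pos <- matrix(NA_real_, n, 3)
  states <- character(n)
  pos[1, ] <- st$p * R
  states[1] <- st$state
  for (i in seq_len(n - 1L)) {
    st <- step_motion(st, model, R, dt)
    pos[i + 1L, ] <- st$p * R
    states[i + 1L] <- st$state
  }
  data.frame(
    t_s = (seq_len(n) - 1L) * dt,
    y_um = geometry$center[["y"]] + pos[, 1],
    x_um = geometry$center[["x"]] + pos[, 2],
    z_um = pos[, 3],
    state = states,
    stringsAsFactors = FALSE
  )
}
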