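# Synthetic gait fixture: dynamically consistent marker trajectories plus
# external loads, generated from prescribed smooth joint-angle curves, with
# every ground-truth quantity retained. Because the ground wrench is
# constructed to absorb the whole-body residual, feeding the generated
# kinematics and loads back through inverse dynamics reproduces the stored
# moments and leaves a (numerically) zero residual at the free base.

#' Generate a dynamically consistent synthetic gait trial
#'
#' Joint coordinates follow smooth periodic gait-like curves (at most three
#' harmonics per coordinate, see [gait_coordinate_curves()]); markers are
#' placed by forward kinematics with optional isotropic Gaussian noise. The
#' net external wrench required by whole-body dynamics is computed from a
#' no-load inverse-dynamics pass and assigned to the feet as a vertical-
#' ground-reaction-style force with centre of pressure on the ground plane
#' and a vertical free moment; during double support the wrench is split
#' between the feet by a smooth cosine transition weight.
#'
#' @param model a [link_segment_model()] (default [default_gait_model()])
#' @param cycle gait cycle duration, s
#' @param rate marker sampling rate, Hz (>= 50)
#' @param noise_sd isotropic marker noise standard deviation, m (default 0:
#'   the fixture isolates model-side uncertainty)
#' @param seed RNG seed for the marker noise
#' @param overrides per-coordinate curve overrides, passed to
#'   [gait_coordinate_curves()]
#' @param stance_right fraction of the cycle the right foot is loaded
#'   (default 0.6, with heel strike at t = 0)
#' @param ramp duration of each smooth load-transfer ramp, cycle fraction
#' @return object of class `synthetic_trial` with fields `model`, `times`,
#'   `q`, `qdot`, `qddot` (ground truth), `trajectories`
#'   ([marker_trajectories()]), `loads` ([external_loads()]),
#'   `true_moments` (`joint_moments`), `events`, `params`
#' @examples
#' trial <- generate_trial(rate = 60)
#' trial$events$stance_frames[1:5]
#' @export
generate_trial <- function(model = default_gait_model(), cycle = 1.1,
                           rate = 100, noise_sd = 0, seed = NULL,
                           overrides = NULL, stance_right = 0.6,
                           ramp = 0.12) {
  stopifnot(inherits(model, "link_segment_model"))
  if (rate < 50) stop("sampling rate must be at least 50 Hz")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, cycle, by = 1 / rate)
  Tn <- length(times)
  u <- times / cycle
  cur <- gait_coordinate_curves(model, times, cycle = cycle,
                                overrides = overrides)
  cc <- model$compiled
  out_of_bounds <- sweep(cur$q, 2L, cc$lower, "<") |
    sweep(cur$q, 2L, cc$upper, ">")
  if (any(out_of_bounds)) {
    bad <- unique(cc$coords$name[which(out_of_bounds, arr.ind = TRUE)[, 2L]])
    stop("prescribed curves violate coordinate bounds: ",
         paste(bad, collapse = ", "))
  }

  # markers by forward kinematics (+ optional noise)
  M <- length(cc$marker_names)
  xyz <- array(NA_real_, c(3L, M, Tn),
               dimnames = list(c("x", "y", "z"), cc$marker_names, NULL))
  for (t in seq_len(Tn)) xyz[, , t] <- forward_kinematics(model, cur$q[t, ])
  if (noise_sd > 0) xyz <- xyz + stats::rnorm(length(xyz), 0, noise_sd)
  trajectories <- marker_trajectories(times, xyz, rate = rate)

  # whole-body residual wrench with no loads applied
  id0 <- inverse_dynamics(model, cur$q, cur$qdot, cur$qddot, loads = NULL,
                          times = times)
  f0 <- id0$residual$force
  n0 <- id0$residual$moment
  # root joint centre in ground: free-joint translations + fixed offset
  root <- model$segments[[1L]]
  p_b <- cbind(cur$q[, 1L] + root$location_in_parent[1L],
               cur$q[, 2L] + root$location_in_parent[2L],
               cur$q[, 3L] + root$location_in_parent[3L])
  # torque of the required wrench about the ground origin
  T0 <- n0 + t(vapply(seq_len(Tn), function(t) cross3(p_b[t, ], f0[t, ]),
                      numeric(3)))

  wr <- stance_weight(u, stance_right, ramp)
  grf <- function(w) {
    Fm <- w * f0
    Tm <- w * T0
    P <- matrix(0, Tn, 3L)
    Mm <- matrix(0, Tn, 3L)
    for (t in seq_len(Tn)) {
      Fy <- Fm[t, 2L]
      if (abs(Fy) >= 10) {
        px <- Tm[t, 3L] / Fy
        pz <- -Tm[t, 1L] / Fy
        P[t, ] <- c(px, 0, pz)
        Mm[t, ] <- c(0, Tm[t, 2L] - pz * Fm[t, 1L] + px * Fm[t, 3L], 0)
      } else {
        # too little load for a meaningful CoP: keep the full free moment
        Mm[t, ] <- Tm[t, ]
      }
    }
    list(force = Fm, point = P, torque = Mm)
  }
  gr <- grf(wr)
  gl <- grf(1 - wr)
  loads <- external_loads(
    times,
    c(list(segment = "foot_r"), gr),
    c(list(segment = "foot_l"), gl)
  )

  true_moments <- inverse_dynamics(model, cur$q, cur$qdot, cur$qddot,
                                   loads = loads, times = times)
  events <- detect_gait_events(loads, segment = "foot_r")
  structure(
    list(model = model, times = times, q = cur$q, qdot = cur$qdot,
         qddot = cur$qddot, trajectories = trajectories, loads = loads,
         true_moments = true_moments, events = events,
         params = list(cycle = cycle, rate = rate, noise_sd = noise_sd,
                       stance_right = stance_right, ramp = ramp,
                       overrides = overrides, seed = seed)),
    class = "synthetic_trial"
  )
}

# Smooth (C1) load share carried by the right foot over the cycle: cosine
# ramps of width `ramp` at weight acceptance and toe-off.
stance_weight <- function(u, stance_right, ramp) {
  w <- numeric(length(u))
  up <- u <= ramp
  w[up] <- 0.5 * (1 - cos(pi * u[up] / ramp))
  mid <- u > ramp & u <= stance_right - ramp
  w[mid] <- 1
  down <- u > stance_right - ramp & u <= stance_right
  w[down] <- 0.5 * (1 + cos(pi * (u[down] - (stance_right - ramp)) / ramp))
  w
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial: %d frames @ %g Hz, cycle %g s, noise sd %g m>\n",
    length(x$times), x$params$rate, x$params$cycle, x$params$noise_sd))
  invisible(x)
}

#' Detect stance and push-off windows from vertical ground reaction force
#'
#' Stance is where the vertical force on the chosen foot exceeds
#' `threshold` N, with hysteresis (the foot must drop below 75% of the
#' threshold to leave stance); the longest contiguous loaded window is
#' taken. Push-off is the final `pushoff_fraction` of stance.
#'
#' @param loads an [external_loads()]
#' @param segment name of the stance foot segment (default `"foot_r"`)
#' @param threshold vertical-force threshold, N
#' @param pushoff_fraction final fraction of stance treated as push-off
#' @return list of class `gait_events`: `stance_frames`, `pushoff_frames`
#'   (integer frame indices), `stance_times`, `pushoff_times` (s)
#' @export
detect_gait_events <- function(loads, segment = "foot_r", threshold = 20,
                               pushoff_fraction = 0.4) {
  stopifnot(inherits(loads, "external_loads"))
  li <- which(vapply(loads$loads, function(l) l$segment == segment,
                     logical(1)))
  if (length(li) == 0L) stop("no load applied to segment ", segment)
  fy <- loads$loads[[li[1L]]]$force[, 2L]
  on <- logical(length(fy))
  state <- FALSE
  lo <- 0.75 * threshold
  for (t in seq_along(fy)) {
    state <- if (state) fy[t] > lo else fy[t] > threshold
    on[t] <- state
  }
  if (!any(on)) stop("no stance phase: vertical force never exceeds threshold")
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iw <- which(runs$values)
  best <- iw[which.max(runs$lengths[iw])]
  stance <- starts[best]:ends[best]
  n_po <- max(1L, ceiling(pushoff_fraction * length(stance)))
  pushoff <- stance[(length(stance) - n_po + 1L):length(stance)]
  structure(
    list(stance_frames = stance, pushoff_frames = pushoff,
         stance_times = range(loads$times[stance]),
         pushoff_times = range(loads$times[pushoff]),
         segment = segment, threshold = threshold,
         pushoff_fraction = pushoff_fraction),
    class = "gait_events"
  )
}
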