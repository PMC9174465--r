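# Zero-phase low-pass filtering and numerical differentiation of coordinate
# trajectories.

#' Zero-phase Butterworth low-pass filter
#'
#' A 4th-order Butterworth filter applied forward and backward (effective
#' order 8, zero phase lag, DC gain exactly 1). Edge effects are controlled
#' the standard way: the signal is extended at both ends by odd reflection
#' and each pass starts from the filter's step-response steady state, so a
#' constant signal passes through unchanged to machine precision.
#'
#' @param x numeric vector or matrix (one signal per column)
#' @param rate sampling rate, Hz; must exceed `2 * cutoff`
#' @param cutoff low-pass cutoff, Hz (default 6, the conventional gait
#'   kinematics choice)
#' @param order filter order per pass (default 4)
#' @return filtered signal, same shape as `x`
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' y <- lowpass_filter(sin(2 * pi * t) + 0.1 * sin(2 * pi * 30 * t), 100, 6)
#' @export
lowpass_filter <- function(x, rate, cutoff = 6, order = 4L) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  if (cutoff >= rate / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist rate (%g Hz)",
                 cutoff, rate / 2))
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  if (is.matrix(x)) {
    out <- apply(x, 2L, filtfilt_padded, b = bf$b, a = bf$a)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  filtfilt_padded(x, bf$b, bf$a)
}

# Forward-backward filtering with odd end reflection and steady-state
# initial conditions (the scipy/Octave filtfilt convention).
filtfilt_padded <- function(x, b, a) {
  n <- max(length(a), length(b)) - 1L
  N <- length(x)
  if (N <= 2L * n) stop("signal too short to filter")
  npad <- min(N - 1L, 3L * (n + 1L))
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[N] - x[(N - 1L):(N - npad)]
  xp <- c(head_pad, x, tail_pad)
  one_pass <- function(v) {
    init <- rep(v[1L], n)
    signal::filter(b, a, v, init.x = init, init.y = init)
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1L):(npad + N)]
}

#' Numerical differentiation of sampled trajectories
#'
#' Velocities use central differences at interior samples and one-sided
#' differences at the ends; accelerations apply the same operator to the
#' velocities. Exact for polynomials up to degree 1 (velocity) and, at
#' interior samples on a uniform grid, degree 2 (acceleration).
#'
#' @param values numeric vector or matrix (frames in rows)
#' @param times sample times, s; at least 3 frames, uniform step within 1%
#' @return list of class `coordinate_derivatives` with `velocities` and
#'   `accelerations`, same shape as `values`
#' @export
differentiate <- function(values, times) {
  vec_in <- !is.matrix(values)
  X <- if (vec_in) matrix(values, ncol = 1L) else values
  times <- as.numeric(times)
  Tn <- nrow(X)
  if (length(times) != Tn) stop("times must match the number of frames")
  if (Tn < 3L) stop("differentiation needs at least 3 frames")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if ((max(dt) - min(dt)) / stats::median(dt) > 0.01) {
    stop("time step must be uniform within 1%")
  }
  d1 <- function(M) {
    V <- M
    V[2:(Tn - 1L), ] <- (M[3:Tn, , drop = FALSE] - M[1:(Tn - 2L), , drop = FALSE]) /
      (times[3:Tn] - times[1:(Tn - 2L)])
    V[1L, ] <- (M[2L, ] - M[1L, ]) / dt[1L]
    V[Tn, ] <- (M[Tn, ] - M[Tn - 1L, ]) / dt[Tn - 1L]
    V
  }
  vel <- d1(X)
  acc <- d1(vel)
  if (vec_in) {
    vel <- as.numeric(vel)
    acc <- as.numeric(acc)
  }
  structure(list(velocities = vel, accelerations = acc),
            class = "coordinate_derivatives")
}

#' Unwrap, filter and differentiate an IK solution
#'
#' The standard processing chain between inverse kinematics and inverse
#' dynamics: rotational coordinates are unwrapped across frames, every
#' coordinate is zero-phase low-pass filtered, and velocities and
#' accelerations are estimated by numerical differentiation.
#'
#' @param model the model the coordinates belong to
#' @param ik an `ik_solution` (or a T x n_q coordinate matrix)
#' @param times required when `ik` is a bare matrix
#' @param cutoff low-pass cutoff, Hz
#' @return list with `coordinates` (filtered), `velocities`,
#'   `accelerations` (all T x n_q), `times`
#' @export
process_coordinates <- function(model, ik, times = NULL, cutoff = 6) {
  if (inherits(ik, "ik_solution")) {
    Q <- ik$coordinates
    times <- ik$times
  } else {
    Q <- ik
    if (is.null(times)) stop("times required when passing a coordinate matrix")
  }
  cc <- model$compiled
  rot <- cc$coords$kind == "rot"
  Q[, rot] <- apply(Q[, rot, drop = FALSE], 2L, unwrap_angles)
  rate <- 1 / stats::median(diff(times))
  Qf <- lowpass_filter(Q, rate, cutoff)
  der <- differentiate(Qf, times)
  list(times = times, coordinates = Qf, velocities = der$velocities,
       accelerations = der$accelerations)
}
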