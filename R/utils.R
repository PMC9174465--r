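# Small numeric helpers shared across the package.

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues' formula. `axis` must have unit norm; this is checked at model
#' construction time, not here (hot path).
#'
#' @param axis unit 3-vector
#' @param angle rotation angle, rad
#' @return 3x3 rotation matrix
#' @keywords internal
#' @noRd
rot_axis_angle <- function(axis, angle) {
  ca <- cos(angle)
  sa <- sin(angle)
  C <- 1 - ca
  x <- axis[1L]; y <- axis[2L]; z <- axis[3L]
  matrix(
    c(ca + x * x * C,      x * y * C + z * sa,  x * z * C - y * sa,
      x * y * C - z * sa,  ca + y * y * C,      y * z * C + x * sa,
      x * z * C + y * sa,  y * z * C - x * sa,  ca + z * z * C),
    nrow = 3L, ncol = 3L
  )
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @noRd
skew3 <- function(v) {
  matrix(c(0, v[3L], -v[2L],
           -v[3L], 0, v[1L],
           v[2L], -v[1L], 0), nrow = 3L, ncol = 3L)
}

#' Cross product of two 3-vectors
#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Euclidean norm
#' @noRd
norm3 <- function(v) sqrt(sum(v * v))

#' Clamp a vector into [lower, upper] elementwise
#' @noRd
clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Remove 2*pi discontinuities from an angle series
#'
#' Standard phase unwrapping: wherever the step between consecutive samples
#' exceeds pi in magnitude, a multiple of 2*pi is added to all subsequent
#' samples so the series is continuous.
#'
#' @param x numeric vector of angles, rad
#' @return unwrapped vector, same length
#' @export
unwrap_angles <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jumps <- round(d / (2 * pi))
  x - c(0, cumsum(jumps)) * 2 * pi
}

#' Uniform draws inside a closed 3-ball
#'
#' Rejection sampling: candidates are drawn uniformly in the cube
#' `[-radius, radius]^3` and kept when their norm does not exceed `radius`,
#' so every point of the ball is selected with equal probability. Acceptance
#' probability is pi/6 (about 52%), so the expected number of candidate
#' rounds is small and bounded.
#'
#' @param n number of points
#' @param radius ball radius (>= 0)
#' @return `n` x 3 matrix; every row has norm <= `radius`
#' @examples
#' set.seed(1)
#' x <- runif_ball(1000, 0.01)
#' max(sqrt(rowSums(x^2))) <= 0.01
#' @export
runif_ball <- function(n, radius) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 0)
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  if (radius == 0) return(matrix(0, n, 3L))
  out <- matrix(NA_real_, n, 3L)
  got <- 0L
  # cannot loop forever: acceptance is pi/6 per candidate; the cap is a guard
  for (round in seq_len(1000L)) {
    need <- n - got
    m <- max(need * 2L, 16L)
    cand <- matrix(stats::runif(3L * m, -radius, radius), m, 3L)
    keep <- cand[rowSums(cand * cand) <= radius * radius, , drop = FALSE]
    if (nrow(keep) > 0L) {
      take <- min(nrow(keep), need)
      out[(got + 1L):(got + take), ] <- keep[seq_len(take), , drop = FALSE]
      got <- got + take
    }
    if (got == n) return(out)
  }
  stop("internal error: ball rejection sampler failed to fill the request")
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a (base seed, level, draw) triple to a 31-bit seed so that each
#' ensemble draw gets its own RNG stream, reproducible and independent of
#' the order in which draws are generated.
#' @noRd
derive_seed <- function(seed, level, draw) {
  s <- (as.double(seed) %% 2147483647) + 1000003 * as.double(level) +
    7919 * as.double(draw)
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
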