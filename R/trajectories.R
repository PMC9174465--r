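# Time-stamped marker trajectories (TRC semantics): named 3D marker
# positions per frame, with a missing-sample mask.

#' Construct a marker-trajectory set
#'
#' @param times strictly increasing time stamps, s
#' @param positions a 3 x M x T array (dimnames on the marker dimension) or
#'   a long tibble with columns `time`, `marker`, `x`, `y`, `z`
#' @param rate sampling rate in Hz; defaults to `1 / median(diff(times))`
#'   and must agree with the median time step within 1%
#' @return object of class `marker_trajectories` with fields `times`,
#'   `rate`, `names`, `xyz` (3 x M x T array; `NA` marks missing samples)
#' @export
marker_trajectories <- function(times, positions, rate = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (is.data.frame(positions)) {
    req <- c("time", "marker", "x", "y", "z")
    if (!all(req %in% names(positions))) {
      stop("long-format positions need columns ", paste(req, collapse = ", "))
    }
    mk <- unique(positions$marker)
    xyz <- array(NA_real_, c(3L, length(mk), length(times)),
                 dimnames = list(c("x", "y", "z"), mk, NULL))
    ti <- match(round(positions$time, 9L), round(times, 9L))
    mi <- match(positions$marker, mk)
    if (anyNA(ti)) stop("position rows with times absent from `times`")
    idx <- cbind(1L, mi, ti)
    xyz[idx] <- positions$x
    idx[, 1L] <- 2L; xyz[idx] <- positions$y
    idx[, 1L] <- 3L; xyz[idx] <- positions$z
  } else {
    xyz <- positions
    stopifnot(is.array(xyz), length(dim(xyz)) == 3L, dim(xyz)[1L] == 3L)
    if (is.null(dimnames(xyz)[[2L]])) stop("positions need marker names")
  }
  if (dim(xyz)[3L] != length(times)) {
    stop("frame count of positions does not match length(times)")
  }
  med_dt <- if (length(times) > 1L) stats::median(diff(times)) else NA_real_
  if (is.null(rate)) {
    rate <- if (is.na(med_dt)) NA_real_ else 1 / med_dt
  } else if (!is.na(med_dt) && abs(rate * med_dt - 1) > 0.01) {
    stop(sprintf("declared rate %.6g Hz inconsistent with median step %.6g s",
                 rate, med_dt))
  }
  structure(
    list(times = times, rate = rate, names = dimnames(xyz)[[2L]], xyz = xyz),
    class = "marker_trajectories"
  )
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories: %d markers x %d frames @ %.5g Hz, %.6g-%.6g s>\n",
              length(x$names), length(x$times), x$rate,
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' @export
as_tibble.marker_trajectories <- function(x, ...) {
  Tn <- length(x$times)
  M <- length(x$names)
  tibble::tibble(
    time = rep(x$times, each = M),
    marker = rep(x$names, times = Tn),
    x = as.numeric(x$xyz[1L, , ]),
    y = as.numeric(x$xyz[2L, , ]),
    z = as.numeric(x$xyz[3L, , ])
  )
}

#' Number of frames in a trajectory set
#' @param x a `marker_trajectories`
#' @return integer frame count
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "marker_trajectories"))
  length(x$times)
}
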