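# The nine peak gait metrics and the crouch-gait classification.
#
# Conventions: hip flexion, knee flexion and ankle dorsiflexion coordinates
# are positive in flexion / dorsiflexion, so extension and plantarflexion
# peaks are maxima of the negated signals. Angle metrics are reported in
# degrees, moments in N m, powers in W.

#' Map model coordinates to the gait metrics
#'
#' Names the hip/knee/ankle coordinates (of the analysis leg) used when
#' extracting peak metrics. Defaults match [default_gait_model()]'s right
#' leg.
#'
#' @param hip_flexion,knee_flexion,ankle_dorsiflexion coordinate names
#' @return named list of coordinate names
#' @export
gait_metric_spec <- function(hip_flexion = "hip_flexion_r",
                             knee_flexion = "knee_flexion_r",
                             ankle_dorsiflexion = "ankle_dorsiflexion_r") {
  list(hip_flexion = hip_flexion, knee_flexion = knee_flexion,
       ankle_dorsiflexion = ankle_dorsiflexion)
}

PEAK_METRIC_NAMES <- c(
  "peak_hip_extension_angle", "min_knee_flexion_angle_stance",
  "peak_ankle_plantarflexion_angle", "peak_hip_flexion_moment",
  "peak_knee_flexion_moment_stance", "peak_ankle_plantarflexion_moment",
  "peak_hip_power_pushoff", "min_knee_power_stance",
  "peak_ankle_power_pushoff")

#' Extract the nine peak gait metrics from one trial
#'
#' Three joint angles (peak hip extension, minimum knee flexion during
#' stance, peak ankle plantarflexion), three joint moments (peak hip
#' flexion, peak knee flexion during stance, peak ankle plantarflexion) and
#' three joint powers (peak hip power at push-off, minimum knee power
#' during stance, peak ankle power at push-off). Stance-restricted metrics
#' search only the stance window and push-off metrics only the push-off
#' window of `events`.
#'
#' @param angles T x n_q coordinate matrix, rad (named columns)
#' @param moments a `joint_moments` object or T x n_q matrix, N m
#' @param powers a `joint_powers` object or T x n_q matrix, W
#' @param events a `gait_events` list from [detect_gait_events()]
#' @param metrics a [gait_metric_spec()]
#' @return one-row tibble with the nine metrics (deg, N m, W)
#' @export
extract_peaks <- function(angles, moments, powers, events,
                          metrics = gait_metric_spec()) {
  if (inherits(moments, "joint_moments")) moments <- moments$moments
  if (inherits(powers, "joint_powers")) powers <- powers$powers
  Tn <- nrow(angles)
  stance <- events$stance_frames
  pushoff <- events$pushoff_frames
  windows <- list(cycle = seq_len(Tn), stance = stance, pushoff = pushoff)
  col <- function(M, nm) {
    if (!nm %in% colnames(M)) stop("metric coordinate not found: ", nm)
    M[, nm]
  }
  peak <- function(x, window_name, metric, maximize = TRUE) {
    w <- windows[[window_name]]
    w <- w[w >= 1L & w <= Tn]
    if (length(w) == 0L) {
      stop(sprintf("empty %s window for metric %s", window_name, metric))
    }
    if (maximize) max(x[w]) else min(x[w])
  }
  hf <- col(angles, metrics$hip_flexion) * 180 / pi
  kf <- col(angles, metrics$knee_flexion) * 180 / pi
  ad <- col(angles, metrics$ankle_dorsiflexion) * 180 / pi
  mh <- col(moments, metrics$hip_flexion)
  mk <- col(moments, metrics$knee_flexion)
  ma <- col(moments, metrics$ankle_dorsiflexion)
  ph <- col(powers, metrics$hip_flexion)
  pk <- col(powers, metrics$knee_flexion)
  pa <- col(powers, metrics$ankle_dorsiflexion)
  tibble::tibble(
    peak_hip_extension_angle = peak(-hf, "cycle", "peak_hip_extension_angle"),
    min_knee_flexion_angle_stance =
      peak(kf, "stance", "min_knee_flexion_angle_stance", maximize = FALSE),
    peak_ankle_plantarflexion_angle =
      peak(-ad, "cycle", "peak_ankle_plantarflexion_angle"),
    peak_hip_flexion_moment = peak(mh, "cycle", "peak_hip_flexion_moment"),
    peak_knee_flexion_moment_stance =
      peak(mk, "stance", "peak_knee_flexion_moment_stance"),
    peak_ankle_plantarflexion_moment =
      peak(-ma, "cycle", "peak_ankle_plantarflexion_moment"),
    peak_hip_power_pushoff = peak(ph, "pushoff", "peak_hip_power_pushoff"),
    min_knee_power_stance =
      peak(pk, "stance", "min_knee_power_stance", maximize = FALSE),
    peak_ankle_power_pushoff = peak(pa, "pushoff", "peak_ankle_power_pushoff")
  )
}

CROUCH_LEVELS <- c("typically developing", "mild crouch", "moderate crouch",
                   "severe crouch")

#' Classify crouch-gait severity from minimum stance knee flexion
#'
#' Minimum knee flexion angle during stance below 15 degrees is typically
#' developing, 15-30 mild crouch, 30-50 moderate crouch, and above 50
#' severe crouch. Boundary convention: a boundary value belongs to the
#' higher-severity class (15 is mild, 30 moderate, 50 severe).
#'
#' @param min_knee_flexion_stance angle(s), deg; vectorized
#' @return factor with levels "typically developing", "mild crouch",
#'   "moderate crouch", "severe crouch"
#' @examples
#' classify_crouch(c(10, 15, 40, 55))
#' @export
classify_crouch <- function(min_knee_flexion_stance) {
  x <- as.numeric(min_knee_flexion_stance)
  if (any(!is.finite(x))) stop("crouch classification needs finite angles")
  cut(x, breaks = c(-Inf, 15, 30, 50, Inf), labels = CROUCH_LEVELS,
      right = FALSE)
}

#' Classification spread of an ensemble of knee-flexion minima
#'
#' Given the per-model minimum stance knee flexion angles of an uncertainty
#' ensemble, reports the angle range, every severity category the closed
#' range intersects, and whether the classification is ambiguous (more than
#' one category intersected, i.e. equally plausible models straddle a
#' boundary).
#'
#' @param min_knee_flexion_stance per-model angles, deg
#' @return list: `range` (c(min, max), deg), `categories` (character),
#'   `ambiguous` (logical)
#' @examples
#' classification_range(c(12, 14, 18))
#' @export
classification_range <- function(min_knee_flexion_stance) {
  x <- as.numeric(min_knee_flexion_stance)
  if (length(x) < 1L || any(!is.finite(x))) {
    stop("need at least one finite angle")
  }
  lo <- min(x)
  hi <- max(x)
  bounds <- c(15, 30, 50)
  # interval k covers [bounds[k-1], bounds[k]) with the lower edge inclusive
  hits <- c(lo < 15,
            hi >= 15 & lo < 30,
            hi >= 30 & lo < 50,
            hi >= 50)
  cats <- CROUCH_LEVELS[hits]
  list(range = c(lo, hi), categories = cats, ambiguous = length(cats) > 1L)
}

#' Per-level ranges of the peak metrics
#'
#' Collects the minimum and maximum of each peak metric across all models
#' at each uncertainty level (equally plausible models are summarized by
#' their range, not a distribution).
#'
#' @param peaks tibble with a `level` column (uncertainty level, m) and the
#'   nine peak-metric columns, one row per model
#' @return long tibble: `level`, `metric`, `min`, `max`, `width`
#' @export
metric_ranges <- function(peaks) {
  stopifnot(is.data.frame(peaks), "level" %in% names(peaks))
  present <- intersect(PEAK_METRIC_NAMES, names(peaks))
  if (length(present) == 0L) stop("no peak-metric columns found")
  peaks |>
    dplyr::select(dplyr::all_of(c("level", present))) |>
    tidyr::pivot_longer(dplyr::all_of(present), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(metric = factor(.data$metric, levels = PEAK_METRIC_NAMES),
                  width = .data$max - .data$min) |>
    dplyr::arrange(.data$level, .data$metric)
}
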