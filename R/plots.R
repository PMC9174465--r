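# ggplot2 visualizations: ensemble trajectory fans, peak-metric range bars
# per uncertainty level, and crouch-classification bars against the
# severity boundaries.

#' Ensemble trajectory fan plot
#'
#' Overlays every ensemble model's coordinate trajectory (thin, by level)
#' on the baseline model's trajectory (black), the standard way of showing
#' that a single IK solution is one member of a population of equally
#' plausible trajectories.
#'
#' @param run a [run_pipeline()] result
#' @param coordinates coordinate names to plot (default: the right-leg
#'   sagittal angles)
#' @param what `"angles"` (deg), `"moments"` (N m) or `"powers"` (W)
#' @return a ggplot object
#' @export
plot_trajectory_fans <- function(run, coordinates = NULL,
                                 what = c("angles", "moments", "powers")) {
  stopifnot(inherits(run, "uq_run"))
  what <- match.arg(what)
  coordinates <- coordinates %||%
    c("hip_flexion_r", "knee_flexion_r", "ankle_dorsiflexion_r")
  get_mat <- function(entry, base = FALSE) {
    src <- if (base) run$baseline else entry
    switch(what,
           angles = src$ik$coordinates * 180 / pi,
           moments = if (base) src$moments$moments else src$moments$moments,
           powers = src$powers$powers)
  }
  ok <- run$results[run$results$status == "ok", ]
  long_one <- function(M, id, lvl) {
    M <- M[, coordinates, drop = FALSE]
    tibble::tibble(
      time = rep(run$times, times = length(coordinates)),
      coordinate = rep(coordinates, each = length(run$times)),
      value = as.numeric(M), model = id, e = lvl)
  }
  ens <- dplyr::bind_rows(lapply(seq_len(nrow(ok)), function(i) {
    entry <- list(ik = ok$ik[[i]], moments = ok$moments[[i]],
                  powers = ok$powers[[i]])
    M <- switch(what, angles = entry$ik$coordinates * 180 / pi,
                moments = entry$moments$moments,
                powers = entry$powers$powers)
    long_one(M, paste0(ok$level_index[i], ".", ok$draw[i]), ok$e[i])
  }))
  base_M <- switch(what, angles = run$baseline$ik$coordinates * 180 / pi,
                   moments = run$baseline$moments$moments,
                   powers = run$baseline$powers$powers)
  base <- long_one(base_M, "baseline", NA_real_)
  ylab <- switch(what, angles = "angle (deg)", moments = "moment (N m)",
                 powers = "power (W)")
  ggplot2::ggplot(ens, ggplot2::aes(x = .data$time, y = .data$value,
                                    group = .data$model,
                                    colour = factor(.data$e))) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_line(data = base, colour = "black", linewidth = 0.7) +
    ggplot2::facet_wrap(~coordinate, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = ylab, colour = "e (m)") +
    ggplot2::theme_minimal()
}

#' Peak-metric range bars per uncertainty level
#'
#' @param report a [uncertainty_report()]
#' @return a ggplot object
#' @export
plot_metric_ranges <- function(report) {
  stopifnot(inherits(report, "uq_report"))
  rng <- report$ranges
  ggplot2::ggplot(rng, ggplot2::aes(x = factor(.data$level * 100))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "uncertainty level e (cm)", y = "peak value range") +
    ggplot2::theme_minimal()
}

#' Crouch-classification bars against the severity boundaries
#'
#' Horizontal bars of the ensemble's minimum-stance-knee-flexion range per
#' uncertainty level, drawn over the classification boundaries at 15, 30
#' and 50 degrees; a bar crossing a boundary is an ambiguous
#' classification.
#'
#' @param report a [uncertainty_report()]
#' @return a ggplot object
#' @export
plot_classification <- function(report) {
  stopifnot(inherits(report, "uq_report"))
  cls <- report$classification
  ggplot2::ggplot(cls, ggplot2::aes(y = factor(.data$e * 100))) +
    ggplot2::geom_vline(xintercept = c(15, 30, 50), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$knee_min,
                                         xmax = .data$knee_max),
                            height = 0.25) +
    ggplot2::labs(x = "minimum stance knee flexion (deg)",
                  y = "uncertainty level e (cm)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_metric_ranges
#' @param object a `uq_report`
#' @param ... unused
#' @export
autoplot.uq_report <- function(object, ...) plot_metric_ranges(object)

#' @rdname plot_trajectory_fans
#' @param object a `uq_run`
#' @param ... passed to [plot_trajectory_fans()]
#' @export
autoplot.uq_run <- function(object, ...) plot_trajectory_fans(object, ...)
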