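# The uncertainty-propagation pipeline: run every ensemble model through
# the identical IK -> filter/differentiate -> inverse dynamics -> joint
# power -> peak-metric chain using the same experimental inputs (marker
# data, weights, external loads), then summarize marker-error metrics and
# peak-metric ranges per uncertainty level.

#' Run one model through the analysis pipeline
#'
#' IK on the marker trajectories, unwrap/low-pass filter (default 6 Hz) and
#' differentiate the coordinates, inverse dynamics under the given external
#' loads, joint powers, and the nine peak metrics.
#'
#' @param model a [link_segment_model()]
#' @param trajectories a [marker_trajectories()]
#' @param loads an [external_loads()] (resampled onto the marker time base)
#' @param events a `gait_events` list; detected from `loads` when `NULL`
#' @param weights optional named IK weight overrides
#' @param cutoff low-pass cutoff, Hz
#' @param metrics a [gait_metric_spec()]
#' @param control an [ik_control()]
#' @return list: `ik` (`ik_solution`), `processed` (filtered coordinates and
#'   derivatives), `moments` (`joint_moments`), `powers` (`joint_powers`),
#'   `peaks` (one-row tibble), `events`
#' @export
run_single_model <- function(model, trajectories, loads, events = NULL,
                             weights = NULL, cutoff = 6,
                             metrics = gait_metric_spec(),
                             control = ik_control()) {
  loads <- resample_loads(loads, trajectories$times)
  if (is.null(events)) events <- detect_gait_events(loads)
  ik <- solve_ik(model, trajectories, weights = weights, control = control)
  proc <- process_coordinates(model, ik, cutoff = cutoff)
  id <- inverse_dynamics(model, proc$coordinates, proc$velocities,
                         proc$accelerations, loads = loads,
                         times = proc$times)
  pw <- joint_powers(id, proc$velocities)
  pk <- extract_peaks(proc$coordinates, id, pw, events, metrics = metrics)
  list(ik = ik, processed = proc, moments = id, powers = pw, peaks = pk,
       events = events)
}

#' Run the full ensemble through the pipeline
#'
#' Every ensemble model is analyzed with the identical experimental inputs:
#' the same marker trajectories, the same IK weights and the same external
#' loads. Marker errors of each model are measured against the original
#' model's marker positions along its own (baseline) IK solution, not
#' against the experimental markers. Per-model failures are recorded with
#' their provenance and do not stop the run.
#'
#' @param ensemble a [build_ensemble()] result (its reference model becomes
#'   the baseline)
#' @param trajectories a [marker_trajectories()]
#' @param loads an [external_loads()]
#' @param events optional `gait_events`; detected from `loads` when `NULL`
#' @param weights optional named IK weight overrides
#' @param tracked_markers markers over which RMSE metrics are computed
#'   (default: all model markers, i.e. the full lower-body set)
#' @param cutoff low-pass filter cutoff, Hz
#' @param metrics a [gait_metric_spec()]
#' @param control an [ik_control()]
#' @return object of class `uq_run`: `baseline` (the reference model's
#'   pipeline output), `results` (tibble: provenance, per-model outputs as
#'   list-columns, `status`), `failures` (character), plus the ensemble's
#'   config attributes
#' @export
run_pipeline <- function(ensemble, trajectories, loads, events = NULL,
                         weights = NULL, tracked_markers = NULL,
                         cutoff = 6, metrics = gait_metric_spec(),
                         control = ik_control()) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  cfg <- attr(ensemble, "config")
  ref_model <- attr(ensemble, "reference_model")
  loads <- resample_loads(loads, trajectories$times)
  if (is.null(events)) events <- detect_gait_events(loads)
  baseline <- run_single_model(ref_model, trajectories, loads,
                               events = events, weights = weights,
                               cutoff = cutoff, metrics = metrics,
                               control = control)
  # original-model marker positions along the baseline IK solution: the
  # reference against which ensemble marker errors are measured
  Tn <- n_frames(trajectories)
  M <- length(ref_model$compiled$marker_names)
  ref_pos <- array(0, c(3L, M, Tn))
  for (t in seq_len(Tn)) {
    ref_pos[, , t] <- forward_kinematics(ref_model,
                                         baseline$ik$coordinates[t, ])
  }
  tracked <- tracked_markers %||% ref_model$compiled$marker_names

  rows <- vector("list", nrow(ensemble))
  for (i in seq_len(nrow(ensemble))) {
    mdl <- ensemble$model[[i]]
    res <- tryCatch({
      out <- run_single_model(mdl, trajectories, loads, events = events,
                              weights = weights, cutoff = cutoff,
                              metrics = metrics, control = control)
      err <- marker_distance_matrix(mdl, out$ik$coordinates, ref_pos,
                                    ref_model$compiled$marker_names)
      list(out = out, err = err, status = "ok")
    }, error = function(e) {
      list(out = NULL, err = NULL,
           status = paste0("failed: ", conditionMessage(e)))
    })
    rows[[i]] <- tibble::tibble(
      level_index = ensemble$level_index[i], e = ensemble$e[i],
      draw = ensemble$draw[i], status = res$status,
      ik = list(if (res$status == "ok") res$out$ik),
      moments = list(if (res$status == "ok") res$out$moments),
      powers = list(if (res$status == "ok") res$out$powers),
      peaks = list(if (res$status == "ok") res$out$peaks),
      marker_error = list(res$err))
  }
  results <- dplyr::bind_rows(rows)
  failures <- results$status[results$status != "ok"]
  structure(
    list(baseline = baseline, results = results, failures = failures,
         events = events, tracked_markers = tracked, config = cfg,
         reference_model = ref_model, times = trajectories$times),
    class = "uq_run"
  )
}

# Frame-by-frame distances between a model's markers (posed at its own IK
# coordinates) and reference ground positions. Returns T x M, m.
marker_distance_matrix <- function(model, coordinates, ref_pos,
                                   marker_names) {
  Tn <- nrow(coordinates)
  D <- matrix(NA_real_, Tn, length(marker_names),
              dimnames = list(NULL, marker_names))
  for (t in seq_len(Tn)) {
    p <- forward_kinematics(model, coordinates[t, ])
    D[t, ] <- sqrt(colSums((p[, marker_names, drop = FALSE] -
                            ref_pos[, , t])^2))
  }
  D
}

#' Ensemble marker-error metrics
#'
#' The two scalar summaries of an ensemble's marker errors with respect to
#' the original model: the RMSE across tracked markers at each instant,
#' averaged over frames, maximized over models; and the single largest
#' marker error over all markers, frames and models.
#'
#' @param errors list of per-model T x M marker-distance matrices (m)
#' @param tracked markers included in the RMSE (default: all columns)
#' @return named list: `rmse_avg_frames_max_models`, `max_error_all` (m)
#' @export
marker_error_metrics <- function(errors, tracked = NULL) {
  errors <- errors[!vapply(errors, is.null, logical(1))]
  if (length(errors) == 0L) stop("no per-model marker errors supplied")
  per_model <- vapply(errors, function(E) {
    tr <- tracked %||% colnames(E)
    Et <- E[, tr, drop = FALSE]
    mean(sqrt(rowMeans(Et^2)))
  }, numeric(1))
  list(rmse_avg_frames_max_models = max(per_model),
       max_error_all = max(vapply(errors, max, numeric(1))))
}

#' Summarize an uncertainty run per level
#'
#' Builds the per-level report: marker-error metrics (RMSE averaged over
#' frames and maximized over models; maximum marker error over all frames
#' and models) and the min/max range of each of the nine peak metrics
#' across the level's analysis set. With nested ensembles
#' (`augment_previous = TRUE`) level k's analysis set contains all models
#' generated at levels 1..k, so ranges are weakly non-decreasing in e.
#'
#' @param run a [run_pipeline()] result
#' @return object of class `uq_report`: `marker_errors` (per-level tibble),
#'   `ranges` (long per-level tibble of metric ranges), `peaks` (per-model
#'   peaks with level provenance), `classification` (per-level crouch
#'   classification spread), `config`
#' @export
uncertainty_report <- function(run) {
  stopifnot(inherits(run, "uq_run"))
  cfg <- run$config
  ok <- run$results[run$results$status == "ok", ]
  if (nrow(ok) == 0L) stop("every ensemble model failed; no report")
  level_set <- function(li) {
    if (cfg$augment_previous) ok[ok$level_index <= li, ] else
      ok[ok$level_index == li, ]
  }
  lvls <- sort(unique(ok$level_index))
  me_rows <- list()
  peak_rows <- list()
  cls_rows <- list()
  for (li in lvls) {
    sub <- level_set(li)
    me <- marker_error_metrics(sub$marker_error, run$tracked_markers)
    me_rows[[li]] <- tibble::tibble(
      level_index = li, e = cfg$levels_e[li], n_models = nrow(sub),
      rmse_avg_frames_max_models = me$rmse_avg_frames_max_models,
      max_marker_error = me$max_error_all)
    pk <- dplyr::bind_rows(sub$peaks)
    pk$level <- cfg$levels_e[li]
    peak_rows[[li]] <- pk
    cr <- classification_range(pk$min_knee_flexion_angle_stance)
    cls_rows[[li]] <- tibble::tibble(
      level_index = li, e = cfg$levels_e[li],
      knee_min = cr$range[1L], knee_max = cr$range[2L],
      categories = paste(cr$categories, collapse = " | "),
      ambiguous = cr$ambiguous)
  }
  peaks <- dplyr::bind_rows(peak_rows)
  structure(
    list(marker_errors = dplyr::bind_rows(me_rows),
         ranges = metric_ranges(peaks), peaks = peaks,
         classification = dplyr::bind_rows(cls_rows),
         baseline_peaks = run$baseline$peaks, config = cfg,
         n_failures = length(run$failures)),
    class = "uq_report"
  )
}

#' @export
print.uq_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<uq_report: %s, levels %s m, n = %d per level%s>\n",
              cfg$strategy, paste(cfg$levels_e, collapse = "/"), cfg$n,
              if (x$n_failures > 0)
                sprintf(", %d failures", x$n_failures) else ""))
  cat("\nMarker errors (m):\n")
  print(as.data.frame(x$marker_errors), row.names = FALSE, digits = 4)
  cat("\nPeak-metric ranges:\n")
  print(as.data.frame(x$ranges), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname uncertainty_report
#' @param x a `uq_report`
#' @param ... unused
#' @export
tidy.uq_report <- function(x, ...) {
  x$ranges |>
    dplyr::mutate(metric = as.character(.data$metric))
}

#' @rdname uncertainty_report
#' @export
glance.uq_report <- function(x, ...) {
  me <- x$marker_errors
  tibble::tibble(
    strategy = x$config$strategy,
    n_levels = nrow(me),
    n_models = max(me$n_models),
    max_rmse = max(me$rmse_avg_frames_max_models),
    max_marker_error = max(me$max_marker_error),
    max_rmse_below_e = all(me$rmse_avg_frames_max_models <= me$e),
    ambiguous_levels = sum(x$classification$ambiguous),
    n_failures = x$n_failures
  )
}
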