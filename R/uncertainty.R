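# Ensemble generation: populations of equally plausible models whose marker
# positions stay within a prescribed uncertainty distance e of the original
# model's, produced either by perturbing marker registrations directly
# (uniform in a ball of radius e) or by resampling body-segment scale
# factors and accepting sets whose posed marker displacement stays within e.

#' Configuration of an uncertainty-propagation run
#'
#' @param strategy `"marker_registration"` or `"segment_scaling"`
#' @param levels_e strictly increasing uncertainty levels, m
#'   (default 0.5, 1, 1.5, 2 cm)
#' @param n models generated per level (>= 1)
#' @param scale_interval scale-factor sampling interval (segment scaling)
#' @param seed integer RNG seed; every draw derives its own sub-stream from
#'   it, so ensembles are reproducible and order-independent
#' @param rejection_cap maximum candidate draws per accepted scaled model
#' @param augment_previous if `TRUE` (default), each level's analysis set
#'   is the previous level's set augmented with `n` new models drawn at the
#'   new level, so sets are nested; if `FALSE`, every level stands alone
#'   with `n` fresh models
#' @param isotropic draw one scale factor per segment (`TRUE`, default) or
#'   an independent factor per segment axis
#' @param per_marker_e optional named vector overriding `e` for specific
#'   markers during registration perturbation
#' @return list of class `uncertainty_config`
#' @export
uncertainty_config <- function(strategy = c("marker_registration",
                                            "segment_scaling"),
                               levels_e = c(0.005, 0.010, 0.015, 0.020),
                               n = 100L, scale_interval = c(0.90, 1.10),
                               seed = 1L, rejection_cap = 100000L,
                               augment_previous = TRUE, isotropic = TRUE,
                               per_marker_e = NULL) {
  strategy <- match.arg(strategy)
  levels_e <- as.numeric(levels_e)
  if (length(levels_e) < 1L || any(levels_e <= 0) ||
      any(diff(levels_e) <= 0)) {
    stop("levels_e must be strictly increasing and positive")
  }
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  scale_interval <- as.numeric(scale_interval)
  if (length(scale_interval) != 2L || scale_interval[1L] <= 0 ||
      scale_interval[1L] >= scale_interval[2L]) {
    stop("scale_interval must be 0 < lo < hi")
  }
  structure(
    list(strategy = strategy, levels_e = levels_e, n = n,
         scale_interval = scale_interval, seed = as.integer(seed),
         rejection_cap = as.integer(rejection_cap),
         augment_previous = isTRUE(augment_previous),
         isotropic = isTRUE(isotropic), per_marker_e = per_marker_e),
    class = "uncertainty_config"
  )
}

#' Perturb a model's marker registrations
#'
#' Offsets every marker's local position independently by a draw uniform in
#' the closed ball of radius `e` (candidates uniform in the cube
#' `[-e, e]^3`, redrawn while outside the ball), leaving every other model
#' field untouched. Uses the current RNG state.
#'
#' @param model a [link_segment_model()]
#' @param e uncertainty level (ball radius), m; `e = 0` returns the model
#'   unchanged
#' @param per_marker_e optional named numeric vector giving individual
#'   radii for some markers
#' @return perturbed model; every offset has norm at most its marker's `e`
#' @examples
#' set.seed(1)
#' m2 <- perturb_markers(default_gait_model(), 0.01)
#' @export
perturb_markers <- function(model, e, per_marker_e = NULL) {
  stopifnot(inherits(model, "link_segment_model"))
  if (!is.numeric(e) || length(e) != 1L || e < 0) {
    stop("e must be a nonnegative scalar distance in metres")
  }
  mk <- model$markers
  radii <- rep(e, nrow(mk))
  if (!is.null(per_marker_e)) {
    unknown <- setdiff(names(per_marker_e), mk$name)
    if (length(unknown) > 0L) {
      stop("per_marker_e for unknown marker(s): ",
           paste(unknown, collapse = ", "))
    }
    radii[match(names(per_marker_e), mk$name)] <- as.numeric(per_marker_e)
  }
  if (all(radii == 0)) return(model)
  off <- runif_ball(nrow(mk), 1) * radii
  mk$lx <- mk$lx + off[, 1L]
  mk$ly <- mk$ly + off[, 2L]
  mk$lz <- mk$lz + off[, 3L]
  out <- model
  out$markers <- mk
  # marker moves leave the compiled index tables valid; sync positions only
  out$compiled$marker_local <- rbind(mk$lx, mk$ly, mk$lz)
  out
}

#' Sample an accepted scaled model
#'
#' Repeatedly draws per-segment scale factors uniformly from
#' `scale_interval`, scales the model, poses the scaled model by inverse
#' kinematics against the original model's calibration-pose marker
#' positions, and accepts the first candidate whose markers all lie within
#' `e` of their original counterparts. Uses the current RNG state.
#'
#' @param model a [link_segment_model()]
#' @param e acceptance distance, m (> 0)
#' @param scale_interval sampling interval for the factors
#' @param calibration_pose coordinate vector defining the comparison pose
#'   (default the neutral pose)
#' @param isotropic one factor per segment (default) or per axis
#' @param rejection_cap give up after this many rejected candidates
#' @param preserve_mass_properties passed to [scale_model()]
#' @return list: `model` (accepted scaled model, unposed), `factors`
#'   (`scale_factor_set`), `attempts`, `max_marker_distance` (m, at the
#'   accepted pose)
#' @export
sample_scaled_model <- function(model, e, scale_interval = c(0.90, 1.10),
                                calibration_pose = NULL, isotropic = TRUE,
                                rejection_cap = 100000L,
                                preserve_mass_properties = FALSE) {
  stopifnot(inherits(model, "link_segment_model"))
  if (!is.numeric(e) || length(e) != 1L || e <= 0) {
    stop("e must be a positive distance in metres")
  }
  pose <- if (is.null(calibration_pose)) neutral_pose(model) else
    check_q(model, calibration_pose)
  ref <- forward_kinematics(model, pose)
  seg_names <- names(model$segments)
  # pose-invariant prefilter: distances between markers on the same segment
  # cannot be altered by IK, so a candidate whose within-segment pair
  # distances move by more than 2e can never pass the posed check
  cc <- model$compiled
  pair_idx <- list()
  for (s in unique(cc$marker_seg)) {
    ms <- which(cc$marker_seg == s)
    if (length(ms) >= 2L) {
      cmb <- utils::combn(ms, 2L)
      pair_idx[[length(pair_idx) + 1L]] <-
        list(seg = s, i = cmb[1L, ], j = cmb[2L, ],
             d0 = sqrt(colSums((cc$marker_local[, cmb[1L, ], drop = FALSE] -
                                cc$marker_local[, cmb[2L, ], drop = FALSE])^2)))
    }
  }
  prefilter_pass <- function(fs) {
    for (pp in pair_idx) {
      f <- fs[[seg_names[pp$seg]]]
      d <- sqrt(colSums((f * (cc$marker_local[, pp$i, drop = FALSE] -
                              cc$marker_local[, pp$j, drop = FALSE]))^2))
      if (any(abs(d - pp$d0) > 2 * e)) return(FALSE)
    }
    TRUE
  }
  for (attempt in seq_len(rejection_cap)) {
    draw <- if (isotropic) {
      stats::runif(length(seg_names), scale_interval[1L], scale_interval[2L])
    } else {
      matrix(stats::runif(3L * length(seg_names), scale_interval[1L],
                          scale_interval[2L]), nrow = 3L)
    }
    fs <- scale_factors(.list = stats::setNames(
      if (is.matrix(draw)) lapply(seq_along(seg_names), function(i) draw[, i])
      else as.list(draw), seg_names))
    if (!prefilter_pass(fs)) next
    cand <- scale_model(model, fs,
                        preserve_mass_properties = preserve_mass_properties)
    chk <- check_scaled_model(cand, ref, pose)
    if (chk$max_distance <= e) {
      return(list(model = cand, factors = fs, attempts = attempt,
                  max_marker_distance = chk$max_distance))
    }
  }
  stop(sprintf(
    paste0("no scale-factor set accepted within %d draws at e = %g m; ",
           "increase e or narrow the scale interval"),
    rejection_cap, e))
}

# Pose a scaled candidate against reference marker positions and measure
# the worst marker distance. Shared by the sampler and by the independent
# re-check of accepted models.
check_scaled_model <- function(candidate, ref_markers, initial_guess,
                               control = ik_control()) {
  sol <- solve_ik_frame(candidate, ref_markers,
                        initial_guess = initial_guess, control = control)
  list(max_distance = max(sol$errors), pose = sol$q, errors = sol$errors)
}

#' Build an ensemble of perturbed models
#'
#' Generates `config$n` models at each uncertainty level with the
#' configured strategy. With `augment_previous = TRUE` the analysis set at
#' each level is nested: it contains every model generated at lower levels
#' plus `n` new models drawn at the current level. Fully reproducible from
#' `config$seed`; each (level, draw) pair uses its own derived RNG
#' sub-stream.
#'
#' @param model the original (reference) [link_segment_model()]
#' @param config an [uncertainty_config()]
#' @return object of class `model_ensemble`: a tibble with one row per
#'   generated model (`level_index`, `e`, `draw`, `seed_used`, `model`,
#'   `factors`, `attempts`) plus the config and reference model as
#'   attributes
#' @examples
#' ens <- build_ensemble(default_gait_model(),
#'   uncertainty_config("marker_registration", levels_e = 0.01, n = 2))
#' nrow(ens)
#' @export
build_ensemble <- function(model, config) {
  stopifnot(inherits(model, "link_segment_model"),
            inherits(config, "uncertainty_config"))
  rows <- list()
  for (li in seq_along(config$levels_e)) {
    e <- config$levels_e[li]
    for (d in seq_len(config$n)) {
      sd <- derive_seed(config$seed, li, d)
      set.seed(sd)
      if (config$strategy == "marker_registration") {
        mdl <- perturb_markers(model, e, per_marker_e = config$per_marker_e)
        fct <- NULL
        att <- 1L
      } else {
        smp <- sample_scaled_model(
          model, e, scale_interval = config$scale_interval,
          isotropic = config$isotropic,
          rejection_cap = config$rejection_cap)
        mdl <- smp$model
        fct <- smp$factors
        att <- smp$attempts
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level_index = li, e = e, draw = d, seed_used = sd,
        model = list(mdl), factors = list(fct), attempts = att)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "reference_model") <- model
  class(out) <- c("model_ensemble", class(out))
  out
}

#' Models in a level's analysis set
#'
#' With nested augmentation the analysis set of level `k` contains every
#' model generated at levels `1..k`; without it, only level `k`'s own
#' models.
#'
#' @param ensemble a [build_ensemble()] result
#' @param level_index level number (1-based)
#' @return the subset of ensemble rows in the level's analysis set
#' @export
ensemble_members <- function(ensemble, level_index) {
  cfg <- attr(ensemble, "config")
  stopifnot(inherits(ensemble, "model_ensemble"), !is.null(cfg))
  if (cfg$augment_previous) {
    ensemble[ensemble$level_index <= level_index, ]
  } else {
    ensemble[ensemble$level_index == level_index, ]
  }
}

#' @export
print.model_ensemble <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<model_ensemble: %s, %d models (%d level(s) x n = %d), seed %d, %s>\n",
    cfg$strategy, nrow(x), length(cfg$levels_e), cfg$n, cfg$seed,
    if (cfg$augment_previous) "nested" else "independent levels"))
  NextMethod()
}
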