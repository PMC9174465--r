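# Ensemble samplers, nesting, marker-error metrics, peaks and
# classification.

test_that("ball draws are uniform in the ball (radius CDF and moments)", {
  set.seed(41)
  n <- 20000L
  x <- runif_ball(n, 1)
  r <- sqrt(rowSums(x^2))
  expect_lte(max(r), 1)
  # P(R <= r) = r^3 for the uniform ball, so r^3 must be standard uniform
  ks <- suppressWarnings(stats::ks.test(r^3, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(r) - 0.75), 0.01)
  # components are mean-zero and symmetric
  expect_lt(max(abs(colMeans(x))), 0.01)
})

test_that("marker perturbation respects e exactly and touches nothing else", {
  m <- default_gait_model()
  set.seed(42)
  expect_identical(perturb_markers(m, 0), m)
  for (e in c(0.005, 0.02)) {
    p <- perturb_markers(m, e)
    off <- cbind(p$markers$lx - m$markers$lx, p$markers$ly - m$markers$ly,
                 p$markers$lz - m$markers$lz)
    expect_lte(max(sqrt(rowSums(off^2))), e)
    expect_gt(max(sqrt(rowSums(off^2))), 0)
    expect_identical(p$segments, m$segments)
    expect_identical(p$markers$weight, m$markers$weight)
  }
  # per-marker radii override the global level
  p2 <- perturb_markers(m, 0.01, per_marker_e = c(RASI = 0))
  expect_identical(p2$markers$lx[p2$markers$name == "RASI"],
                   m$markers$lx[m$markers$name == "RASI"])
  expect_error(perturb_markers(m, -1), "nonnegative")
})

test_that("scale sampling accepts unit factors at once and rejects impossible intervals", {
  m <- default_gait_model()
  # interval collapsed at 1: zero marker displacement, accepted immediately
  set.seed(43)
  s <- sample_scaled_model(m, 0.005, scale_interval = c(1 - 1e-9, 1 + 1e-9))
  expect_equal(s$attempts, 1L)
  expect_lt(s$max_marker_distance, 1e-6)
  # factors pinned near 1.1 move distal markers centimetres; e = 5 mm
  # cannot be met and the sampler reports the cap
  expect_error(
    sample_scaled_model(m, 0.005, scale_interval = c(1.099, 1.10),
                        rejection_cap = 25L),
    "increase e|narrow")
})

test_that("accepted scaled models stay within e at the calibration pose", {
  m <- default_gait_model()
  pose <- neutral_pose(m)
  ref <- forward_kinematics(m, pose)
  set.seed(44)
  for (rep in 1:3) {
    s <- sample_scaled_model(m, 0.01)
    # independent re-check of the acceptance condition
    chk <- mocapuq:::check_scaled_model(s$model, ref, pose)
    expect_lte(chk$max_distance, 0.01)
    f <- do.call(rbind, s$factors)
    expect_true(all(f >= 0.9 & f <= 1.1))
  }
})

test_that("ensembles are seeded, nested and size-checked", {
  m <- default_gait_model()
  cfg <- uncertainty_config("marker_registration",
                            levels_e = c(0.005, 0.01), n = 2, seed = 99)
  e1 <- build_ensemble(m, cfg)
  e2 <- build_ensemble(m, cfg)
  expect_identical(e1$model, e2$model)
  expect_equal(nrow(e1), 4L)
  # level-2 analysis set contains both level-1 models plus 2 new ones
  lvl2 <- ensemble_members(e1, 2)
  expect_equal(nrow(lvl2), 4L)
  expect_identical(lvl2$model[lvl2$level_index == 1], e1$model[e1$level_index == 1])
  lvl1 <- ensemble_members(e1, 1)
  expect_equal(nrow(lvl1), 2L)
  # without augmentation each level stands alone
  cfg_i <- uncertainty_config("marker_registration",
                              levels_e = c(0.005, 0.01), n = 2, seed = 99,
                              augment_previous = FALSE)
  ei <- build_ensemble(m, cfg_i)
  expect_equal(nrow(ensemble_members(ei, 2)), 2L)
  expect_error(uncertainty_config("marker_registration", n = 0), "at least 1")
  expect_error(uncertainty_config("marker_registration",
                                  levels_e = c(0.01, 0.005)), "increasing")
})

test_that("every registration offset in an ensemble respects its level", {
  m <- default_gait_model()
  cfg <- uncertainty_config("marker_registration",
                            levels_e = c(0.005, 0.015), n = 4, seed = 7)
  ens <- build_ensemble(m, cfg)
  for (i in seq_len(nrow(ens))) {
    p <- ens$model[[i]]
    off <- cbind(p$markers$lx - m$markers$lx, p$markers$ly - m$markers$ly,
                 p$markers$lz - m$markers$lz)
    expect_lte(max(sqrt(rowSums(off^2))), ens$e[i])
  }
})

test_that("marker-error metrics match a naive double-loop recomputation", {
  set.seed(45)
  errs <- lapply(1:4, function(i) {
    matrix(abs(stats::rnorm(5 * 3, 0.005, 0.003)), 5, 3,
           dimnames = list(NULL, c("A", "B", "C")))
  })
  got <- marker_error_metrics(errs)
  per_model <- numeric(4)
  mx <- -Inf
  for (i in 1:4) {
    frame_rmse <- numeric(5)
    for (t in 1:5) {
      acc <- 0
      for (j in 1:3) {
        acc <- acc + errs[[i]][t, j]^2
        mx <- max(mx, errs[[i]][t, j])
      }
      frame_rmse[t] <- sqrt(acc / 3)
    }
    per_model[i] <- mean(frame_rmse)
  }
  expect_equal(got$rmse_avg_frames_max_models, max(per_model),
               tolerance = 1e-12)
  expect_equal(got$max_error_all, mx, tolerance = 1e-12)
  # constant error d at every frame and marker gives (d, d)
  cst <- list(matrix(0.004, 6, 3, dimnames = list(NULL, c("A", "B", "C"))))
  expect_equal(marker_error_metrics(cst),
               list(rmse_avg_frames_max_models = 0.004,
                    max_error_all = 0.004))
  expect_error(marker_error_metrics(list()), "no per-model")
})

test_that("peak extraction equals a brute-force windowed scan", {
  trial <- get_trial(rate = 60)
  base <- run_single_model(trial$model, trial$trajectories, trial$loads,
                           events = trial$events)
  pk <- base$peaks
  ang <- base$processed$coordinates * 180 / pi
  mom <- base$moments$moments
  pow <- base$powers$powers
  st <- trial$events$stance_frames
  po <- trial$events$pushoff_frames
  expect_equal(pk$peak_hip_extension_angle, max(-ang[, "hip_flexion_r"]))
  expect_equal(pk$min_knee_flexion_angle_stance,
               min(ang[st, "knee_flexion_r"]))
  expect_equal(pk$peak_ankle_plantarflexion_angle,
               max(-ang[, "ankle_dorsiflexion_r"]))
  expect_equal(pk$peak_hip_flexion_moment, max(mom[, "hip_flexion_r"]))
  expect_equal(pk$peak_knee_flexion_moment_stance,
               max(mom[st, "knee_flexion_r"]))
  expect_equal(pk$peak_ankle_plantarflexion_moment,
               max(-mom[, "ankle_dorsiflexion_r"]))
  expect_equal(pk$peak_hip_power_pushoff, max(pow[po, "hip_flexion_r"]))
  expect_equal(pk$min_knee_power_stance, min(pow[st, "knee_flexion_r"]))
  expect_equal(pk$peak_ankle_power_pushoff,
               max(pow[po, "ankle_dorsiflexion_r"]))
})

test_that("constructed extrema and degenerate inputs round-trip through peaks", {
  Tn <- 20L
  nm <- c("hip_flexion_r", "knee_flexion_r", "ankle_dorsiflexion_r")
  zero <- matrix(0, Tn, 3, dimnames = list(NULL, nm))
  ev <- structure(list(stance_frames = 1:12, pushoff_frames = 8:12),
                  class = "gait_events")
  pk0 <- extract_peaks(zero, zero, zero, ev)
  expect_true(all(as.numeric(pk0) == 0))
  ang <- zero
  ang[7, "knee_flexion_r"] <- -5 * pi / 180  # injected stance minimum
  ang[15, "knee_flexion_r"] <- -30 * pi / 180 # outside stance; ignored
  pk <- extract_peaks(ang, zero, zero, ev)
  expect_equal(pk$min_knee_flexion_angle_stance, -5)
  ev_bad <- structure(list(stance_frames = integer(0), pushoff_frames = 1:2),
                      class = "gait_events")
  expect_error(extract_peaks(zero, zero, zero, ev_bad),
               "min_knee_flexion_angle_stance")
})

test_that("crouch classification applies the boundary convention", {
  got <- classify_crouch(c(10, 14.99, 15, 29.99, 30, 49.99, 50, 50.01, 70))
  expect_equal(as.character(got),
               c("typically developing", "typically developing",
                 "mild crouch", "mild crouch", "moderate crouch",
                 "moderate crouch", "severe crouch", "severe crouch",
                 "severe crouch"))
  expect_error(classify_crouch(NaN), "finite")
})

test_that("classification ranges flag boundary-straddling ensembles", {
  r <- classification_range(c(20, 22, 25))
  expect_equal(r$categories, "mild crouch")
  expect_false(r$ambiguous)
  r2 <- classification_range(c(12, 18))
  expect_setequal(r2$categories, c("typically developing", "mild crouch"))
  expect_true(r2$ambiguous)
  r3 <- classification_range(30)
  expect_equal(r3$categories, "moderate crouch")
  expect_equal(r3$range, c(30, 30))
  r4 <- classification_range(c(14, 51))
  expect_length(r4$categories, 4L)
})

test_that("metric ranges collapse singletons and cover pairs", {
  pk <- tibble::tibble(level = c(0.01, 0.01), peak_hip_extension_angle = c(10, 20),
                       min_knee_flexion_angle_stance = c(5, 5))
  rng <- metric_ranges(pk)
  hip <- rng[rng$metric == "peak_hip_extension_angle", ]
  expect_equal(c(hip$min, hip$max), c(10, 20))
  knee <- rng[rng$metric == "min_knee_flexion_angle_stance", ]
  expect_equal(knee$width, 0)
})
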