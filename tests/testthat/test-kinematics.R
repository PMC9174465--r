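# Inverse kinematics, filtering and differentiation.

test_that("IK returns the generating pose at a zero-residual fixed point", {
  m <- default_gait_model()
  set.seed(21)
  q_true <- neutral_pose(m) + stats::runif(16, -0.4, 0.4)
  obs <- forward_kinematics(m, q_true)
  sol <- solve_ik_frame(m, obs, initial_guess = q_true)
  expect_lt(max(sol$errors), 1e-8)
  sol2 <- solve_ik_frame(m, obs, initial_guess = neutral_pose(m))
  expect_lt(max(sol2$errors), 1e-8)
  expect_lt(max(abs(sol2$q - q_true)), 1e-6)
})

test_that("free-segment IK reproduces a rigid transform (Kabsch oracle)", {
  seg <- segment("body", NA,
                 joint_spec("free", list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
                            c("tx", "ty", "tz", "rz", "rx", "ry")),
                 c(0, 0, 0), mass = 1)
  mk <- dplyr::bind_rows(
    marker_registration("M1", "body", c(0.1, 0, 0)),
    marker_registration("M2", "body", c(0, 0.15, 0)),
    marker_registration("M3", "body", c(-0.05, 0, 0.12)),
    marker_registration("M4", "body", c(0.07, -0.09, -0.04)))
  m <- link_segment_model(list(seg), mk)
  P <- forward_kinematics(m, neutral_pose(m))
  set.seed(22)
  for (rep in 1:4) {
    ang <- stats::runif(3, -0.8, 0.8)
    R <- (function(a) {
      Rz <- cbind(c(cos(a[1]), sin(a[1]), 0), c(-sin(a[1]), cos(a[1]), 0),
                  c(0, 0, 1))
      Rx <- rbind(c(1, 0, 0), c(0, cos(a[2]), -sin(a[2])),
                  c(0, sin(a[2]), cos(a[2])))
      Ry <- rbind(c(cos(a[3]), 0, sin(a[3])), c(0, 1, 0),
                  c(-sin(a[3]), 0, cos(a[3])))
      Rz %*% Rx %*% Ry
    })(ang)
    tr <- stats::runif(3, -0.5, 0.5)
    obs <- R %*% P + tr
    colnames(obs) <- colnames(P)
    sol <- solve_ik_frame(m, obs)
    expect_lt(max(sol$errors), 1e-6)
    # recovered pose reproduces the same rigid transform per Kabsch
    kb <- kabsch_fit(P, obs)
    fit <- forward_kinematics(m, sol$q)
    expect_lt(max(abs(fit - (kb$R %*% P + as.numeric(kb$t)))), 1e-6)
  }
})

test_that("a single offset marker yields the least-squares compromise found by grid search", {
  # one pin coordinate, two markers, one displaced 1 cm: brute-force the
  # 1-dof objective at 1e-4 rad resolution and compare
  m <- link_segment_model(
    list(segment("seg", NA, joint_spec("pin", list(c(0, 0, 1)), "theta"),
                 c(0, 0, 0))),
    dplyr::bind_rows(
      marker_registration("P1", "seg", c(0.3, 0, 0)),
      marker_registration("P2", "seg", c(0, -0.25, 0.05)),
      marker_registration("P3", "seg", c(-0.1, 0.2, -0.03))))
  th0 <- 0.4
  obs <- forward_kinematics(m, c(theta = th0))
  # displace P1 by 1 cm normal to its lever arm (in the rotation plane)
  dir <- c(-sin(th0), cos(th0), 0)
  obs[, "P1"] <- obs[, "P1"] + 0.01 * dir
  sol <- solve_ik_frame(m, obs, initial_guess = c(theta = th0))
  grid <- seq(th0 - 0.05, th0 + 0.05, by = 1e-4)
  objective <- vapply(grid, function(th) {
    fk <- forward_kinematics(m, c(theta = th))
    sum((fk - obs)^2)
  }, numeric(1))
  th_grid <- grid[which.min(objective)]
  expect_lt(abs(sol$q[["theta"]] - th_grid), 1e-4)
  expect_lte(sol$objective, min(objective) + 1e-12)
  # residual splits between the two markers, not all on the offset one
  expect_gt(sol$errors[["P2"]], 0)
  expect_lt(sol$errors[["P1"]], 0.01)
})

test_that("under-determined frames fail loudly", {
  m <- default_gait_model()
  obs <- forward_kinematics(m, neutral_pose(m))
  expect_error(solve_ik_frame(m, obs[, 1:2]), "under-determined")
  # collinear markers
  mc <- link_segment_model(
    list(segment("seg", NA, joint_spec("pin", list(c(0, 0, 1)), "th"),
                 c(0, 0, 0))),
    dplyr::bind_rows(
      marker_registration("A", "seg", c(0.1, 0, 0)),
      marker_registration("B", "seg", c(0.2, 0, 0)),
      marker_registration("C", "seg", c(0.3, 0, 0))))
  obs_c <- forward_kinematics(mc, c(th = 0))
  expect_error(solve_ik_frame(mc, obs_c), "collinear")
})

test_that("trajectory IK recovers noise-free synthetic coordinates", {
  trial <- get_trial(rate = 60)
  ik <- solve_ik(trial$model, trial$trajectories)
  expect_lt(max(abs(ik$coordinates - trial$q)), 1e-6)
  expect_lt(max(ik$rmse_per_frame), 1e-7)
  # rmse_per_frame is the RMS of per-marker errors at each frame
  E <- ik$per_marker_error
  expect_equal(ik$rmse_per_frame, sqrt(rowMeans(E^2)), tolerance = 1e-12)
})

test_that("constant pose solves identically every frame and is batch-invariant", {
  m <- default_gait_model()
  q0 <- neutral_pose(m) + 0.1
  obs <- forward_kinematics(m, q0)
  Tn <- 10L
  xyz <- array(rep(obs, Tn), c(3, ncol(obs), Tn),
               dimnames = list(NULL, colnames(obs), NULL))
  tr <- marker_trajectories(seq(0, by = 0.01, length.out = Tn), xyz)
  ik <- solve_ik(m, tr)
  for (t in 2:Tn) expect_identical(ik$coordinates[t, ], ik$coordinates[1, ])
  # batching invariance: all frames vs two halves with carried guess
  trial <- get_trial(rate = 60)
  full <- solve_ik(trial$model, trial$trajectories)
  Tn2 <- n_frames(trial$trajectories)
  half <- floor(Tn2 / 2)
  tr1 <- marker_trajectories(trial$times[1:half],
                             trial$trajectories$xyz[, , 1:half, drop = FALSE])
  tr2 <- marker_trajectories(trial$times[(half + 1):Tn2],
                             trial$trajectories$xyz[, , (half + 1):Tn2,
                                                    drop = FALSE])
  ik1 <- solve_ik(trial$model, tr1)
  ik2 <- solve_ik(trial$model, tr2,
                  initial_guess = ik1$coordinates[half, ])
  expect_identical(rbind(ik1$coordinates, ik2$coordinates),
                   full$coordinates)
})

test_that("missing samples drop markers from the frame objective", {
  trial <- get_trial(rate = 60)
  xyz <- trial$trajectories$xyz
  xyz[, "TOE_R", 5] <- NA
  tr <- marker_trajectories(trial$times, xyz)
  ik <- solve_ik(trial$model, tr)
  expect_true(is.na(ik$per_marker_error[5, "TOE_R"]))
  # equals the solve without that marker entirely at that frame
  obs <- trial$trajectories$xyz[, , 5]
  obs_wo <- obs[, colnames(obs) != "TOE_R"]
  guess <- ik$coordinates[4, ]
  a <- solve_ik_frame(trial$model, obs_wo, initial_guess = guess)
  expect_equal(unname(ik$coordinates[5, ]), unname(a$q))
})

test_that("dropping a marker (weight zero) never increases the IK objective", {
  m <- default_gait_model()
  set.seed(23)
  q_true <- neutral_pose(m) + stats::runif(16, -0.3, 0.3)
  obs <- forward_kinematics(m, q_true)
  obs <- obs + matrix(stats::rnorm(length(obs), 0, 0.01), nrow = 3)
  full <- solve_ik_frame(m, obs)
  for (drop in c("RASI", "TOE_R", "SHA_L_L")) {
    w <- stats::setNames(0, drop)
    red <- solve_ik_frame(m, obs, weights = w, initial_guess = full$q)
    expect_lte(red$objective, full$objective + 1e-12)
  }
})

test_that("zero-phase filter has unit DC gain and the designed band behavior", {
  x <- rep(3.7, 120)
  expect_lt(max(abs(lowpass_filter(x, 100, 6) - 3.7)), 1e-10)
  t <- seq(0, 2, by = 0.01)
  lo <- sin(2 * pi * 1 * t)
  y <- lowpass_filter(lo, 100, 6)
  mid <- 50:150
  expect_lt(max(abs(y[mid] - lo[mid])) / max(abs(lo)), 0.01)
  hi <- sin(2 * pi * 30 * t)
  z <- lowpass_filter(hi, 100, 6)
  atten <- max(abs(z[mid])) / max(abs(hi))
  expect_lt(20 * log10(atten), -20)
  expect_error(lowpass_filter(lo, 10, 6), "Nyquist")
})

test_that("differentiation is exact for low-degree polynomials", {
  t <- seq(0, 1, by = 0.01)
  d <- differentiate(2 * t, t)
  expect_equal(d$velocities, rep(2, length(t)), tolerance = 1e-12)
  expect_equal(d$accelerations[3:(length(t) - 2)],
               rep(0, length(t) - 4), tolerance = 1e-9)
  d2 <- differentiate(t^2, t)
  interior <- 2:(length(t) - 1)
  expect_equal(d2$accelerations[3:(length(t) - 2)],
               rep(2, length(t) - 4), tolerance = 1e-9)
  expect_error(differentiate(c(1, 2), c(0, 1)), "3 frames")
  expect_error(differentiate(1:5, c(0, 1, 2, 3.5, 4)), "uniform")
})

test_that("derivative error of a sampled sinusoid shrinks at second order", {
  errs <- vapply(c(0.01, 0.005), function(dt) {
    t <- seq(0, 1, by = dt)
    d <- differentiate(sin(2 * pi * t), t)
    interior <- 3:(length(t) - 2)
    max(abs(d$velocities[interior] - 2 * pi * cos(2 * pi * t[interior])))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.5)  # ~4 for O(dt^2)
})

test_that("filter + differentiate tracks the analytic derivative of a band-limited signal", {
  rate <- 100
  t <- seq(0, 2, by = 1 / rate)
  f <- 2  # Hz, below cutoff/2 = 3 Hz
  x <- sin(2 * pi * f * t)
  v <- differentiate(lowpass_filter(x, rate, 6), t)$velocities
  v_true <- 2 * pi * f * cos(2 * pi * f * t)
  interior <- 25:(length(t) - 24)
  expect_lt(max(abs(v[interior] - v_true[interior])) / max(abs(v_true)),
            0.02)
})
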