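# Inverse dynamics and joint powers.

test_that("zero gravity, zero motion, no loads give zero moments", {
  m <- default_gait_model()
  q <- neutral_pose(m)
  z <- matrix(0, 1, length(q))
  id <- inverse_dynamics(m, matrix(q, 1), z, z, gravity = c(0, 0, 0))
  expect_lt(max(abs(id$moments)), 1e-12)
  expect_lt(max(abs(id$residual$force)), 1e-12)
})

test_that("static pendulum matches the closed-form gravity moment", {
  mass <- 2; d <- 0.3
  pend <- make_pendulum(mass = mass, d = d)
  g <- 9.80665
  for (th in c(-1.1, 0, 0.3, 0.7, 1.5)) {
    id <- inverse_dynamics(pend, th, 0, 0)
    expect_equal(unname(id$moments[1, "theta"]), mass * g * d * sin(th),
                 tolerance = 1e-12)
  }
})

test_that("prescribed-motion pendulum matches the analytic equation of motion", {
  mass <- 2; d <- 0.3; I <- 0.04
  pend <- make_pendulum(mass = mass, d = d, I = I)
  g <- 9.80665
  t <- seq(0, 2, by = 0.01)
  q <- matrix(0.8 * sin(2 * t), ncol = 1)
  qd <- matrix(1.6 * cos(2 * t), ncol = 1)
  qdd <- matrix(-3.2 * sin(2 * t), ncol = 1)
  id <- inverse_dynamics(pend, q, qd, qdd, times = t)
  tau <- (I + mass * d^2) * qdd + mass * g * d * sin(q)
  expect_lt(max(abs(id$moments[, 1] - tau)), 1e-8)
})

test_that("moments are linear in external loads at fixed kinematics", {
  m <- default_gait_model()
  set.seed(31)
  q <- matrix(neutral_pose(m) + stats::runif(16, -0.3, 0.3), 1)
  qd <- matrix(stats::runif(16, -1, 1), 1)
  qdd <- matrix(stats::runif(16, -5, 5), 1)
  mk_spec <- function(seed, seg) {
    set.seed(seed)
    list(segment = seg, force = stats::runif(3, -300, 300),
         point = stats::runif(3, -0.5, 0.5),
         torque = stats::runif(3, -20, 20))
  }
  s1 <- mk_spec(1, "foot_r"); s2 <- mk_spec(2, "shank_l")
  l1 <- external_loads(0, s1)
  l2 <- external_loads(0, s2)
  l12 <- external_loads(0, s1, s2)
  id <- function(l) inverse_dynamics(m, q, qd, qdd, loads = l,
                                     times = 0)$moments
  expect_lt(max(abs(id(l12) - (id(l1) + id(l2) - id(NULL)))), 1e-10)
})

test_that("joint power is the elementwise moment-velocity product", {
  pw <- joint_powers(matrix(c(100, -50), 1), matrix(c(2, 0), 1))
  expect_equal(as.numeric(pw$powers), c(200, 0))
  expect_error(joint_powers(matrix(1, 1, 2), matrix(1, 1, 3)), "shape")
})

test_that("total joint power balances mechanical energy on a conservative trajectory", {
  mass <- 2; d <- 0.3; I <- 0.04
  pend <- make_pendulum(mass = mass, d = d, I = I)
  g <- 9.80665
  t <- seq(0, 2, by = 0.002)
  q <- 0.8 * sin(2 * t); qd <- 1.6 * cos(2 * t); qdd <- -3.2 * sin(2 * t)
  id <- inverse_dynamics(pend, matrix(q, ncol = 1), matrix(qd, ncol = 1),
                         matrix(qdd, ncol = 1), times = t)
  P <- joint_powers(id, matrix(qd, ncol = 1))$powers[, 1]
  E <- 0.5 * (I + mass * d^2) * qd^2 - mass * g * d * cos(q)
  dE <- diff(E) / diff(t)
  Pmid <- (P[-1] + P[-length(P)]) / 2
  expect_lt(max(abs(dE - Pmid)) / max(abs(Pmid)), 0.01)
})

test_that("inverse-dynamics moments drive forward dynamics back to the accelerations", {
  m <- make_chain(4)
  set.seed(32)
  q <- stats::runif(4, -1, 1)
  qd <- stats::runif(4, -2, 2)
  qdd <- stats::runif(4, -5, 5)
  id <- inverse_dynamics(m, matrix(q, 1), matrix(qd, 1), matrix(qdd, 1))
  acc <- forward_dynamics_acc(m, q, qd, id$moments[1, ])
  expect_lt(max(abs(acc - qdd)), 1e-6)
  # and on the gait model including the free base residual coordinates
  g <- default_gait_model()
  qg <- neutral_pose(g) + stats::runif(16, -0.3, 0.3)
  qgd <- stats::runif(16, -1, 1)
  qgdd <- stats::runif(16, -4, 4)
  idg <- inverse_dynamics(g, matrix(qg, 1), matrix(qgd, 1), matrix(qgdd, 1))
  accg <- forward_dynamics_acc(g, qg, qgd, idg$moments[1, ])
  expect_lt(max(abs(accg - qgdd)), 1e-6)
})

test_that("the free-base residual wrench is reported, not hidden", {
  trial <- get_trial(rate = 60)
  # without the generated loads the base residual is the whole-body wrench
  id0 <- inverse_dynamics(trial$model, trial$q, trial$qdot, trial$qddot,
                          times = trial$times)
  expect_gt(max(abs(id0$residual$force[, 2])), 500)  # ~body weight, N
  # with the dynamically consistent loads it collapses to zero
  expect_lt(max(abs(trial$true_moments$residual$force)), 1e-9)
  expect_lt(max(abs(trial$true_moments$residual$moment)), 1e-9)
})

test_that("unknown load segments and shape mismatches are domain errors", {
  m <- make_chain(2)
  l <- external_loads(0, list(segment = "nope", force = c(0, 1, 0),
                              point = c(0, 0, 0), torque = c(0, 0, 0)))
  expect_error(inverse_dynamics(m, matrix(0, 1, 2), matrix(0, 1, 2),
                                matrix(0, 1, 2), loads = l, times = 0),
               "unknown segment")
  expect_error(inverse_dynamics(m, matrix(0, 1, 3), matrix(0, 1, 2),
                                matrix(0, 1, 2)), "T x 2")
})
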