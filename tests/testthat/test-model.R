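# Model construction, forward kinematics and scaling.

test_that("forward kinematics handles identity and pure-rotation poses", {
  m <- link_segment_model(
    list(segment("seg", NA, joint_spec("pin", list(c(0, 0, 1)), "theta"),
                 location_in_parent = c(0, 0, 0))),
    dplyr::bind_rows(
      marker_registration("M", "seg", c(0.1, 0, 0)),
      marker_registration("L", "seg", c(0.4, 0, 0)),
      marker_registration("O", "seg", c(0, 0.05, 0))))
  fk0 <- forward_kinematics(m, c(theta = 0))
  expect_equal(unname(fk0[, "M"]), c(0.1, 0, 0))
  fk90 <- forward_kinematics(m, c(theta = pi / 2))
  expect_equal(unname(fk90[, "L"]), c(0, 0.4, 0), tolerance = 1e-12)
})

test_that("forward kinematics matches the homogeneous-transform oracle", {
  set.seed(11)
  for (n in c(2, 3, 5)) {
    m <- make_chain(n)
    for (rep in 1:5) {
      q <- stats::runif(n, -2, 2)
      names(q) <- model_coordinates(m)$name
      expect_lt(max(abs(forward_kinematics(m, q) - naive_marker_fk(m, q))),
                1e-12)
    }
  }
  # and on the full gait model with a free base and ball joints
  g <- default_gait_model()
  for (rep in 1:5) {
    q <- neutral_pose(g) + stats::runif(16, -0.8, 0.8)
    expect_lt(max(abs(forward_kinematics(g, q) - naive_marker_fk(g, q))),
              1e-12)
  }
})

test_that("coordinate validation rejects unknown names and out-of-bounds", {
  m <- make_chain(2)
  q <- neutral_pose(m)
  names(q)[1] <- "nope"
  expect_error(forward_kinematics(m, q), "nope")
  q2 <- neutral_pose(m)
  q2[1] <- 10
  expect_error(forward_kinematics(m, q2), "out of bounds")
})

test_that("model validation enforces the structural invariants", {
  seg_ok <- segment("a", NA, joint_spec("pin", list(c(0, 0, 1)), "qa"),
                    c(0, 0, 0))
  mk <- marker_registration("M", "a", c(0, 0, 0))
  # duplicate coordinate names across joints
  seg_b <- segment("b", "a", joint_spec("pin", list(c(0, 0, 1)), "qa"),
                   c(0, -1, 0))
  expect_error(link_segment_model(list(seg_ok, seg_b), mk), "unique")
  # two roots
  seg_c <- segment("c", NA, joint_spec("pin", list(c(0, 0, 1)), "qc"),
                   c(0, 0, 0))
  expect_error(link_segment_model(list(seg_ok, seg_c), mk), "root")
  # marker on unknown segment
  expect_error(link_segment_model(list(seg_ok),
                                  marker_registration("M", "zz", c(0, 0, 0))),
               "unknown segment")
  # free joint below the root
  seg_f <- segment("f", "a",
                   joint_spec("free", list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
                              paste0("f", 1:6)), c(0, -1, 0))
  expect_error(link_segment_model(list(seg_ok, seg_f), mk), "root")
  # non-unit axis
  expect_error(joint_spec("pin", list(c(0, 0, 2)), "q"), "unit")
  # negative mass
  expect_error(segment("a", NA, joint_spec("pin", list(c(0, 0, 1)), "q"),
                       c(0, 0, 0), mass = -1), "mass")
})

test_that("scaling with unit factors is the identity", {
  m <- default_gait_model()
  m2 <- scale_model(m, scale_factors(.list = stats::setNames(
    rep(list(1), length(m$segments)), names(m$segments))))
  expect_equal(m2$markers, m$markers)
  expect_equal(m2$segments, m$segments)
})

test_that("scaling multiplies marker local positions by the owner factors", {
  m <- default_gait_model()
  m2 <- scale_model(m, scale_factors(thigh_r = 1.1))
  orig <- m$markers[m$markers$segment == "thigh_r", ]
  new <- m2$markers[m2$markers$segment == "thigh_r", ]
  expect_equal(new$lx, 1.1 * orig$lx)
  expect_equal(new$ly, 1.1 * orig$ly)
  expect_equal(new$lz, 1.1 * orig$lz)
  # other segments untouched
  expect_equal(m2$markers[m2$markers$segment != "thigh_r", ],
               m$markers[m$markers$segment != "thigh_r", ])
})

test_that("scaling is multiplicative and moves distal joints with parents", {
  m <- default_gait_model()
  f <- scale_factors(thigh_r = 1.07, shank_r = 0.95, pelvis = c(1.02, 0.9, 1.1))
  g <- scale_factors(thigh_r = 0.9, pelvis = c(1.1, 1.05, 0.85))
  fg <- scale_factors(thigh_r = 1.07 * 0.9, shank_r = 0.95,
                      pelvis = c(1.02 * 1.1, 0.9 * 1.05, 1.1 * 0.85))
  a <- scale_model(scale_model(m, f), g)
  b <- scale_model(m, fg)
  q <- neutral_pose(m)
  expect_lt(max(abs(forward_kinematics(a, q) - forward_kinematics(b, q))),
            1e-12)
  # thigh scaling shifts the shank markers by exactly the knee-centre shift
  m09 <- scale_model(m, scale_factors(thigh_r = 0.9))
  d_knee <- 0.9 * m$segments$shank_r$location_in_parent -
    m$segments$shank_r$location_in_parent
  fk0 <- forward_kinematics(m, q)
  fk9 <- forward_kinematics(m09, q)
  shank_mk <- m$markers$name[m$markers$segment == "shank_r"]
  for (nm in shank_mk) {
    expect_equal(unname(fk9[, nm] - fk0[, nm]), d_knee, tolerance = 1e-12)
  }
})

test_that("volume mass scaling responds to factors and can be disabled", {
  m <- default_gait_model()
  m2 <- scale_model(m, scale_factors(thigh_r = 1.1))
  expect_equal(m2$segments$thigh_r$mass, m$segments$thigh_r$mass * 1.1^3)
  expect_equal(m2$segments$thigh_r$inertia,
               m$segments$thigh_r$inertia * 1.1^3 * 1.1^2)
  m3 <- scale_model(m, scale_factors(thigh_r = 1.1),
                    preserve_mass_properties = TRUE)
  expect_equal(m3$segments$thigh_r$mass, m$segments$thigh_r$mass)
  expect_equal(m3$segments$thigh_r$inertia, m$segments$thigh_r$inertia)
  expect_error(scale_model(m, scale_factors(thigh_r = -1)), "positive")
})
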