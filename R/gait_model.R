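# Default lower-body gait fixture: a 7-segment model (pelvis with the
# head-arms-trunk mass lumped in, and thigh-shank-foot per leg) whose
# masses sum to 83.5 kg. It is the smallest model that exhibits all nine
# peak gait metrics (hip/knee/ankle angles, moments, powers).
#
# Frame convention: x forward, y up, z to the subject's right. Hip flexion,
# knee flexion and ankle dorsiflexion coordinates are positive in flexion /
# dorsiflexion; extension, and plantarflexion, are negative values of those
# coordinates.

#' Default lower-body gait model
#'
#' Pelvis (free, 6 dof) with a ball hip, pin knee, and pin ankle per leg
#' (16 generalized coordinates), anthropometric mass distribution summing
#' to `total_mass` kg with the head-arms-trunk mass lumped into the pelvis
#' segment, and a 14-marker set (4 pelvis, 2 thigh, 2 shank, 1 toe marker
#' per leg) registered at anatomically plausible positions.
#'
#' @param total_mass whole-body mass, kg (default 83.5)
#' @return a [link_segment_model()]
#' @examples
#' default_gait_model()
#' @export
default_gait_model <- function(total_mass = 83.5) {
  # anthropometric fractions: thigh 10%, shank 4.65%, foot 1.45% per leg
  m_thigh <- 0.100 * total_mass
  m_shank <- 0.0465 * total_mass
  m_foot <- 0.0145 * total_mass
  m_pelvis <- total_mass - 2 * (m_thigh + m_shank + m_foot)

  ez <- c(0, 0, 1)
  ex <- c(1, 0, 0)
  ey <- c(0, 1, 0)

  leg <- function(side) {
    sgn <- if (side == "r") 1 else -1
    sfx <- paste0("_", side)
    list(
      segment(
        paste0("thigh", sfx), parent = "pelvis",
        joint = joint_spec("ball", axes = list(ez, ex, ey),
                           coordinate_names = paste0(
                             c("hip_flexion", "hip_adduction", "hip_rotation"), sfx)),
        location_in_parent = c(0, -0.07, sgn * 0.09),
        mass = m_thigh, com = c(0, -0.18, 0),
        inertia = diag(c(0.14, 0.025, 0.14)), length_axis = ey
      ),
      segment(
        paste0("shank", sfx), parent = paste0("thigh", sfx),
        joint = joint_spec("pin", axes = list(-ez),
                           coordinate_names = paste0("knee_flexion", sfx)),
        location_in_parent = c(0, -0.41, 0),
        mass = m_shank, com = c(0, -0.19, 0),
        inertia = diag(c(0.055, 0.007, 0.055)), length_axis = ey
      ),
      segment(
        paste0("foot", sfx), parent = paste0("shank", sfx),
        joint = joint_spec("pin", axes = list(ez),
                           coordinate_names = paste0("ankle_dorsiflexion", sfx)),
        location_in_parent = c(0, -0.43, 0),
        mass = m_foot, com = c(0.07, -0.03, 0),
        inertia = diag(c(0.001, 0.0045, 0.0045)), length_axis = ex
      )
    )
  }

  pelvis <- segment(
    "pelvis", parent = NA,
    joint = joint_spec(
      "free", axes = list(ez, ex, ey),
      coordinate_names = c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                           "pelvis_tilt", "pelvis_list", "pelvis_rotation")),
    location_in_parent = c(0, 0, 0),
    mass = m_pelvis, com = c(0, 0.25, 0),
    inertia = diag(c(1.9, 0.9, 2.1)), length_axis = ey
  )

  mk <- function(name, seg, pos) marker_registration(name, seg, pos)
  leg_markers <- function(side) {
    sgn <- if (side == "r") 1 else -1
    S <- toupper(side)
    sfx <- paste0("_", side)
    dplyr::bind_rows(
      mk(paste0("THI_", S, "_U"), paste0("thigh", sfx),
         c(0.05, -0.18, sgn * 0.06)),
      mk(paste0("THI_", S, "_L"), paste0("thigh", sfx),
         c(-0.02, -0.32, sgn * 0.07)),
      mk(paste0("SHA_", S, "_U"), paste0("shank", sfx),
         c(0.04, -0.15, sgn * 0.05)),
      mk(paste0("SHA_", S, "_L"), paste0("shank", sfx),
         c(-0.01, -0.30, sgn * 0.06)),
      mk(paste0("TOE_", S), paste0("foot", sfx), c(0.17, -0.06, sgn * 0.01))
    )
  }
  markers <- dplyr::bind_rows(
    mk("RASI", "pelvis", c(0.09, 0.02, 0.12)),
    mk("LASI", "pelvis", c(0.09, 0.02, -0.12)),
    mk("RPSI", "pelvis", c(-0.11, 0.03, 0.05)),
    mk("LPSI", "pelvis", c(-0.11, 0.03, -0.05)),
    leg_markers("r"),
    leg_markers("l")
  )

  link_segment_model(c(list(pelvis), leg("r"), leg("l")), markers,
                     name = "lowerbody_gait")
}

# Harmonic description of the default gait cycle: value(u) =
# const + sum_h a_h * cos(2*pi*h*u + p_h), h = 1..3, u = t/cycle in [0, 1),
# right heel strike at u = 0. Units: deg for rotations, m for translations.
# Amplitudes are gait-plausible for natural-speed walking (knee: loading
# bump ~19 deg, stance minimum ~6 deg, swing peak ~56 deg; ankle: dorsi
# ~11 deg in late stance, plantarflexion peak ~-14 deg around toe-off); the
# right-leg curves are phase-shifted by half a cycle for the left.
default_curve_table <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 8L, byrow = TRUE)
    tibble::tibble(coordinate = as.character(m[, 1L]),
                   const = as.numeric(m[, 2L]), a1 = as.numeric(m[, 3L]),
                   p1 = as.numeric(m[, 4L]), a2 = as.numeric(m[, 5L]),
                   p2 = as.numeric(m[, 6L]), a3 = as.numeric(m[, 7L]),
                   p3 = as.numeric(m[, 8L]))
  }
  tribble_(
    "pelvis_tx",            0,     0.020,  -1.571, 0,      0,      0, 0,
    "pelvis_ty",            0.96,  0,       0,     0.015,  3.1416, 0, 0,
    "pelvis_tz",            0,     0.025,  -1.571, 0,      0,      0, 0,
    "pelvis_tilt",          3,     0,       0,     1.5,    0.5,    0, 0,
    "pelvis_list",          0,     2,      -1.571, 0,      0,      0, 0,
    "pelvis_rotation",      0,     5,      -1.571, 0,      0,      0, 0,
    "hip_flexion_r",        8,    24,       0.35,  0,      0,      0, 0,
    "hip_adduction_r",      0,     4,      -1.271, 0,      0,      0, 0,
    "hip_rotation_r",       0,     3,      -1.571, 0,      0,      0, 0,
    "knee_flexion_r",      21.4,  16.738,   1.7723, 15.251, -2.5632, 4.114, -1.461,
    "ankle_dorsiflexion_r", -0.22,  6.149,  -1.9002,  7.248,  1.1241, 2.284,  2.9641
  )
}

#' Prescribed joint-angle curves of the synthetic gait cycle
#'
#' Evaluates smooth periodic gait-like coordinate trajectories (at most two
#' harmonics per coordinate) together with their analytic first and second
#' time derivatives. Left-leg coordinates mirror the right with a half-cycle
#' phase shift.
#'
#' @param model the model whose coordinates to fill (default
#'   [default_gait_model()])
#' @param times evaluation times, s
#' @param cycle gait cycle duration, s
#' @param overrides optional named list: per-coordinate replacement rows
#'   `c(const, a1, p1, a2, p2)` or `c(const, a1, p1, a2, p2, a3, p3)`
#'   (deg / m), e.g. to raise the knee-flexion offset for a crouched trial
#' @return list of `q`, `qdot`, `qddot` (T x n_q matrices, rad and m)
#' @export
gait_coordinate_curves <- function(model = default_gait_model(), times,
                                   cycle = 1.1, overrides = NULL) {
  tab <- default_curve_table()
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      v <- as.numeric(overrides[[nm]])
      if (length(v) == 5L) v <- c(v, 0, 0)
      if (length(v) != 7L) {
        stop("override rows are c(const, a1, p1, a2, p2[, a3, p3])")
      }
      if (nm %in% tab$coordinate) {
        tab[tab$coordinate == nm, -1L] <- as.list(v)
      } else {
        tab <- rbind(tab, tibble::tibble(coordinate = nm, const = v[1L],
                                         a1 = v[2L], p1 = v[3L], a2 = v[4L],
                                         p2 = v[5L], a3 = v[6L], p3 = v[7L]))
      }
    }
  }
  cc <- model$compiled
  Tn <- length(times)
  q <- matrix(0, Tn, cc$n_q, dimnames = list(NULL, cc$coords$name))
  qd <- q; qdd <- q
  w1 <- 2 * pi / cycle
  for (k in seq_len(cc$n_q)) {
    nm <- cc$coords$name[k]
    shift <- 0
    base <- nm
    if (grepl("_l$", nm)) {
      base <- sub("_l$", "_r", nm)
      shift <- 0.5
    }
    row <- tab[tab$coordinate == base, ]
    if (nrow(row) == 0L) next
    u <- times / cycle + shift
    val <- rep(row$const, Tn)
    d1 <- numeric(Tn)
    d2 <- numeric(Tn)
    amps <- c(row$a1, row$a2, row$a3)
    phs <- c(row$p1, row$p2, row$p3)
    for (h in 1:3) {
      if (amps[h] == 0) next
      th <- h * 2 * pi * u + phs[h]
      wh <- h * w1
      val <- val + amps[h] * cos(th)
      d1 <- d1 - amps[h] * wh * sin(th)
      d2 <- d2 - amps[h] * wh^2 * cos(th)
    }
    if (cc$coords$kind[k] == "rot") {
      val <- val * pi / 180; d1 <- d1 * pi / 180; d2 <- d2 * pi / 180
    }
    q[, k] <- val; qd[, k] <- d1; qdd[, k] <- d2
  }
  list(q = q, qdot = qd, qddot = qdd)
}
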