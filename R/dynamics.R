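# Inverse dynamics of the link-segment model: a recursive Newton-Euler
# evaluation over the segment tree. The outward pass propagates angular
# velocity/acceleration and linear acceleration from the root; the inward
# pass accumulates each segment's inertial wrench together with gravity and
# any applied external loads, and projects the joint wrench onto each
# coordinate's axis to obtain generalized forces (net joint moments for
# rotational coordinates, forces for translations). The free base cannot be
# actuated, so its six generalized forces are the residual wrench; it is
# returned explicitly rather than hidden.

#' Container for measured external loads
#'
#' @param times time stamps, s
#' @param ... one or more loads, each a list with fields `segment` (name of
#'   the segment the load acts on), `force` (T x 3, N, ground frame),
#'   `point` (T x 3, m, ground-frame point of application) and `torque`
#'   (T x 3, N m, free moment); single rows are recycled over time
#' @return object of class `external_loads`
#' @export
external_loads <- function(times, ...) {
  times <- as.numeric(times)
  Tn <- length(times)
  loads <- lapply(list(...), function(l) {
    stopifnot(is.list(l), !is.null(l$segment))
    fix <- function(M) {
      M <- matrix(as.numeric(M), ncol = 3L)
      if (nrow(M) == 1L) M <- M[rep(1L, Tn), , drop = FALSE]
      if (nrow(M) != Tn) stop("load table rows must match length(times)")
      M
    }
    list(segment = as.character(l$segment), force = fix(l$force),
         point = fix(l$point), torque = fix(l$torque %||% c(0, 0, 0)))
  })
  structure(list(times = times, loads = loads), class = "external_loads")
}

#' Resample external loads onto a new time base
#'
#' Linear interpolation per component; times outside the original range take
#' the nearest endpoint value.
#'
#' @param loads an [external_loads()]
#' @param times new time base, s
#' @return resampled [external_loads()]
#' @export
resample_loads <- function(loads, times) {
  stopifnot(inherits(loads, "external_loads"))
  if (length(loads$times) == length(times) &&
      max(abs(loads$times - times)) < 1e-12) {
    return(loads)
  }
  interp <- function(M) {
    apply(M, 2L, function(col) {
      stats::approx(loads$times, col, xout = times, rule = 2L)$y
    })
  }
  new <- lapply(loads$loads, function(l) {
    list(segment = l$segment, force = interp(l$force),
         point = interp(l$point), torque = interp(l$torque))
  })
  structure(list(times = as.numeric(times), loads = new),
            class = "external_loads")
}

#' Zero the centre of pressure of near-zero loads
#'
#' When the force magnitude is below `threshold` the centre of pressure of a
#' force-plate channel is numerically meaningless; this sets the point of
#' application to the origin for those frames so that interpolated CoP noise
#' cannot inject spurious moments.
#'
#' @param loads an [external_loads()]
#' @param threshold force magnitude below which the CoP is zeroed, N
#' @return modified [external_loads()]
#' @export
zero_cop_below <- function(loads, threshold = 10) {
  stopifnot(inherits(loads, "external_loads"))
  loads$loads <- lapply(loads$loads, function(l) {
    small <- sqrt(rowSums(l$force^2)) < threshold
    l$point[small, ] <- 0
    l
  })
  loads
}

# Outward + inward Newton-Euler pass for one frame. Returns generalized
# forces (length n_q) and the root residual wrench.
rnea_frame <- function(model, q, qdot, qddot, frame_loads, gravity) {
  cc <- model$compiled
  segs <- model$segments
  S <- cc$n_seg
  R <- vector("list", S)
  p_j <- matrix(0, 3L, S)
  w <- matrix(0, 3L, S)
  al <- matrix(0, 3L, S)
  a_j <- matrix(0, 3L, S)
  axis_g <- matrix(0, 3L, cc$n_q)
  seg_row0 <- integer(S)

  for (i in seq_len(S)) {
    s <- segs[[i]]
    j <- s$joint
    pi_ <- cc$parent_idx[i]
    if (pi_ > 0L) {
      Rp <- R[[pi_]]
      r <- as.numeric(Rp %*% s$location_in_parent)
      pj <- p_j[, pi_] + r
      wi <- w[, pi_]
      ali <- al[, pi_]
      aj <- a_j[, pi_] + cross3(ali, r) + cross3(wi, cross3(wi, r))
    } else {
      Rp <- diag(3)
      pj <- s$location_in_parent
      wi <- c(0, 0, 0); ali <- c(0, 0, 0); aj <- c(0, 0, 0)
    }
    row0 <- which(cc$coord_seg == i)[1L]
    seg_row0[i] <- row0
    idx <- row0 + seq_len(j$n_trans + j$n_rot) - 1L
    qs <- q[idx]; qds <- qdot[idx]; qdds <- qddot[idx]
    if (j$n_trans > 0L) {
      # free-joint translations (root only): along ground axes
      pj <- pj + qs[1:3]
      aj <- aj + qdds[1:3]
      axis_g[, idx[1:3]] <- diag(3)
    }
    Rcur <- Rp
    if (j$n_rot > 0L) {
      for (k in seq_len(j$n_rot)) {
        kk <- j$n_trans + k
        ak <- as.numeric(Rcur %*% j$axes[, k])
        axis_g[, idx[kk]] <- ak
        ali <- ali + qdds[kk] * ak + qds[kk] * cross3(wi, ak)
        wi <- wi + qds[kk] * ak
        Rcur <- Rcur %*% rot_axis_angle(j$axes[, k], qs[kk])
      }
    }
    R[[i]] <- Rcur
    p_j[, i] <- pj
    w[, i] <- wi
    al[, i] <- ali
    a_j[, i] <- aj
  }

  # inward pass
  f_acc <- matrix(0, 3L, S)
  n_acc <- matrix(0, 3L, S)
  tau <- numeric(cc$n_q)
  for (i in rev(seq_len(S))) {
    s <- segs[[i]]
    Ri <- R[[i]]
    rc <- as.numeric(Ri %*% s$com)
    pc <- p_j[, i] + rc
    ac <- a_j[, i] + cross3(al[, i], rc) + cross3(w[, i], cross3(w[, i], rc))
    Ig <- Ri %*% s$inertia %*% t(Ri)
    Fi <- s$mass * (ac - gravity)
    Ni <- as.numeric(Ig %*% al[, i]) + cross3(w[, i], as.numeric(Ig %*% w[, i]))
    for (l in frame_loads) {
      if (l$seg != i) next
      Fi <- Fi - l$force
      Ni <- Ni - l$torque - cross3(l$point - pc, l$force)
    }
    fi <- Fi + f_acc[, i]
    ni <- Ni + cross3(pc - p_j[, i], Fi) + n_acc[, i]
    pi_ <- cc$parent_idx[i]
    if (pi_ > 0L) {
      f_acc[, pi_] <- f_acc[, pi_] + fi
      n_acc[, pi_] <- n_acc[, pi_] + ni + cross3(p_j[, i] - p_j[, pi_], fi)
    }
    j <- s$joint
    idx <- seg_row0[i] + seq_len(j$n_trans + j$n_rot) - 1L
    if (j$n_trans > 0L) {
      for (k in 1:3) tau[idx[k]] <- sum(axis_g[, idx[k]] * fi)
    }
    if (j$n_rot > 0L) {
      for (k in seq_len(j$n_rot)) {
        kk <- idx[j$n_trans + k]
        tau[kk] <- sum(axis_g[, kk] * ni)
      }
    }
    if (pi_ == 0L) {
      root_wrench <- list(force = fi, moment = ni)
    }
  }
  list(tau = tau, residual = root_wrench)
}

# Normalize per-frame load access: list of (seg index, force, point, torque).
loads_for_frame <- function(model, loads, t) {
  if (is.null(loads)) return(list())
  lapply(loads$loads, function(l) {
    seg <- match(l$segment, model$compiled$seg_names)
    if (is.na(seg)) stop("external load on unknown segment: ", l$segment)
    list(seg = seg, force = l$force[t, ], point = l$point[t, ],
         torque = l$torque[t, ])
  })
}

#' Inverse dynamics over a trajectory
#'
#' Computes generalized forces (net joint moments for rotational
#' coordinates, N m; forces for translational coordinates, N) for every
#' frame, given coordinates and their time derivatives and any measured
#' external loads. The root segment's six generalized forces are the
#' residual wrench required to realize the motion; it is also returned as a
#' ground-frame force and moment (about the root joint centre).
#'
#' Sign convention: a positive moment drives the coordinate in its positive
#' direction (e.g. a positive value on a `*_flexion` coordinate is a flexion
#' moment).
#'
#' @param model a [link_segment_model()]
#' @param q,qdot,qddot T x n_q matrices (or length-n_q vectors for a single
#'   frame), model coordinate order
#' @param loads optional [external_loads()], resampled onto `times` if given
#' @param times frame times, s (required when `loads` is given with a
#'   different time base)
#' @param gravity gravity vector, m/s^2, ground frame
#' @return object of class `joint_moments`: `times`, `moments` (T x n_q,
#'   named columns), `residual` (list of `force`, `moment`: T x 3 matrices)
#' @export
inverse_dynamics <- function(model, q, qdot, qddot, loads = NULL,
                             times = NULL, gravity = c(0, -9.80665, 0)) {
  stopifnot(inherits(model, "link_segment_model"))
  cc <- model$compiled
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  }
  Q <- as_mat(q); Qd <- as_mat(qdot); Qdd <- as_mat(qddot)
  if (ncol(Q) != cc$n_q || !all(dim(Q) == dim(Qd)) || !all(dim(Q) == dim(Qdd))) {
    stop(sprintf("q, qdot, qddot must all be T x %d", cc$n_q))
  }
  Tn <- nrow(Q)
  if (is.null(times)) times <- seq_len(Tn) - 1
  if (!is.null(loads)) loads <- resample_loads(loads, times)
  gravity <- as.numeric(gravity)
  M <- matrix(0, Tn, cc$n_q, dimnames = list(NULL, cc$coords$name))
  resF <- matrix(0, Tn, 3L)
  resM <- matrix(0, Tn, 3L)
  for (t in seq_len(Tn)) {
    fl <- loads_for_frame(model, loads, t)
    out <- rnea_frame(model, Q[t, ], Qd[t, ], Qdd[t, ], fl, gravity)
    M[t, ] <- out$tau
    resF[t, ] <- out$residual$force
    resM[t, ] <- out$residual$moment
  }
  structure(
    list(times = times, moments = M,
         residual = list(force = resF, moment = resM)),
    class = "joint_moments"
  )
}

#' @export
print.joint_moments <- function(x, ...) {
  cat(sprintf("<joint_moments: %d frames x %d coordinates; max |residual force| %.3g N>\n",
              nrow(x$moments), ncol(x$moments), max(abs(x$residual$force))))
  invisible(x)
}

#' Instantaneous joint powers
#'
#' Elementwise product of each coordinate's net moment and velocity.
#'
#' @param moments a `joint_moments` object (or T x n_q matrix)
#' @param velocities T x n_q matrix of coordinate velocities
#' @param times frame times when `moments` is a bare matrix
#' @return object of class `joint_powers`: `times`, `powers` (T x n_q, W)
#' @export
joint_powers <- function(moments, velocities, times = NULL) {
  if (inherits(moments, "joint_moments")) {
    times <- moments$times
    M <- moments$moments
  } else {
    M <- moments
  }
  if (!is.matrix(velocities)) velocities <- matrix(velocities, nrow = 1L)
  if (!all(dim(M) == dim(velocities))) {
    stop("moments and velocities must have matching shape")
  }
  structure(list(times = times, powers = M * velocities),
            class = "joint_powers")
}

#' Accelerations implied by applied generalized forces
#'
#' Forward dynamics via the articulated system's equations of motion
#' assembled from inverse dynamics: the joint-space mass matrix is built one
#' column at a time with unit accelerations (no gravity, no loads) and the
#' bias term from a zero-acceleration call, then accelerations solve
#' `M(q) qddot = tau - bias`. Used to verify inverse-dynamics consistency.
#'
#' @param model a [link_segment_model()]
#' @param q,qdot coordinate vector and velocity (single frame)
#' @param tau applied generalized forces, length n_q (including the root's
#'   residual wrench components)
#' @param loads optional single-frame [external_loads()]
#' @param gravity gravity vector
#' @return length n_q acceleration vector
#' @export
forward_dynamics_acc <- function(model, q, qdot, tau, loads = NULL,
                                 gravity = c(0, -9.80665, 0)) {
  cc <- model$compiled
  n <- cc$n_q
  fl <- if (is.null(loads)) list() else loads_for_frame(model, loads, 1L)
  zero <- numeric(n)
  bias <- rnea_frame(model, q, qdot, zero, fl, gravity)$tau
  Mm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ej <- zero; ej[j] <- 1
    Mm[, j] <- rnea_frame(model, q, zero, ej, list(), c(0, 0, 0))$tau
  }
  as.numeric(solve(Mm, tau - bias))
}
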