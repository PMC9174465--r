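# Shared fixtures and independent oracles.

# Planar pendulum: one segment on a pin joint about z, rod along -y.
make_pendulum <- function(mass = 2, d = 0.3, I = 0.04) {
  link_segment_model(
    list(segment("rod", NA,
                 joint_spec("pin", list(c(0, 0, 1)), "theta"),
                 location_in_parent = c(0, 0, 0), mass = mass,
                 com = c(0, -d, 0), inertia = diag(c(0.01, 0.001, I)),
                 length_axis = c(0, 1, 0))),
    dplyr::bind_rows(
      marker_registration("TIP", "rod", c(0, -0.5, 0)),
      marker_registration("MID", "rod", c(0.02, -0.25, 0))),
    name = "pendulum")
}

# Serial chain of `n` pin-jointed links under a free or fixed base, with
# two markers per link; used for randomized FK checks.
make_chain <- function(n = 3, link = 0.3) {
  axes <- list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  segs <- list(segment(
    "link1", NA, joint_spec("pin", list(c(0, 0, 1)), "q1"),
    location_in_parent = c(0.1, 0.2, -0.1), mass = 1, com = c(0, -link / 2, 0),
    inertia = diag(c(0.01, 0.002, 0.01))))
  for (i in seq_len(n - 1L)) {
    segs[[i + 1L]] <- segment(
      paste0("link", i + 1L), paste0("link", i),
      joint_spec("pin", list(axes[[(i %% 3L) + 1L]]), paste0("q", i + 1L)),
      location_in_parent = c(0, -link, 0), mass = 1,
      com = c(0, -link / 2, 0), inertia = diag(c(0.01, 0.002, 0.01)))
  }
  mk <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::bind_rows(
      marker_registration(paste0("A", i), paste0("link", i),
                          c(0.05, -link / 3, 0.02)),
      marker_registration(paste0("B", i), paste0("link", i),
                          c(-0.03, -0.8 * link, -0.04)))
  }))
  link_segment_model(segs, mk, name = paste0("chain", n))
}

# Independent forward-kinematics oracle: composes 4x4 homogeneous
# transforms by walking the parent chain per marker, sharing no code with
# the package's fk_state path.
naive_marker_fk <- function(model, q) {
  qn <- stats::setNames(as.numeric(q), names(q))
  if (is.null(names(qn))) names(qn) <- model_coordinates(model)$name
  homog <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  rot4 <- function(axis, ang) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    homog(diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K, c(0, 0, 0))
  }
  seg_transform <- function(seg_name) {
    s <- model$segments[[seg_name]]
    Tp <- if (is.na(s$parent)) diag(4) else seg_transform(s$parent)
    Tj <- homog(diag(3), s$location_in_parent)
    j <- s$joint
    if (j$n_trans > 0L) {
      tq <- qn[j$coordinate_names[1:3]]
      Tj <- Tj %*% homog(diag(3), tq)
    }
    if (j$n_rot > 0L) {
      for (k in seq_len(j$n_rot)) {
        ang <- qn[j$coordinate_names[j$n_trans + k]]
        Tj <- Tj %*% rot4(j$axes[, k], ang)
      }
    }
    Tp %*% Tj
  }
  mk <- model$markers
  out <- sapply(seq_len(nrow(mk)), function(i) {
    Tm <- seg_transform(mk$segment[i])
    (Tm %*% c(mk$lx[i], mk$ly[i], mk$lz[i], 1))[1:3]
  })
  colnames(out) <- mk$name
  out
}

# Closed-form rigid registration (Kabsch): rotation + translation aligning
# P onto Q (3 x n each).
kabsch_fit <- function(P, Q) {
  cp <- rowMeans(P)
  cq <- rowMeans(Q)
  H <- (P - cp) %*% t(Q - cq)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = cq - R %*% cp)
}

# One synthetic trial per (rate, extra key), cached across tests.
.trial_cache <- new.env(parent = emptyenv())
get_trial <- function(rate = 60, ...) {
  key <- paste0("r", rate, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.trial_cache[[key]])) {
    .trial_cache[[key]] <- generate_trial(rate = rate, ...)
  }
  .trial_cache[[key]]
}
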