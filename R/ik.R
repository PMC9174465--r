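# Constrained inverse kinematics: weighted nonlinear least squares over the
# model's generalized coordinates, minimizing
#   sum_i w_i || m_i(q) - o_i ||^2
# subject to coordinate bounds, where m_i(q) is the model marker position
# from forward kinematics and o_i the observed position. Solved by a
# Levenberg-Marquardt iteration with an analytic Jacobian (geometric:
# d m / d q_k = a_k x (m - p_joint) for rotational coordinates, a_k for
# translations) and projection of each step onto the bound box.

#' Inverse-kinematics solver settings
#'
#' @param max_iterations iteration cap
#' @param gtol stop when the infinity norm of the objective gradient falls
#'   below this
#' @param ptol stop when the step norm falls below this
#' @param lambda0 initial Levenberg-Marquardt damping
#' @return list of control settings
#' @export
ik_control <- function(max_iterations = 200L, gtol = 1e-10, ptol = 1e-12,
                       lambda0 = 1e-3) {
  list(max_iterations = as.integer(max_iterations), gtol = gtol, ptol = ptol,
       lambda0 = lambda0)
}

# Match observed marker columns to model markers, dropping missing samples
# (any NA coordinate) and zero-weight markers from the objective.
match_markers <- function(model, observed, weights = NULL) {
  cc <- model$compiled
  if (is.list(observed) && !is.matrix(observed)) {
    observed <- vapply(observed, as.numeric, numeric(3))
  }
  stopifnot(is.matrix(observed), nrow(observed) == 3L)
  obs_names <- colnames(observed)
  if (is.null(obs_names)) stop("observed marker matrix needs column names")
  idx <- match(obs_names, cc$marker_names)
  keep <- which(!is.na(idx) & colSums(is.na(observed)) == 0L)
  w <- cc$marker_weight[idx[keep]]
  if (!is.null(weights)) {
    ov <- intersect(names(weights), obs_names[keep])
    w[match(ov, obs_names[keep])] <- as.numeric(weights[ov])
  }
  pos <- keep[w > 0]
  list(model_idx = idx[pos], obs = observed[, pos, drop = FALSE],
       weights = w[w > 0], names = obs_names[pos])
}

# Markers are "usable" for a frame when at least 3 of them are not (nearly)
# collinear; otherwise orientation about the marker line is unobservable.
check_usable <- function(obs) {
  if (ncol(obs) < 3L) {
    stop(sprintf("under-determined: %d usable marker(s), need at least 3",
                 ncol(obs)))
  }
  ctr <- rowMeans(obs)
  dev <- obs - ctr
  sv <- svd(dev, nu = 0L, nv = 0L)$d
  if (length(sv) < 2L || sv[2L] < 1e-10) {
    stop("under-determined: usable markers are collinear")
  }
  invisible(TRUE)
}

# Residuals (weighted, stacked xyz per marker) and Jacobian at q.
# Vectorized over markers: for a rotational coordinate with ground axis a
# and joint centre p_j, d m / d q = a x (m - p_j) for every marker m distal
# to the joint; for a translation it is the axis itself.
ik_residual <- function(model, q, mi, obs, sw, jac = TRUE) {
  cc <- model$compiled
  st <- fk_state(model, q)
  M <- length(mi)
  mseg <- cc$marker_seg[mi]
  pos <- matrix(0, 3L, M)
  for (s in unique(mseg)) {
    sel <- which(mseg == s)
    pos[, sel] <- st$R[[s]] %*% cc$marker_local[, mi[sel], drop = FALSE] +
      st$p[, s]
  }
  sw3 <- rep(sw, each = 3L)
  r <- sw3 * as.numeric(pos - obs)
  out <- list(r = r, pos = pos)
  if (jac) {
    J <- matrix(0, 3L * M, cc$n_q)
    rot_kind <- cc$coords$kind == "rot"
    for (k in seq_len(cc$n_q)) {
      tseg <- cc$coord_seg[k]
      sel <- which(cc$ancestor[tseg, mseg])
      if (length(sel) == 0L) next
      ak <- st$axis_g[, k]
      col <- matrix(0, 3L, M)
      if (rot_kind[k]) {
        D <- pos[, sel, drop = FALSE] - st$p[, tseg]
        col[, sel] <- rbind(ak[2L] * D[3L, ] - ak[3L] * D[2L, ],
                            ak[3L] * D[1L, ] - ak[1L] * D[3L, ],
                            ak[1L] * D[2L, ] - ak[2L] * D[1L, ])
      } else {
        col[, sel] <- ak
      }
      J[, k] <- sw3 * as.numeric(col)
    }
    out$J <- J
  }
  out
}

#' Solve inverse kinematics for a single frame
#'
#' Finds a local minimizer of the weighted marker-tracking objective subject
#' to the model's coordinate bounds, starting from `initial_guess`.
#'
#' @param model a [link_segment_model()]
#' @param observed 3 x M matrix of observed marker positions (columns named;
#'   `NA` entries mark missing samples), or a named list of 3-vectors
#' @param weights optional named vector overriding the model's registered
#'   marker weights for this solve
#' @param initial_guess starting coordinate vector; defaults to
#'   [neutral_pose()]
#' @param control an [ik_control()] list
#' @return list with `q` (named coordinate vector), `errors` (named
#'   per-marker distances, m), `objective`, `iterations`, `converged`
#' @examples
#' m <- default_gait_model()
#' obs <- forward_kinematics(m, neutral_pose(m))
#' sol <- solve_ik_frame(m, obs)
#' max(sol$errors)
#' @export
solve_ik_frame <- function(model, observed, weights = NULL,
                           initial_guess = NULL, control = ik_control()) {
  stopifnot(inherits(model, "link_segment_model"))
  cc <- model$compiled
  mm <- match_markers(model, observed, weights)
  check_usable(mm$obs)
  q <- if (is.null(initial_guess)) neutral_pose(model) else
    check_q(model, initial_guess)
  q <- clamp(as.numeric(q), cc$lower, cc$upper)
  sw <- sqrt(mm$weights)

  res <- ik_residual(model, q, mm$model_idx, mm$obs, sw)
  cost <- sum(res$r^2)
  lambda <- control$lambda0
  iter <- 0L
  converged <- FALSE
  while (iter < control$max_iterations) {
    iter <- iter + 1L
    g <- crossprod(res$J, res$r)
    if (max(abs(g)) < control$gtol) { converged <- TRUE; break }
    JtJ <- crossprod(res$J)
    d <- diag(JtJ)
    d[d < 1e-12] <- 1e-12
    step_ok <- FALSE
    for (try in seq_len(25L)) {
      H <- JtJ + lambda * diag(d, nrow = length(d))
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        q_new <- clamp(q + as.numeric(delta), cc$lower, cc$upper)
        res_new <- ik_residual(model, q_new, mm$model_idx, mm$obs, sw)
        cost_new <- sum(res_new$r^2)
        if (cost_new < cost) {
          step_norm <- sqrt(sum((q_new - q)^2))
          q <- q_new; res <- res_new; cost <- cost_new
          lambda <- max(lambda / 3, 1e-12)
          step_ok <- TRUE
          if (step_norm < control$ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok || converged) { converged <- converged || !step_ok; break }
  }
  if (!converged && iter >= control$max_iterations) {
    stop(sprintf(
      "IK did not converge within %d iterations (objective %.6g m^2)",
      control$max_iterations, cost))
  }
  err <- sqrt(colSums((res$pos - mm$obs)^2))
  names(err) <- mm$names
  names(q) <- cc$coords$name
  list(q = q, errors = err, objective = cost, iterations = iter,
       converged = TRUE)
}

#' Solve inverse kinematics over a trajectory
#'
#' Solves frame by frame with a warm start: frame 0 starts from
#' `initial_guess` (default the neutral pose) and every later frame from the
#' previous frame's solution, so the solve is deterministic and invariant to
#' batching. Frames in which a marker sample is missing drop that marker
#' from the objective; frames with fewer than 3 usable markers are an error.
#'
#' @param model a [link_segment_model()]
#' @param trajectories a [marker_trajectories()]
#' @param weights optional named weight overrides
#' @param initial_guess starting pose for the first frame
#' @param control an [ik_control()] list
#' @param tracked_errors optional character vector: markers over which to
#'   report errors (defaults to all matched markers)
#' @return object of class `ik_solution`: `times`, `coordinates` (T x n_q
#'   matrix, named columns), `per_marker_error` (T x M matrix, m),
#'   `rmse_per_frame` (length-T vector, m)
#' @export
solve_ik <- function(model, trajectories, weights = NULL,
                     initial_guess = NULL, control = ik_control(),
                     tracked_errors = NULL) {
  stopifnot(inherits(model, "link_segment_model"),
            inherits(trajectories, "marker_trajectories"))
  cc <- model$compiled
  Tn <- n_frames(trajectories)
  Q <- matrix(NA_real_, Tn, cc$n_q, dimnames = list(NULL, cc$coords$name))
  common <- intersect(trajectories$names, cc$marker_names)
  if (length(common) == 0L) stop("no trajectory marker matches the model")
  E <- matrix(NA_real_, Tn, length(common), dimnames = list(NULL, common))
  guess <- if (is.null(initial_guess)) neutral_pose(model) else
    check_q(model, initial_guess)
  for (t in seq_len(Tn)) {
    obs <- trajectories$xyz[, , t]
    sol <- tryCatch(
      solve_ik_frame(model, obs, weights = weights, initial_guess = guess,
                     control = control),
      error = function(e) stop(sprintf("frame %d (t = %.4f s): %s", t,
                                       trajectories$times[t],
                                       conditionMessage(e)), call. = FALSE)
    )
    Q[t, ] <- sol$q
    E[t, names(sol$errors)] <- sol$errors
    guess <- sol$q
  }
  tracked <- tracked_errors %||% common
  new_ik_solution(trajectories$times, Q, E, tracked)
}

new_ik_solution <- function(times, Q, E, tracked) {
  tr <- intersect(tracked, colnames(E))
  rmse <- apply(E[, tr, drop = FALSE], 1L,
                function(e) sqrt(mean(e[!is.na(e)]^2)))
  structure(
    list(times = times, coordinates = Q, per_marker_error = E,
         rmse_per_frame = rmse, tracked = tr),
    class = "ik_solution"
  )
}

#' @export
print.ik_solution <- function(x, ...) {
  cat(sprintf(
    "<ik_solution: %d frames x %d coordinates; mean RMSE %.4g m, max marker error %.4g m>\n",
    nrow(x$coordinates), ncol(x$coordinates), mean(x$rmse_per_frame),
    max(x$per_marker_error, na.rm = TRUE)))
  invisible(x)
}

#' @export
as_tibble.ik_solution <- function(x, ...) {
  tibble::as_tibble(cbind(time = x$times, x$coordinates))
}
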