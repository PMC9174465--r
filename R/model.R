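# Link-segment skeletal model: segments connected by low-dof joints in a
# tree, with point-mass/inertia properties and markers registered in each
# segment's frame. Frames are right-handed with x forward, y up, z lateral
# (to the subject's right); rotational coordinates are in radians and
# translations in metres throughout.

JOINT_DOF <- c(free = 6L, pin = 1L, universal = 2L, ball = 3L)

#' Specify a joint connecting a segment to its parent
#'
#' A joint is an ordered sequence of rotations about unit axes fixed in the
#' parent frame (applied intrinsically, i.e. each subsequent axis is carried
#' by the preceding rotations), optionally preceded for a `free` joint by
#' three translations along the parent's x, y, z axes. Supported types:
#' `free` (6 dof: tx, ty, tz then three rotations), `ball` (3 rotations),
#' `universal` (2), `pin` (1).
#'
#' @param type one of `"free"`, `"pin"`, `"universal"`, `"ball"`
#' @param axes rotation axes as a 3-row matrix (one column per rotational
#'   dof) or a list of unit 3-vectors, expressed in the parent frame
#' @param coordinate_names character vector naming every generalized
#'   coordinate (translations first for `free` joints); must be unique
#'   within the model
#' @param bounds optional 2-row matrix (`lower`, `upper`) per coordinate;
#'   defaults to `c(-pi, pi)` for rotations and `c(-5, 5)` m for
#'   translations
#' @return an object of class `joint_spec`
#' @export
joint_spec <- function(type, axes, coordinate_names, bounds = NULL) {
  type <- match.arg(type, names(JOINT_DOF))
  dof <- JOINT_DOF[[type]]
  n_trans <- if (type == "free") 3L else 0L
  n_rot <- dof - n_trans
  if (is.list(axes)) axes <- do.call(cbind, axes)
  axes <- matrix(as.numeric(axes), nrow = 3L)
  if (ncol(axes) != n_rot) {
    stop(sprintf("joint type '%s' needs %d rotation axes, got %d",
                 type, n_rot, ncol(axes)))
  }
  nrm <- sqrt(colSums(axes^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("joint axes must be unit vectors")
  coordinate_names <- as.character(coordinate_names)
  if (length(coordinate_names) != dof) {
    stop(sprintf("joint type '%s' has %d coordinates; %d names given",
                 type, dof, length(coordinate_names)))
  }
  if (anyDuplicated(coordinate_names)) stop("duplicate coordinate names in joint")
  if (is.null(bounds)) {
    bounds <- matrix(rep(c(-pi, pi), dof), nrow = 2L)
    if (n_trans > 0L) bounds[, seq_len(n_trans)] <- c(-5, 5)
  }
  bounds <- matrix(as.numeric(bounds), nrow = 2L)
  if (ncol(bounds) != dof) stop("bounds must have one column per coordinate")
  if (any(bounds[1L, ] >= bounds[2L, ])) stop("coordinate bounds need min < max")
  structure(
    list(type = type, axes = axes, n_trans = n_trans, n_rot = n_rot,
         coordinate_names = coordinate_names, bounds = bounds),
    class = "joint_spec"
  )
}

#' Define a body segment of a link-segment model
#'
#' @param name segment identifier
#' @param parent name of the parent segment, or `NA` for the root (the root
#'   attaches to the ground frame)
#' @param joint a [joint_spec()] connecting this segment to its parent
#' @param location_in_parent 3-vector, m: the joint centre expressed in the
#'   parent frame (ground frame for the root). The segment's own frame has
#'   its origin at the joint centre.
#' @param mass segment mass, kg (>= 0)
#' @param com centre of mass in the segment frame, m
#' @param inertia 3x3 symmetric positive-semidefinite inertia about the com
#'   in the segment frame, kg m^2
#' @param length_axis unit 3-vector: the segment's longitudinal axis, used
#'   by the inertia scaling rule
#' @return an object of class `lsm_segment`
#' @export
segment <- function(name, parent = NA_character_, joint, location_in_parent,
                    mass = 0, com = c(0, 0, 0), inertia = diag(0, 3),
                    length_axis = c(0, 1, 0)) {
  stopifnot(inherits(joint, "joint_spec"))
  location_in_parent <- as.numeric(location_in_parent)
  com <- as.numeric(com)
  stopifnot(length(location_in_parent) == 3L, length(com) == 3L)
  if (!is.numeric(mass) || length(mass) != 1L || mass < 0) {
    stop("segment mass must be a nonnegative scalar")
  }
  inertia <- matrix(as.numeric(inertia), 3L, 3L)
  if (max(abs(inertia - t(inertia))) > 1e-9) stop("inertia must be symmetric")
  ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) stop("inertia must be positive semidefinite")
  length_axis <- as.numeric(length_axis)
  if (abs(norm3(length_axis) - 1) > 1e-9) stop("length_axis must be unit norm")
  structure(
    list(name = as.character(name), parent = as.character(parent),
         joint = joint, location_in_parent = location_in_parent,
         mass = mass, com = com, inertia = inertia,
         length_axis = length_axis),
    class = "lsm_segment"
  )
}

#' Register a marker on a model segment
#'
#' @param name marker identifier (unique within a model)
#' @param segment name of the segment the marker is fixed to
#' @param local_position 3-vector, m, in the segment frame
#' @param weight nonnegative inverse-kinematics tracking weight
#' @return one-row tibble describing the registration
#' @export
marker_registration <- function(name, segment, local_position, weight = 1) {
  local_position <- as.numeric(local_position)
  stopifnot(length(local_position) == 3L)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0) {
    stop("marker weight must be a nonnegative scalar")
  }
  tibble::tibble(
    name = as.character(name), segment = as.character(segment),
    lx = local_position[1L], ly = local_position[2L], lz = local_position[3L],
    weight = as.numeric(weight)
  )
}

#' Assemble a link-segment model
#'
#' Validates that the segments form a tree rooted at a single segment, that
#' marker and coordinate names are unique, and that every marker's segment
#' exists, then precomputes the indexing used by forward kinematics, IK and
#' inverse dynamics.
#'
#' @param segments list of [segment()] objects
#' @param markers tibble of marker registrations, as rows built by
#'   [marker_registration()] (bind them with `rbind` / `dplyr::bind_rows`)
#' @param name model identifier
#' @return an object of class `link_segment_model`
#' @export
link_segment_model <- function(segments, markers, name = "model") {
  stopifnot(is.list(segments), length(segments) >= 1L)
  if (!all(vapply(segments, inherits, logical(1), "lsm_segment"))) {
    stop("segments must all be built with segment()")
  }
  seg_names <- vapply(segments, `[[`, character(1), "name")
  if (anyDuplicated(seg_names)) stop("duplicate segment names")
  names(segments) <- seg_names
  parents <- vapply(segments, `[[`, character(1), "parent")
  roots <- seg_names[is.na(parents)]
  if (length(roots) != 1L) {
    stop(sprintf("model must have exactly one root segment, found %d",
                 length(roots)))
  }
  bad <- parents[!is.na(parents) & !(parents %in% seg_names)]
  if (length(bad) > 0L) {
    stop("unknown parent segment(s): ", paste(unique(bad), collapse = ", "))
  }
  order <- topo_order(seg_names, parents)

  markers <- tibble::as_tibble(markers)
  req <- c("name", "segment", "lx", "ly", "lz", "weight")
  if (!all(req %in% names(markers))) {
    stop("markers must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(markers$name)) stop("duplicate marker names")
  unknown <- setdiff(markers$segment, seg_names)
  if (length(unknown) > 0L) {
    stop("marker(s) on unknown segment(s): ", paste(unknown, collapse = ", "))
  }

  model <- structure(
    list(name = as.character(name), segments = segments[order],
         markers = markers),
    class = "link_segment_model"
  )
  compile_model(model)
}

# Parent-before-child ordering of the segment tree (depth-first from root).
topo_order <- function(seg_names, parents) {
  children <- split(seg_names, factor(ifelse(is.na(parents), ".ground", parents),
                                      levels = c(".ground", seg_names)))
  out <- character(0)
  visit <- function(nm) {
    out <<- c(out, nm)
    for (ch in children[[nm]]) visit(ch)
  }
  visit(children[[".ground"]])
  if (length(out) != length(seg_names)) {
    stop("segment graph is not a tree (cycle or unreachable segment)")
  }
  out
}

# Precompute flat arrays used by the hot paths. Called by every operation
# that returns a modified model.
compile_model <- function(model) {
  segs <- model$segments
  S <- length(segs)
  seg_names <- names(segs)
  parent_idx <- integer(S)
  coord_rows <- list()
  qi <- 0L
  for (i in seq_len(S)) {
    s <- segs[[i]]
    parent_idx[i] <- if (is.na(s$parent)) 0L else match(s$parent, seg_names)
    j <- s$joint
    dof <- j$n_trans + j$n_rot
    kind <- c(rep("trans", j$n_trans), rep("rot", j$n_rot))
    coord_rows[[i]] <- tibble::tibble(
      name = j$coordinate_names, segment = s$name, kind = kind,
      dof_index = seq_len(dof), index = qi + seq_len(dof),
      lower = j$bounds[1L, ], upper = j$bounds[2L, ]
    )
    qi <- qi + dof
  }
  coords <- dplyr::bind_rows(coord_rows)
  free_nonroot <- vapply(segs, function(s) s$joint$type == "free" &&
                           !is.na(s$parent), logical(1))
  if (any(free_nonroot)) {
    stop("free (6-dof) joints are only supported at the root segment")
  }
  if (anyDuplicated(coords$name)) {
    stop("coordinate names must be unique across joints: duplicated ",
         paste(unique(coords$name[duplicated(coords$name)]), collapse = ", "))
  }
  # ancestor[i, j] is TRUE when segment i is segment j or one of its ancestors
  anc <- diag(TRUE, S)
  for (jseg in seq_len(S)) {
    p <- parent_idx[jseg]
    while (p > 0L) {
      anc[p, jseg] <- TRUE
      p <- parent_idx[p]
    }
  }
  mk <- model$markers
  model$compiled <- list(
    n_seg = S, seg_names = seg_names, parent_idx = parent_idx,
    n_q = qi, coords = coords,
    lower = coords$lower, upper = coords$upper,
    coord_seg = match(coords$segment, seg_names),
    ancestor = anc,
    marker_seg = match(mk$segment, seg_names),
    marker_local = rbind(mk$lx, mk$ly, mk$lz),
    marker_weight = mk$weight, marker_names = mk$name
  )
  model
}

#' @export
print.link_segment_model <- function(x, ...) {
  cc <- x$compiled
  cat(sprintf("<link_segment_model '%s'>\n", x$name))
  cat(sprintf("  %d segments, %d coordinates, %d markers, total mass %.2f kg\n",
              cc$n_seg, cc$n_q, length(cc$marker_names),
              sum(vapply(x$segments, `[[`, numeric(1), "mass"))))
  invisible(x)
}

#' Coordinate table of a model
#'
#' @param model a [link_segment_model()]
#' @return tibble with one row per generalized coordinate: `name`,
#'   `segment`, `kind` (`"trans"` or `"rot"`), `lower`, `upper`
#' @export
model_coordinates <- function(model) {
  stopifnot(inherits(model, "link_segment_model"))
  model$compiled$coords[c("name", "segment", "kind", "lower", "upper")]
}

#' Neutral pose of a model (all coordinates zero, clamped into bounds)
#'
#' @param model a [link_segment_model()]
#' @return named coordinate vector
#' @export
neutral_pose <- function(model) {
  cc <- model$compiled
  q <- clamp(rep(0, cc$n_q), cc$lower, cc$upper)
  names(q) <- cc$coords$name
  q
}

# Validate and order a user-supplied coordinate vector.
check_q <- function(model, q, check_bounds = TRUE) {
  cc <- model$compiled
  if (!is.null(names(q)) && !identical(names(q), cc$coords$name)) {
    missing <- setdiff(cc$coords$name, names(q))
    extra <- setdiff(names(q), cc$coords$name)
    if (length(extra) > 0L) {
      stop("unknown coordinate name(s): ", paste(extra, collapse = ", "))
    }
    if (length(missing) > 0L) {
      stop("missing coordinate value(s): ", paste(missing, collapse = ", "))
    }
    q <- q[cc$coords$name]
  }
  if (length(q) != cc$n_q) {
    stop(sprintf("q must have %d entries, got %d", cc$n_q, length(q)))
  }
  q <- as.numeric(q)
  if (check_bounds) {
    tol <- 1e-9
    bad <- which(q < cc$lower - tol | q > cc$upper + tol)
    if (length(bad) > 0L) {
      stop("coordinate out of bounds: ",
           paste(cc$coords$name[bad], collapse = ", "))
    }
  }
  q
}

# Core pose computation. Returns per-segment ground-frame rotation matrices
# and joint-centre positions, plus the ground-frame direction of every
# rotational coordinate axis at this pose (needed by the IK Jacobian and by
# inverse dynamics).
fk_state <- function(model, q) {
  cc <- model$compiled
  segs <- model$segments
  S <- cc$n_seg
  R <- vector("list", S)
  p <- matrix(0, 3L, S)
  axis_g <- matrix(0, 3L, cc$n_q)  # rot coords only; trans columns hold axis too
  for (i in seq_len(S)) {
    s <- segs[[i]]
    j <- s$joint
    pi_ <- cc$parent_idx[i]
    if (pi_ > 0L) {
      Rp <- R[[pi_]]
      pj <- p[, pi_] + Rp %*% s$location_in_parent
    } else {
      Rp <- diag(3)
      pj <- s$location_in_parent
    }
    pj <- as.numeric(pj)
    row0 <- cc$coords$index[cc$coord_seg == i][1L]
    qseg <- q[row0 + seq_len(j$n_trans + j$n_rot) - 1L]
    if (j$n_trans > 0L) {
      # free-joint translations act along the parent's axes
      pj <- pj + as.numeric(Rp %*% qseg[1:3])
      axis_g[, row0:(row0 + 2L)] <- Rp
    }
    Rcur <- Rp
    if (j$n_rot > 0L) {
      for (k in seq_len(j$n_rot)) {
        ak <- as.numeric(Rcur %*% j$axes[, k])
        axis_g[, row0 + j$n_trans + k - 1L] <- ak
        Rcur <- Rcur %*% rot_axis_angle(j$axes[, k], qseg[j$n_trans + k])
      }
    }
    R[[i]] <- Rcur
    p[, i] <- pj
  }
  list(R = R, p = p, axis_g = axis_g)
}

#' Forward kinematics: ground-frame marker positions at a pose
#'
#' Composes the joint transforms from the root down and maps every
#' registered marker's local position into the ground frame.
#'
#' @param model a [link_segment_model()]
#' @param q coordinate vector (named or in model coordinate order), within
#'   bounds
#' @return 3 x M matrix of marker positions, m, columns named by marker
#' @examples
#' m <- default_gait_model()
#' fk <- forward_kinematics(m, neutral_pose(m))
#' dim(fk)
#' @export
forward_kinematics <- function(model, q) {
  stopifnot(inherits(model, "link_segment_model"))
  q <- check_q(model, q)
  st <- fk_state(model, q)
  marker_positions(model, st)
}

# Marker ground positions from a precomputed fk_state.
marker_positions <- function(model, st) {
  cc <- model$compiled
  M <- length(cc$marker_names)
  out <- matrix(0, 3L, M)
  for (i in seq_len(M)) {
    s <- cc$marker_seg[i]
    out[, i] <- st$R[[s]] %*% cc$marker_local[, i] + st$p[, s]
  }
  colnames(out) <- cc$marker_names
  out
}
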