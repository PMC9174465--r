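# Body-segment scaling: each segment carries a triplet of dimensionless
# factors along its own frame axes. Geometry expressed in a segment's frame
# (its com, its markers, and its children's joint centres) is stretched
# componentwise by that segment's factors.

#' Build a set of per-segment scale factors
#'
#' Factors may be given as scalars (isotropic) or 3-vectors (per segment
#' axis). Segments not mentioned default to 1.
#'
#' @param ... named arguments, one per segment, e.g.
#'   `scale_factors(thigh_r = 1.05, shank_r = c(1, 1.02, 1))`
#' @param .list alternatively, a named list of the same
#' @return object of class `scale_factor_set`: named list of positive
#'   3-vectors
#' @export
scale_factors <- function(..., .list = NULL) {
  fs <- .list %||% list(...)
  if (length(fs) > 0L && (is.null(names(fs)) || any(names(fs) == ""))) {
    stop("scale factors must be named by segment")
  }
  fs <- lapply(fs, function(f) {
    f <- as.numeric(f)
    if (length(f) == 1L) f <- rep(f, 3L)
    if (length(f) != 3L) stop("each scale factor must be a scalar or 3-vector")
    if (any(f <= 0)) stop("scale factors must be strictly positive")
    f
  })
  structure(fs, class = "scale_factor_set")
}

#' Scale a link-segment model
#'
#' Applies per-segment dimension changes: each segment's com and marker
#' local positions are multiplied componentwise by its own factors, and each
#' segment's joint centre (`location_in_parent`) by its parent's factors.
#' Markers stay fixed relative to the segment's anatomical frame, so their
#' ground-frame positions move with the segment's dimensions.
#'
#' Mass properties follow a volume rule by default: mass scales with the
#' product of the three factors, and inertia with (new mass / old mass)
#' times the square of the stretch along the segment's `length_axis`. Set
#' `preserve_mass_properties = TRUE` to scale geometry only.
#'
#' @param model a [link_segment_model()]
#' @param factors a [scale_factors()] set; omitted segments default to 1
#' @param preserve_mass_properties keep mass and inertia unchanged
#' @return the scaled model
#' @examples
#' m <- default_gait_model()
#' m2 <- scale_model(m, scale_factors(thigh_r = 1.1))
#' @export
scale_model <- function(model, factors, preserve_mass_properties = FALSE) {
  stopifnot(inherits(model, "link_segment_model"))
  if (!inherits(factors, "scale_factor_set")) {
    factors <- scale_factors(.list = as.list(factors))
  }
  unknown <- setdiff(names(factors), names(model$segments))
  if (length(unknown) > 0L) {
    stop("scale factors for unknown segment(s): ",
         paste(unknown, collapse = ", "))
  }
  fac <- function(nm) factors[[nm]] %||% c(1, 1, 1)
  segs <- model$segments
  for (nm in names(segs)) {
    s <- segs[[nm]]
    f <- fac(nm)
    if (!is.na(s$parent)) s$location_in_parent <- s$location_in_parent * fac(s$parent)
    s$com <- s$com * f
    if (!preserve_mass_properties && s$mass > 0) {
      mass_ratio <- prod(f)
      s_len <- norm3(f * s$length_axis)
      s$inertia <- s$inertia * (mass_ratio * s_len^2)
      s$mass <- s$mass * mass_ratio
    }
    segs[[nm]] <- s
  }
  mk <- model$markers
  fmat <- t(vapply(mk$segment, fac, numeric(3), USE.NAMES = FALSE))
  mk$lx <- mk$lx * fmat[, 1L]
  mk$ly <- mk$ly * fmat[, 2L]
  mk$lz <- mk$lz * fmat[, 3L]
  out <- model
  out$segments <- segs
  out$markers <- mk
  # scaling changes geometry only, never the tree, coordinates or marker
  # identities, so the compiled index tables stay valid
  out$compiled$marker_local <- rbind(mk$lx, mk$ly, mk$lz)
  out
}
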