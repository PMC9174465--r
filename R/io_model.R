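# Model configuration files: one YAML document describing segments,
# joints, markers and weights. Round-trips read -> write -> read are
# lossless (numbers are written with 15 significant digits).

#' Write a model to a YAML configuration file
#'
#' @param model a [link_segment_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "link_segment_model"))
  seg_doc <- lapply(model$segments, function(s) {
    j <- s$joint
    list(
      name = s$name,
      parent = if (is.na(s$parent)) NULL else s$parent,
      joint = list(
        type = j$type,
        axes = lapply(seq_len(ncol(j$axes)), function(k) as.numeric(j$axes[, k])),
        coordinates = as.list(j$coordinate_names),
        bounds = lapply(seq_len(ncol(j$bounds)), function(k)
          as.numeric(j$bounds[, k]))),
      location_in_parent = as.numeric(s$location_in_parent),
      mass = s$mass,
      com = as.numeric(s$com),
      inertia = lapply(1:3, function(r) as.numeric(s$inertia[r, ])),
      length_axis = as.numeric(s$length_axis))
  })
  mk_doc <- lapply(seq_len(nrow(model$markers)), function(i) {
    m <- model$markers[i, ]
    list(name = m$name, segment = m$segment,
         position = c(m$lx, m$ly, m$lz), weight = m$weight)
  })
  doc <- list(name = model$name, segments = unname(seg_doc),
              markers = mk_doc)
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

#' Read a model from a YAML configuration file
#'
#' @param path file written by [write_model()] (schema documented there)
#' @return a [link_segment_model()]
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$segments)) stop("model config has no segments: ", path)
  segs <- lapply(doc$segments, function(sd) {
    jd <- sd$joint
    axes <- lapply(jd$axes, as.numeric)
    bounds <- if (!is.null(jd$bounds))
      do.call(cbind, lapply(jd$bounds, as.numeric)) else NULL
    segment(
      name = sd$name,
      parent = sd$parent %||% NA_character_,
      joint = joint_spec(jd$type, axes = axes,
                         coordinate_names = unlist(jd$coordinates),
                         bounds = bounds),
      location_in_parent = as.numeric(sd$location_in_parent),
      mass = sd$mass %||% 0,
      com = as.numeric(sd$com %||% c(0, 0, 0)),
      inertia = do.call(rbind, lapply(sd$inertia %||%
                                        list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                                      as.numeric)),
      length_axis = as.numeric(sd$length_axis %||% c(0, 1, 0)))
  })
  markers <- dplyr::bind_rows(lapply(doc$markers, function(md) {
    marker_registration(md$name, md$segment, as.numeric(md$position),
                        weight = md$weight %||% 1)
  }))
  link_segment_model(segs, markers, name = doc$name %||% "model")
}
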