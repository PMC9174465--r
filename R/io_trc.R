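# TRC marker-trajectory files: tab-delimited, five header lines (file type,
# header keys, header values, marker names, per-marker X/Y/Z labels), then
# one row per frame of Frame#, Time and X/Y/Z triples. Units of mm or m are
# honored; positions are metres in memory. Blank cells mark missing
# samples.

#' Read a TRC marker file
#'
#' @param path file path
#' @return a [marker_trajectories()]; positions in m, missing samples `NA`
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("TRC file too short: ", path)
  hdr_keys <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  hv <- stats::setNames(as.list(hdr_vals), hdr_keys[seq_along(hdr_vals)])
  units <- hv[["Units"]] %||% "mm"
  if (!units %in% c("mm", "m")) {
    stop("TRC line 3: unsupported Units '", units, "'")
  }
  to_m <- if (units == "mm") 1e-3 else 1
  n_markers <- as.integer(hv[["NumMarkers"]] %||% NA)
  n_frames <- as.integer(hv[["NumFrames"]] %||% NA)
  name_cells <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]]
  markers <- name_cells[name_cells != "" &
                          !name_cells %in% c("Frame#", "Time")]
  if (!is.na(n_markers) && length(markers) != n_markers) {
    stop(sprintf("TRC line 4: %d marker names but header declares %d",
                 length(markers), n_markers))
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  if (!is.na(n_frames) && length(data_lines) != n_frames) {
    stop(sprintf("TRC: %d data rows but header declares %d frames",
                 length(data_lines), n_frames))
  }
  ncol_exp <- 2L + 3L * length(markers)
  rows <- strsplit(data_lines, "\t", fixed = TRUE)
  Tn <- length(rows)
  times <- numeric(Tn)
  xyz <- array(NA_real_, c(3L, length(markers), Tn),
               dimnames = list(c("x", "y", "z"), markers, NULL))
  for (t in seq_len(Tn)) {
    cells <- rows[[t]]
    if (length(cells) < ncol_exp) cells <- c(cells, rep("", ncol_exp - length(cells)))
    if (length(cells) > ncol_exp) {
      stop(sprintf("TRC data line %d: %d columns, expected %d",
                   t + 5L, length(cells), ncol_exp))
    }
    cells[cells == ""] <- NA
    vals <- suppressWarnings(as.numeric(cells))
    if (is.na(vals[2L])) stop(sprintf("TRC data line %d: bad time stamp", t + 5L))
    times[t] <- vals[2L]
    xyz[, , t] <- matrix(vals[-(1:2)], nrow = 3L) * to_m
  }
  rate <- suppressWarnings(as.numeric(hv[["DataRate"]] %||% NA))
  marker_trajectories(times, xyz,
                      rate = if (is.na(rate)) NULL else rate)
}

#' Write a TRC marker file
#'
#' @param trajectories a [marker_trajectories()]
#' @param path output path
#' @param units `"mm"` (conventional) or `"m"`
#' @return `path`, invisibly
#' @export
write_trc <- function(trajectories, path, units = c("mm", "m")) {
  stopifnot(inherits(trajectories, "marker_trajectories"))
  units <- match.arg(units)
  from_m <- if (units == "mm") 1e3 else 1
  M <- length(trajectories$names)
  Tn <- n_frames(trajectories)
  rate <- trajectories$rate
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  l3 <- paste(c(fmt_num(rate), fmt_num(rate), Tn, M, units, fmt_num(rate),
                1L, Tn), collapse = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(trajectories$names, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), M),
                               rep(seq_len(M), each = 3L))), collapse = "\t")
  body <- vapply(seq_len(Tn), function(t) {
    v <- as.numeric(trajectories$xyz[, , t]) * from_m
    cells <- ifelse(is.na(v), "", fmt_num(v))
    paste(c(t, fmt_num(trajectories$times[t]), cells), collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, body), path)
  invisible(path)
}

# Full-precision numeric formatting shared by the text writers; round-trips
# doubles well below the formats' stated 1e-9 tolerance.
fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- ""
  out
}
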