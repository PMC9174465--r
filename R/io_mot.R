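# MOT/STO tab-delimited time-series files: a key=value header terminated by
# `endheader`, a column-label line starting with `time`, then the numeric
# table. Used for coordinates, ground reaction loads, moments and powers.

#' Read a MOT/STO table
#'
#' @param path file path
#' @return tibble with a `time` column; attributes `name` and `in_degrees`
#'   carry the header metadata. Angular columns are converted to radians
#'   when the header declares `inDegrees=yes` and `convert_degrees` is
#'   `TRUE`.
#' @param convert_degrees convert angular values to radians when the file
#'   is in degrees (translation columns, identified by the conventional
#'   `_tx/_ty/_tz` suffixes and force/point labels, are left alone)
#' @export
read_mot <- function(path, convert_degrees = TRUE) {
  lines <- readLines(path, warn = FALSE)
  end <- match(TRUE, trimws(tolower(lines)) == "endheader")
  if (is.na(end)) stop("not a MOT/STO file (no endheader): ", path)
  hdr <- lines[seq_len(end - 1L)]
  kv <- strsplit(hdr[grepl("=", hdr, fixed = TRUE)], "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) trimws(x[2L])),
    vapply(kv, function(x) trimws(tolower(x[1L])), character(1)))
  nm <- if (length(hdr) > 0L && !grepl("=", hdr[1L], fixed = TRUE))
    trimws(hdr[1L]) else basename(path)
  in_deg <- identical(tolower(meta[["indegrees"]] %||% "no"), "yes")
  lab_line <- end + 1L
  labels <- strsplit(lines[lab_line], "\t", fixed = TRUE)[[1L]]
  labels <- trimws(labels)
  if (anyDuplicated(labels)) stop("duplicate column labels in ", path)
  data_lines <- lines[-seq_len(lab_line)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  n_rows <- suppressWarnings(as.integer(meta[["nrows"]] %||% NA))
  if (!is.na(n_rows) && length(data_lines) != n_rows) {
    stop(sprintf("%s: %d data rows but header declares %d", path,
                 length(data_lines), n_rows))
  }
  vals <- lapply(strsplit(data_lines, "\t", fixed = TRUE), function(cells) {
    v <- suppressWarnings(as.numeric(trimws(cells)))
    if (length(v) != length(labels)) {
      stop(sprintf("%s: row with %d columns, expected %d", path,
                   length(v), length(labels)))
    }
    v
  })
  tbl <- tibble::as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, vals)), labels))
  if (in_deg && convert_degrees) {
    ang <- !grepl("(_t[xyz]$)|force|torque|moment|^time$|_p[xyz]$|power",
                  labels)
    for (j in which(ang)) tbl[[j]] <- tbl[[j]] * pi / 180
  }
  attr(tbl, "name") <- nm
  attr(tbl, "in_degrees") <- in_deg
  tbl
}

#' Write a MOT/STO table
#'
#' @param table data frame whose first column is `time`
#' @param path output path
#' @param name header name field
#' @param in_degrees write (and declare) angular columns in degrees; the
#'   input is assumed to be in radians and is converted on the way out
#' @return `path`, invisibly
#' @export
write_mot <- function(table, path, name = NULL, in_degrees = FALSE) {
  stopifnot(is.data.frame(table))
  if (names(table)[1L] != "time") stop("first column must be `time`")
  tbl <- as.data.frame(table)
  labels <- names(tbl)
  if (in_degrees) {
    ang <- !grepl("(_t[xyz]$)|force|torque|moment|^time$|_p[xyz]$|power",
                  labels)
    for (j in which(ang)) tbl[[j]] <- tbl[[j]] * 180 / pi
  }
  hdr <- c(name %||% basename(path),
           "version=1",
           sprintf("nRows=%d", nrow(tbl)),
           sprintf("nColumns=%d", ncol(tbl)),
           sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
           "endheader")
  body <- vapply(seq_len(nrow(tbl)), function(i) {
    paste(fmt_num(as.numeric(tbl[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(labels, collapse = "\t"), body), path)
  invisible(path)
}

#' Default ground-reaction-force column mapping
#'
#' Maps MOT column prefixes to the segments loads act on, following the
#' common convention `<prefix>vx/vy/vz` (force), `<prefix>px/py/pz` (centre
#' of pressure) and `<torque_prefix>x/y/z` (free moment).
#'
#' @param ... per-load lists with fields `segment`, `force`, `point`,
#'   `torque` (prefix strings)
#' @return list of load mappings
#' @export
grf_column_mapping <- function(...) {
  maps <- list(...)
  if (length(maps) == 0L) {
    maps <- list(
      list(segment = "foot_r", force = "ground_force_v",
           point = "ground_force_p", torque = "ground_torque_"),
      list(segment = "foot_l", force = "1_ground_force_v",
           point = "1_ground_force_p", torque = "1_ground_torque_"))
  }
  maps
}

#' Interpret a MOT table as external loads
#'
#' @param table a [read_mot()] tibble containing GRF columns
#' @param mapping a [grf_column_mapping()]
#' @param min_force forces below this magnitude (N) get their centre of
#'   pressure zeroed (see [zero_cop_below()])
#' @return an [external_loads()]
#' @export
as_external_loads <- function(table, mapping = grf_column_mapping(),
                              min_force = 10) {
  stopifnot(is.data.frame(table), "time" %in% names(table))
  pick <- function(prefix) {
    cols <- paste0(prefix, c("x", "y", "z"))
    miss <- setdiff(cols, names(table))
    if (length(miss) > 0L) {
      stop("GRF columns not found: ", paste(miss, collapse = ", "))
    }
    as.matrix(table[cols])
  }
  args <- lapply(mapping, function(mp) {
    list(segment = mp$segment, force = pick(mp$force),
         point = pick(mp$point), torque = pick(mp$torque))
  })
  loads <- do.call(external_loads, c(list(times = table$time), args))
  zero_cop_below(loads, threshold = min_force)
}

#' Write external loads as a GRF MOT table
#'
#' @param loads an [external_loads()]
#' @param path output path
#' @param mapping a [grf_column_mapping()] naming the output columns, in
#'   the same order as the loads
#' @return `path`, invisibly
#' @export
write_grf_mot <- function(loads, path, mapping = grf_column_mapping()) {
  stopifnot(inherits(loads, "external_loads"))
  if (length(mapping) != length(loads$loads)) {
    stop("mapping must have one entry per load")
  }
  tbl <- data.frame(time = loads$times)
  for (i in seq_along(loads$loads)) {
    l <- loads$loads[[i]]
    mp <- mapping[[i]]
    for (k in 1:3) {
      ax <- c("x", "y", "z")[k]
      tbl[[paste0(mp$force, ax)]] <- l$force[, k]
      tbl[[paste0(mp$point, ax)]] <- l$point[, k]
      tbl[[paste0(mp$torque, ax)]] <- l$torque[, k]
    }
  }
  write_mot(tbl, path, name = "ground reaction loads")
}
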