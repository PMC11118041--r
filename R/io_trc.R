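# TRC marker-file reader/writer (OpenSim-style dialect).
#
# Header layout:
#   line 1: PathFileType <tab> 4 <tab> (X/Y/Z) <tab> <filename>
#   line 2: DataRate CameraRate NumFrames NumMarkers Units OrigDataRate
#           OrigDataStartFrame OrigNumFrames  (tab-separated labels)
#   line 3: the corresponding values
#   line 4: Frame# <tab> Time <tab> <marker names, one per 3 columns>
#   line 5: X1 Y1 Z1 X2 ... coordinate labels
#   line 6: blank
#   data  : Frame# Time X Y Z ...
# Units are fixed to mm on write; "m" files are converted to mm on read.

#' Write a marker table to a TRC file
#'
#' @param table A [marker_table].
#' @param path Output file path.
#' @return `path`, invisibly. Values round-trip through [read_trc] to
#'   within 1e-6 mm.
#' @export
write_trc <- function(table, path) {
  if (!inherits(table, "marker_table")) {
    stop("`table` must be a marker_table", call. = FALSE)
  }
  n <- length(table$time)
  if (n < 1L) stop("cannot write a zero-frame marker table", call. = FALSE)
  nm <- length(table$markers)
  fs <- table$sampling_rate

  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf(
                    "cannot open '%s' for writing: %s", path,
                    conditionMessage(e)), call. = FALSE))
  on.exit(close(con), add = TRUE)

  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(sprintf("%.6f\t%.6f\t%d\t%d\tmm\t%.6f\t1\t%d",
                     fs, fs, n, nm, fs, n), con)
  hdr <- c("Frame#", "Time",
           unlist(lapply(names(table$markers), function(x) c(x, "", ""))))
  writeLines(paste(hdr, collapse = "\t"), con)
  coord <- c("", "", unlist(lapply(seq_len(nm), function(i) {
    paste0(c("X", "Y", "Z"), i)
  })))
  writeLines(paste(coord, collapse = "\t"), con)
  writeLines("", con)

  mat <- do.call(cbind, table$markers)
  body <- paste(seq_len(n), sprintf("%.6f", table$time), sep = "\t")
  vals <- apply(mat, 1L, function(r) paste(sprintf("%.6f", r),
                                           collapse = "\t"))
  writeLines(paste(body, vals, sep = "\t"), con)
  invisible(path)
}

#' Read a TRC marker file
#'
#' @param path Path to a TRC file.
#' @param required Marker names that must be present (default none beyond
#'   what the file declares); pass [REQUIRED_MARKERS] to enforce the
#'   pipeline's marker set.
#' @return A [marker_table] in millimetres.
#' @export
read_trc <- function(path, required = character()) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop(sprintf(
                      "cannot read '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
  if (length(lines) < 6L) {
    stop(sprintf("TRC format error in '%s': fewer than 6 header lines",
                 path), call. = FALSE)
  }
  if (!grepl("^PathFileType", lines[1L])) {
    stop(sprintf("TRC format error in '%s' line 1: expected PathFileType, got '%s'",
                 path, lines[1L]), call. = FALSE)
  }
  labels <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  values <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (!all(c("DataRate", "NumMarkers", "NumFrames", "Units") %in% labels)) {
    stop(sprintf("TRC format error in '%s' line 2: missing DataRate/NumMarkers labels: '%s'",
                 path, lines[2L]), call. = FALSE)
  }
  meta <- stats::setNames(as.list(values[seq_along(labels)]), labels)
  fs <- suppressWarnings(as.numeric(meta$DataRate))
  nmark <- suppressWarnings(as.integer(meta$NumMarkers))
  units <- meta$Units
  if (is.na(fs) || fs <= 0) {
    stop(sprintf("TRC format error in '%s' line 3: bad DataRate '%s'",
                 path, meta$DataRate), call. = FALSE)
  }
  if (is.na(nmark) || nmark < 1L) {
    stop(sprintf("TRC format error in '%s' line 3: bad NumMarkers '%s'",
                 path, meta$NumMarkers), call. = FALSE)
  }
  name_row <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]]
  marker_names <- name_row[name_row != "" & !name_row %in% c("Frame#", "Time")]
  if (length(marker_names) != nmark) {
    stop(sprintf("TRC format error in '%s' line 4: %d marker names, header declares %d",
                 path, length(marker_names), nmark), call. = FALSE)
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L) {
    stop(sprintf("TRC format error in '%s': no data rows", path),
         call. = FALSE)
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  ncols <- 2L + 3L * nmark
  bad <- which(vapply(fields, length, integer(1)) != ncols)
  if (length(bad) > 0L) {
    stop(sprintf("TRC format error in '%s' data line %d: expected %d columns, got %d",
                 path, bad[1L], ncols, length(fields[[bad[1L]]])),
         call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(fields)), nrow = length(fields),
                ncol = ncols, byrow = TRUE)
  if (anyNA(mat[, 1:2])) {
    stop(sprintf("TRC format error in '%s': non-numeric frame/time field",
                 path), call. = FALSE)
  }
  time <- mat[, 2L]
  scale <- if (identical(units, "m")) 1000 else 1
  markers <- stats::setNames(lapply(seq_len(nmark), function(i) {
    mat[, 2L + 3L * (i - 1L) + 1:3, drop = FALSE] * scale
  }), marker_names)
  mt <- marker_table(fs, markers, time = time)
  if (length(required) > 0L) check_required_markers(mt, required)
  mt
}
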