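# MOT/STO force-file reader/writer (OpenSim storage dialect).
#
# Header: free name line, then `nRows=<n>`, `nColumns=<m>`, `endheader`,
# followed by a tab-separated column-name row and the data. Time is the
# first column; force components in N, centre of pressure in m.

MOT_COLUMNS <- c("time", "f_vert", "f_sag", "f_ml", "cop_x", "cop_y")

#' Write a force table to a MOT/STO file
#'
#' @param table A [force_table].
#' @param path Output file path.
#' @return `path`, invisibly. Values round-trip through [read_mot] to
#'   within 1e-6.
#' @export
write_mot <- function(table, path) {
  if (!inherits(table, "force_table")) {
    stop("`table` must be a force_table", call. = FALSE)
  }
  n <- length(table$time)
  if (n < 1L) stop("cannot write a zero-row force table", call. = FALSE)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf(
                    "cannot open '%s' for writing: %s", path,
                    conditionMessage(e)), call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeLines(basename(path), con)
  writeLines(sprintf("nRows=%d", n), con)
  writeLines(sprintf("nColumns=%d", length(MOT_COLUMNS)), con)
  writeLines("endheader", con)
  writeLines(paste(MOT_COLUMNS, collapse = "\t"), con)
  mat <- cbind(table$time, table$f_vert, table$f_sag, table$f_ml,
               table$cop_x, table$cop_y)
  writeLines(apply(mat, 1L, function(r) paste(sprintf("%.6f", r),
                                              collapse = "\t")), con)
  invisible(path)
}

#' Read a MOT/STO force file
#'
#' The sampling rate is recovered from the median time step.
#'
#' @param path Path to a MOT/STO file written by [write_mot] (or any file
#'   following the same dialect and column set).
#' @return A [force_table].
#' @export
read_mot <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop(sprintf(
                      "cannot read '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0L) {
    stop(sprintf("MOT format error in '%s': no endheader line", path),
         call. = FALSE)
  }
  end <- end[1L]
  header <- lines[seq_len(end - 1L)]
  get_meta <- function(key) {
    hit <- grep(sprintf("^%s=", key), trimws(header), value = TRUE)
    if (length(hit) == 0L) return(NA_integer_)
    suppressWarnings(as.integer(sub(sprintf("^%s=", key), "", hit[1L])))
  }
  nrows <- get_meta("nRows")
  ncols <- get_meta("nColumns")
  if (is.na(nrows) || nrows < 1L) {
    stop(sprintf("MOT format error in '%s': nRows missing or < 1", path),
         call. = FALSE)
  }
  col_line <- lines[end + 1L]
  cols <- strsplit(col_line, "\t", fixed = TRUE)[[1L]]
  if (!is.na(ncols) && length(cols) != ncols) {
    stop(sprintf("MOT format error in '%s': %d column names but header declares nColumns=%d",
                 path, length(cols), ncols), call. = FALSE)
  }
  missing <- setdiff(MOT_COLUMNS, cols)
  if (length(missing) > 0L) {
    stop(sprintf("MOT format error in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  data_lines <- lines[-(seq_len(end + 1L))]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nrows) {
    stop(sprintf("MOT format error in '%s': %d data rows but header declares nRows=%d",
                 path, length(data_lines), nrows), call. = FALSE)
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != length(cols))
  if (length(bad) > 0L) {
    stop(sprintf("MOT format error in '%s' data line %d: column-count mismatch",
                 path, bad[1L]), call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(fields)), nrow = nrows,
                ncol = length(cols), byrow = TRUE,
                dimnames = list(NULL, cols))
  time <- mat[, "time"]
  fs <- if (nrows > 1L) 1 / stats::median(diff(time)) else 1
  force_table(fs,
              f_vert = mat[, "f_vert"], f_sag = mat[, "f_sag"],
              f_ml = mat[, "f_ml"], cop_x = mat[, "cop_x"],
              cop_y = mat[, "cop_y"], time = time)
}
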