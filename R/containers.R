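# Core data containers: marker tables and force tables.
#
# Shared coordinate convention (all modules): right-handed axes with
# X = walking direction (antero-posterior), Y = vertical (up), Z =
# medio-lateral. Marker positions are stored in millimetres, forces in
# newtons, centre of pressure in metres. Frames are 1-based; the time of
# frame i is (i - 1)/sampling_rate.

REQUIRED_MARKERS <- c("RHEEL", "RTOE", "RANKLE", "RKNEE", "RHIP", "SACRUM")

#' Construct a marker trajectory table
#'
#' @param sampling_rate Sampling frequency in Hz (> 0).
#' @param markers Named list of n-by-3 numeric matrices (columns X, Y, Z),
#'   positions in millimetres. All markers must share one length.
#' @param time Optional time vector in seconds; defaults to
#'   `(0:(n-1))/sampling_rate`. Must be strictly increasing with no NaN.
#' @return An object of class `marker_table` with fields `sampling_rate`,
#'   `time`, `markers`.
#' @export
marker_table <- function(sampling_rate, markers, time = NULL) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.list(markers) || length(markers) == 0L ||
      is.null(names(markers)) || any(names(markers) == "")) {
    stop("`markers` must be a non-empty named list of n-by-3 matrices",
         call. = FALSE)
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker needs 3 columns (X, Y, Z)",
                            call. = FALSE)
    colnames(m) <- c("X", "Y", "Z")
    m
  })
  n <- nrow(markers[[1L]])
  if (n < 1L) stop("marker table must contain at least one frame",
                   call. = FALSE)
  lens <- vapply(markers, nrow, integer(1))
  if (any(lens != n)) {
    stop("all marker series must share one length", call. = FALSE)
  }
  if (is.null(time)) time <- (seq_len(n) - 1L) / sampling_rate
  if (length(time) != n) stop("`time` length must match marker length",
                              call. = FALSE)
  if (anyNA(time)) stop("`time` must not contain NaN/NA", call. = FALSE)
  if (n > 1L && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate, time = time, markers = markers),
    class = "marker_table"
  )
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("<marker_table> %d frames @ %g Hz, %d markers: %s\n",
              length(x$time), x$sampling_rate, length(x$markers),
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

# Validate that a marker_table carries the markers the pipeline needs.
check_required_markers <- function(mt, required = REQUIRED_MARKERS) {
  missing <- setdiff(required, names(mt$markers))
  if (length(missing) > 0L) {
    stop(sprintf("missing required marker(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(mt)
}

#' Construct a ground-reaction-force table
#'
#' Sagittal-plane GRF record: vertical force, antero-posterior (sagittal)
#' force, medio-lateral force, and centre of pressure. The COP is only
#' physically meaningful where the vertical force indicates contact; outside
#' contact it is stored as 0 by convention.
#'
#' @param sampling_rate Sampling frequency in Hz (> 0).
#' @param f_vert Vertical force, N (>= 0 during contact by convention).
#' @param f_sag Antero-posterior force, N.
#' @param f_ml Medio-lateral force, N.
#' @param cop_x,cop_y Centre of pressure, m (sagittal-plane coordinates).
#' @param time Optional time vector in seconds.
#' @return An object of class `force_table`.
#' @export
force_table <- function(sampling_rate, f_vert, f_sag, f_ml,
                        cop_x, cop_y, time = NULL) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  n <- length(f_vert)
  if (n < 1L) stop("force table must contain at least one frame",
                   call. = FALSE)
  series <- list(f_vert = f_vert, f_sag = f_sag, f_ml = f_ml,
                 cop_x = cop_x, cop_y = cop_y)
  lens <- vapply(series, length, integer(1))
  if (any(lens != n)) stop("all force series must share one length",
                           call. = FALSE)
  if (is.null(time)) time <- (seq_len(n) - 1L) / sampling_rate
  if (length(time) != n) stop("`time` length must match series length",
                              call. = FALSE)
  structure(
    c(list(sampling_rate = sampling_rate, time = time), series),
    class = "force_table"
  )
}

#' @export
print.force_table <- function(x, ...) {
  cat(sprintf("<force_table> %d frames @ %g Hz, peak f_vert %.1f N\n",
              length(x$time), x$sampling_rate, max(x$f_vert)))
  invisible(x)
}
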