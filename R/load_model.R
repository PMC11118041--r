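# Load-carriage model: proportional GRF scaling and the backpack point
# force. Carried load enters the simulation only through the forces; the
# kinematics are left untouched.

#' Construct a load condition
#'
#' @param load Carried load in kg (>= 0).
#' @param application_offset Length-2 numeric, metres: sagittal and
#'   vertical offset of the point of force application relative to the
#'   body centre of mass. Default `c(-0.02, 0.30)` (2 cm behind, 30 cm
#'   above), representing a backpack.
#' @return An object of class `load_condition`.
#' @export
load_condition <- function(load, application_offset = c(-0.02, 0.30)) {
  stopifnot_scalar_number(load, "load", nonnegative = TRUE)
  if (length(application_offset) != 2L || !is.numeric(application_offset)) {
    stop("`application_offset` must be a length-2 numeric (sagittal, vertical) in m",
         call. = FALSE)
  }
  structure(list(load = load, application_offset = application_offset),
            class = "load_condition")
}

#' Default carried-load grid (kg)
#' @return Numeric vector `c(0, 1, 3, 5, 10, 15, 20)`.
#' @export
default_loads <- function() c(0, 1, 3, 5, 10, 15, 20)

#' Scale ground reaction forces for a carried load
#'
#' Multiplies the vertical and sagittal (antero-posterior) force components
#' by `(1 + load/weight)`. The medio-lateral component, the centre of
#' pressure, and the time base are left unchanged: load effects on the
#' medio-lateral force and on GRF shape are not modelled.
#'
#' @param grf A [force_table].
#' @param load Carried load in kg (>= 0).
#' @param weight Subject body mass in kg (> 0).
#' @return A [force_table] with scaled `f_vert` and `f_sag`. At
#'   `load = 0` the input is returned unchanged.
#' @export
scale_grf <- function(grf, load, weight) {
  if (!inherits(grf, "force_table")) {
    stop("`grf` must be a force_table", call. = FALSE)
  }
  stopifnot_scalar_number(load, "load", nonnegative = TRUE)
  stopifnot_scalar_number(weight, "weight", positive = TRUE)
  if (load == 0) return(grf)
  k <- 1 + load / weight
  out <- grf
  out$f_vert <- grf$f_vert * k
  out$f_sag <- grf$f_sag * k
  out
}

#' Backpack point-force record
#'
#' Bookkeeping record of the concentrated vertical force representing the
#' carried backpack: magnitude `load * g` downward, applied 2 cm behind and
#' 30 cm above the body centre of mass (or a custom offset). The bottom-up
#' lower-limb inverse dynamics uses only the scaled GRFs; this record
#' exists for whole-body consistency checks.
#'
#' @param load Carried load in kg (>= 0).
#' @param com_position Length-2 numeric, metres: body COM (sagittal x,
#'   vertical y).
#' @param application_offset Offset of the application point from the COM,
#'   metres. Default `c(-0.02, 0.30)`.
#' @param gravity Gravitational acceleration, m/s^2. Default 9.81.
#' @return A list with `force` (length-2 vector, N; `c(0, -load*g)`),
#'   `magnitude` (N), and `position` (length-2 vector, m).
#' @export
backpack_force <- function(load, com_position,
                           application_offset = c(-0.02, 0.30),
                           gravity = 9.81) {
  stopifnot_scalar_number(load, "load", nonnegative = TRUE)
  if (length(com_position) != 2L || !is.numeric(com_position)) {
    stop("`com_position` must be a length-2 numeric (x, y) in m",
         call. = FALSE)
  }
  list(
    force = c(0, -load * gravity),
    magnitude = load * gravity,
    position = c(com_position[1] + application_offset[1],
                 com_position[2] + application_offset[2])
  )
}
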