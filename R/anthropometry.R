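# Subject anthropometry and body-segment inertial parameters.
#
# Segment parameters follow Winter's standard anthropometric tables:
# segment mass as a fraction of body mass, segment length as a fraction of
# stature, centre-of-mass position as a fraction of segment length from the
# proximal end, and radius of gyration about the COM as a fraction of
# segment length.

#' Default body-segment inertial parameters (Winter's tables)
#'
#' @return A data.frame with one row per segment (foot, shank, thigh) and
#'   columns `mass_frac`, `length_frac`, `com_frac`, `rog_frac`.
#' @export
default_segment_params <- function() {
  data.frame(
    segment     = c("foot", "shank", "thigh"),
    mass_frac   = c(0.0145, 0.0465, 0.1000),
    length_frac = c(0.152, 0.246, 0.245),
    com_frac    = c(0.500, 0.433, 0.433),
    rog_frac    = c(0.475, 0.302, 0.323),
    stringsAsFactors = FALSE
  )
}

#' Construct a subject anthropometry record
#'
#' @param mass Body mass in kg (> 0). This is the quantity the ground
#'   reaction forces are scaled against when a load is added.
#' @param height Stature in m (> 0).
#' @param segment_params Segment parameter table as returned by
#'   [default_segment_params()]; overridable for sensitivity analyses.
#' @return An object of class `anthropometry`.
#' @export
anthropometry <- function(mass, height,
                          segment_params = default_segment_params()) {
  stopifnot_scalar_number(mass, "mass", positive = TRUE)
  stopifnot_scalar_number(height, "height", positive = TRUE)
  sp <- as.data.frame(segment_params)
  needed <- c("segment", "mass_frac", "length_frac", "com_frac", "rog_frac")
  if (!all(needed %in% names(sp)) ||
      !all(c("foot", "shank", "thigh") %in% sp$segment)) {
    stop("`segment_params` must provide foot/shank/thigh rows with mass_frac, length_frac, com_frac, rog_frac",
         call. = FALSE)
  }
  if (any(sp$mass_frac < 0) || sum(sp$mass_frac) >= 1) {
    stop("segment mass fractions must be >= 0 and sum to < 1 (remainder is head-arms-trunk)",
         call. = FALSE)
  }
  rownames(sp) <- sp$segment
  structure(list(mass = mass, height = height, segment_params = sp),
            class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf("<anthropometry> mass %.1f kg, height %.2f m\n",
              x$mass, x$height))
  invisible(x)
}

# Derived absolute segment properties for one segment of a subject.
segment_properties <- function(subject, segment) {
  sp <- subject$segment_params[segment, ]
  len <- sp$length_frac * subject$height
  mass <- sp$mass_frac * subject$mass
  list(
    mass = mass,
    length = len,
    com_frac = sp$com_frac,
    # moment of inertia about the COM: m * (rog_frac * L)^2
    inertia = mass * (sp$rog_frac * len)^2
  )
}

#' Sample a synthetic study cohort
#'
#' Draws subject masses and heights from independent normal distributions
#' with the study population's moments, truncated below at physiologically
#' plausible floors (mass > 30 kg, height > 1.2 m) to exclude degenerate
#' bodies.
#'
#' @param n Number of subjects (>= 1). Default 15.
#' @param seed Integer seed; sampling is reproducible under a fixed seed.
#' @param mean_mass,sd_mass Population mass moments, kg. Defaults 66.6 and
#'   10.8.
#' @param mean_height,sd_height Population height moments, m. Defaults 1.69
#'   and 0.11.
#' @param segment_params Segment parameter table applied to every subject.
#' @return A list of `n` [anthropometry] objects, with subject ids
#'   `S01`, `S02`, ... attached as names.
#' @export
sample_cohort <- function(n = 15, seed = 1,
                          mean_mass = 66.6, sd_mass = 10.8,
                          mean_height = 1.69, sd_height = 0.11,
                          segment_params = default_segment_params()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot_scalar_number(sd_mass, "sd_mass", nonnegative = TRUE)
  stopifnot_scalar_number(sd_height, "sd_height", nonnegative = TRUE)
  draws <- with_seed(seed, {
    mass <- rep(NA_real_, n)
    height <- rep(NA_real_, n)
    todo <- seq_len(n)
    while (length(todo) > 0L) {
      mass[todo] <- stats::rnorm(length(todo), mean_mass, sd_mass)
      height[todo] <- stats::rnorm(length(todo), mean_height, sd_height)
      todo <- which(mass <= 30 | height <= 1.2)
    }
    list(mass = mass, height = height)
  })
  ids <- sprintf("S%02d", seq_len(n))
  cohort <- lapply(seq_len(n), function(i) {
    anthropometry(draws$mass[i], draws$height[i],
                  segment_params = segment_params)
  })
  names(cohort) <- ids
  cohort
}
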