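# Outcome-table export: tidy long CSV plus one wide "mean (sd)" CSV per
# outcome (rows = joint x load, columns = speed), mirroring the layout of
# published speed-by-load summary tables.

OUTCOME_MEASURES <- c(peak_torque = "peak_torque", peak_power = "peak_power",
                      work = "work")

# Across-subject mean/sd per joint x load x speed cell, as "mean (sd)".
# Means are computed with sum()/n in subject order as stored, so repeated
# runs give byte-identical output.
wide_outcome_table <- function(grid, measure) {
  joints <- c("ankle", "knee", "hip")
  loads <- sort(unique(grid$load))
  speeds <- sort(unique(grid$speed))
  rows <- list()
  for (j in joints) {
    for (l in loads) {
      cells <- vapply(speeds, function(s) {
        v <- grid[[measure]][grid$joint == j & grid$load == l &
                             grid$speed == s]
        sprintf("%.3f (%.3f)", sum(v) / length(v), stats::sd(v))
      }, character(1))
      rows[[length(rows) + 1L]] <- c(joint = j, load = l, cells)
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("joint", "load_kg", sprintf("speed_%g_kmh", speeds))
  out
}

#' Write outcome-grid CSV files
#'
#' Writes `outcomes_tidy.csv` (one row per subject x speed x load x joint)
#' and, per outcome measure, `<measure>_wide.csv` with "mean (sd)" cells
#' across subjects, rows = joint x load and columns = speed. The wide-cell
#' means equal the plain mean over subjects of the tidy values (summation
#' in stored subject order).
#'
#' @param grid An outcome grid from [build_outcome_grid()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_outcome_csv <- function(grid, dir) {
  subjects <- unique(grid$subject_id)
  check_grid_complete(grid, subjects = subjects,
                      speeds = unique(grid$speed),
                      loads = unique(grid$load))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, "outcomes_tidy.csv")
  utils::write.csv(grid, files[1L], row.names = FALSE)
  for (m in OUTCOME_MEASURES) {
    f <- file.path(dir, sprintf("%s_wide.csv", m))
    utils::write.csv(wide_outcome_table(grid, m), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Speed-by-load outcome surface
#'
#' Across-subject mean of one outcome for one joint, as a load x speed
#' matrix (rows = loads, columns = speeds) ready for surface plotting.
#'
#' @param grid An outcome grid.
#' @param measure One of `"peak_torque"`, `"peak_power"`, `"work"`.
#' @param joint One of `"ankle"`, `"knee"`, `"hip"`.
#' @return A numeric matrix with loads as rownames and speeds as colnames.
#' @export
outcome_surface <- function(grid, measure = names(OUTCOME_MEASURES),
                            joint = c("ankle", "knee", "hip")) {
  measure <- match.arg(measure)
  joint <- match.arg(joint)
  g <- grid[grid$joint == joint, ]
  loads <- sort(unique(g$load))
  speeds <- sort(unique(g$speed))
  m <- outer(loads, speeds, Vectorize(function(l, s) {
    mean(g[[measure]][g$load == l & g$speed == s])
  }))
  dimnames(m) <- list(load = as.character(loads),
                      speed = as.character(speeds))
  m
}
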