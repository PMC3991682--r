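# Core record types for an ICA decomposition: one component = a 3D Z-score
# map plus a time course on a shared grid.

#' Construct a single ICA component record
#'
#' Bundles a component's spatial Z-score map, its time course (one column of
#' the mixing matrix), and the grid geometry needed to express distances in
#' millimetres. Component indices are 0-based internally (volume/column order);
#' all user-facing output adds 1 to match the MELODIC display convention.
#'
#' @param component_index Integer >= 0, the 0-based volume/column index.
#' @param zmap 3D numeric array of Z-scores.
#' @param timecourse Numeric vector of T >= 2 samples.
#' @param voxel_dims Positive numeric length-3 vector, voxel edge lengths (mm).
#' @param tr Sampling interval (repetition time) in seconds.
#' @return An object of class `nc_component`.
#' @export
component_record <- function(component_index, zmap, timecourse,
                             voxel_dims = c(1, 1, 1), tr = 1) {
  if (length(dim(zmap)) != 3L) {
    nc_abort("`zmap` must be a 3D array", "input")
  }
  if (length(timecourse) < 2L) {
    nc_abort("`timecourse` must have at least 2 samples", "input")
  }
  if (!any(is.finite(zmap))) {
    nc_abort("`zmap` has no finite voxels", "validation")
  }
  if (any(voxel_dims <= 0) || length(voxel_dims) != 3L) {
    nc_abort("`voxel_dims` must be 3 positive lengths (mm)", "input")
  }
  if (tr <= 0) nc_abort("`tr` must be positive (seconds)", "input")
  structure(
    list(
      component_index = as.integer(component_index),
      zmap = zmap,
      timecourse = as.numeric(timecourse),
      voxel_dims = as.numeric(voxel_dims),
      tr = as.numeric(tr)
    ),
    class = "nc_component"
  )
}

#' Construct a decomposition from a list of component records
#'
#' @param components List of [component_record()] objects sharing one grid
#'   shape and one repetition time.
#' @return An object of class `nc_decomposition`.
#' @export
decomposition <- function(components) {
  if (length(components) < 1L) nc_abort("need at least one component", "input")
  shapes <- vapply(components, function(cc) paste(dim(cc$zmap), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    nc_abort("all components must share one grid shape", "consistency")
  }
  trs <- vapply(components, function(cc) cc$tr, 0)
  if (length(unique(trs)) != 1L) {
    nc_abort("all components must share one tr", "consistency")
  }
  structure(
    list(
      components = components,
      grid = dim(components[[1]]$zmap),
      tr = trs[[1]],
      n_components = length(components),
      n_timepoints = length(components[[1]]$timecourse)
    ),
    class = "nc_decomposition"
  )
}

#' @export
print.nc_component <- function(x, ...) {
  cat(sprintf(
    "<icnoise component %d (displayed as %d): grid %s, T=%d, tr=%gs>\n",
    x$component_index, x$component_index + 1L,
    paste(dim(x$zmap), collapse = "x"), length(x$timecourse), x$tr
  ))
  invisible(x)
}

#' @export
print.nc_decomposition <- function(x, ...) {
  cat(sprintf(
    "<icnoise decomposition: K=%d components, grid %s, T=%d, tr=%gs>\n",
    x$n_components, paste(x$grid, collapse = "x"), x$n_timepoints, x$tr
  ))
  invisible(x)
}
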