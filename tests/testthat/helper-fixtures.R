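# Shared fixtures, built once per test run. Small grids keep the suite fast;
# the geometry contracts don't depend on grid size.

tiny_spec <- phantom_spec(grid = c(16L, 16L, 16L), n_timepoints = 60L,
                          n_components = 8L, seed = 101L)
tiny_space <- make_phantom_space(tiny_spec)

# a thresholded-map object on an arbitrary voxel set (helper for unit tests)
make_thmap <- function(voxels, dm, zvalues = NULL, voxel_dims = c(1, 1, 1)) {
  voxels <- sort(as.integer(voxels))
  structure(
    list(voxels = voxels,
         zvalues = zvalues %||% rep(5, length(voxels)),
         dim = as.integer(dm),
         voxel_dims = voxel_dims,
         n_analysis = prod(dm)),
    class = "nc_thmap"
  )
}

# a hand-made spectrum object (for dynamic-metric edge cases)
make_spectrum <- function(freq, power, tr = 2) {
  out <- tibble::tibble(freq = freq, power = power / sum(power))
  attr(out, "tr") <- tr
  attr(out, "nyquist") <- 1 / (2 * tr)
  class(out) <- c("nc_spectrum", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_nc_error <- function(expr, class) {
  expect_error(expr, class = paste0("icnoise_", class, "_error"))
}
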