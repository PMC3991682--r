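# The ordered feature catalogue and extraction orchestration. The registry
# fixes the identity and order of every feature column; models are bound to a
# registry fingerprint so a trained classifier can refuse a mismatched
# feature matrix.

CORE_GROUPS <- c("aal_count", "mask_pct", "spatial_moments", "cluster",
                 "mirror", "tc_moments", "hff", "extrema", "bands",
                 "autocorr", "dynamic")

# Minimum time-course length the registry accepts: lag-5 autocorrelation
# needs T >= 11 and the spectrum needs T >= 8; 12 gives headroom for both.
MIN_TIMEPOINTS <- 12L

sanitize_id <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Build the ordered feature registry
#'
#' The core catalogue contains, in fixed order: one suprathreshold voxel
#' count per atlas region (116 for the AAL atlas); 10 tissue/region
#' activation percentages; 3 spatial distribution metrics; 4 cluster metrics;
#' mirror symmetry; 4 time-course moments; the high-frequency fraction; 6
#' extrema/jump statistics; 5 band powers; 5 autocorrelations; and 4 dynamic
#' spectrum metrics — 159 features with the full AAL atlas. The registry is
#' extensible via [register_feature()] and reports a fingerprint binding
#' models to an exact feature geometry.
#'
#' @param atlas An `nc_atlas`.
#' @param maskset An `nc_maskset` on the same grid.
#' @param fraction Top-|Z| threshold fraction used during extraction
#'   (default 0.05).
#' @return An `nc_registry`: tibble with columns `identifier`, `category`,
#'   `group`; attributes carry the atlas, masks, fraction and fingerprint.
#' @export
build_registry <- function(atlas, maskset, fraction = 0.05) {
  if (!identical(dim(atlas$labelmap), dim(maskset[[1]]))) {
    nc_abort("atlas and mask grids differ", "consistency")
  }
  rows <- list(
    tibble::tibble(
      identifier = paste0("aal_count_", sanitize_id(atlas$regions$name)),
      category = "spatial", group = "aal_count"
    ),
    tibble::tibble(
      identifier = paste0("pct_total_activation_", mask_roles()),
      category = "spatial", group = "mask_pct"
    ),
    tibble::tibble(
      identifier = c("spatial_kurtosis", "spatial_skewness", "spatial_entropy"),
      category = "spatial", group = "spatial_moments"
    ),
    tibble::tibble(
      identifier = c("avg_peak_distance", "cluster_size_min",
                     "cluster_size_max", "cluster_size_mean"),
      category = "spatial", group = "cluster"
    ),
    tibble::tibble(
      identifier = "pct_lr_symmetric", category = "spatial", group = "mirror"
    ),
    tibble::tibble(
      identifier = c("tc_kurtosis", "tc_skewness", "tc_entropy", "tc_mean"),
      category = "temporal", group = "tc_moments"
    ),
    tibble::tibble(
      identifier = "high_freq_fraction", category = "temporal", group = "hff"
    ),
    tibble::tibble(
      identifier = c("n_local_maxima", "n_local_minima", "avg_dist_maxima",
                     "avg_dist_minima", "avg_jump_max_min", "biggest_jump_max_min"),
      category = "temporal", group = "extrema"
    ),
    tibble::tibble(
      identifier = power_bands()$id, category = "temporal", group = "bands"
    ),
    tibble::tibble(
      identifier = paste0("autocorr_lag", 1:5),
      category = "temporal", group = "autocorr"
    ),
    tibble::tibble(
      identifier = c("dyn_range_low", "dyn_range_high",
                     "dyn_count_diff_low", "dyn_count_diff_high"),
      category = "temporal", group = "dynamic"
    )
  )
  reg <- dplyr::bind_rows(rows)
  if (anyDuplicated(reg$identifier)) {
    nc_abort("duplicate feature identifiers (atlas region names collide?)", "registration")
  }
  structure(
    reg,
    class = c("nc_registry", class(reg)),
    atlas = atlas,
    maskset = maskset,
    fraction = fraction,
    extensions = list(),
    fingerprint = fnv1a32(paste(reg$identifier, collapse = "\n"))
  )
}

#' Register an extension feature
#'
#' Appends a user-defined feature to the registry. The extractor receives the
#' component record and a context list (`zmap_norm`, `thmap`, `spectrum`,
#' `atlas`, `maskset`) and must return one finite numeric value.
#'
#' @param registry An `nc_registry`.
#' @param identifier Unique feature identifier.
#' @param category `"spatial"` or `"temporal"`.
#' @param fn Extractor `function(component, context)`.
#' @return The extended registry (new fingerprint).
#' @export
register_feature <- function(registry, identifier, category, fn) {
  if (identifier %in% registry$identifier) {
    nc_abort(sprintf("feature identifier already registered: %s", identifier),
             "registration")
  }
  stopifnot(category %in% c("spatial", "temporal"), is.function(fn))
  at <- attributes(registry)
  new_row <- tibble::tibble(identifier = identifier, category = category,
                            group = "extension")
  out <- dplyr::bind_rows(tibble::as_tibble(registry), new_row)
  ext <- at$extensions
  ext[[identifier]] <- fn
  structure(
    out,
    class = c("nc_registry", class(out)),
    atlas = at$atlas,
    maskset = at$maskset,
    fraction = at$fraction,
    extensions = ext,
    fingerprint = fnv1a32(paste(out$identifier, collapse = "\n"))
  )
}

#' Registry fingerprint
#'
#' @param registry An `nc_registry`.
#' @return 8-hex-digit string identifying the feature geometry.
#' @export
registry_fingerprint <- function(registry) attr(registry, "fingerprint")

#' @export
print.nc_registry <- function(x, ...) {
  cat(sprintf(
    "<icnoise feature registry: %d features (%d spatial, %d temporal), fingerprint %s>\n",
    nrow(x), sum(x$category == "spatial"), sum(x$category == "temporal"),
    registry_fingerprint(x)
  ))
  invisible(x)
}

#' Extract every registry feature for every component
#'
#' Runs the full spatial and temporal extraction per component: Z-map
#' normalization, top-fraction |Z| thresholding, atlas counts, mask
#' percentages, moments/entropy, cluster metrics, mirror symmetry, spectrum
#' and all time-course descriptors. Extraction is deterministic and pure; a
#' degenerate component (constant map or series) aborts with a consolidated
#' report naming every offender.
#'
#' @param decomposition An `nc_decomposition` on the registry's grid.
#' @param registry An `nc_registry`.
#' @return Tibble: `component_id` (1-based) plus one column per feature, in
#'   registry order; attribute `fingerprint` carries the registry
#'   fingerprint.
#' @export
extract_all <- function(decomposition, registry) {
  atlas <- attr(registry, "atlas")
  maskset <- attr(registry, "maskset")
  fraction <- attr(registry, "fraction")
  grid <- dim(atlas$labelmap)
  if (!identical(as.integer(decomposition$grid), grid)) {
    nc_abort("decomposition grid does not match registry grid", "consistency")
  }
  if (decomposition$n_timepoints < MIN_TIMEPOINTS) {
    nc_abort(sprintf(
      "time courses must have at least %d samples", MIN_TIMEPOINTS
    ), "input")
  }

  failures <- character(0)
  rows <- vector("list", decomposition$n_components)
  for (k in seq_len(decomposition$n_components)) {
    comp <- decomposition$components[[k]]
    vals <- tryCatch(
      extract_component(comp, registry, atlas, maskset, fraction),
      icnoise_error = function(e) {
        failures <<- c(failures, sprintf(
          "component %d: %s", comp$component_index + 1L, conditionMessage(e)
        ))
        NULL
      }
    )
    rows[[k]] <- vals
  }
  if (length(failures) > 0) {
    nc_abort(paste0(
      "feature extraction failed:\n  ", paste(failures, collapse = "\n  ")
    ), "degenerate")
  }
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- registry$identifier
  out <- dplyr::bind_cols(
    tibble::tibble(component_id = vapply(
      decomposition$components, function(cc) cc$component_index + 1L, 0L
    )),
    out
  )
  attr(out, "fingerprint") <- registry_fingerprint(registry)
  out
}

extract_component <- function(comp, registry, atlas, maskset, fraction) {
  zn <- znormalize_map(comp$zmap)
  th <- threshold_top_fraction(zn, fraction, voxel_dims = comp$voxel_dims)
  spec <- periodogram(comp$timecourse, comp$tr)
  cl <- peak_cluster_metrics(zn, th)
  sm <- map_moments(zn)
  tm <- tc_moments(comp$timecourse)
  ex <- extrema_metrics(comp$timecourse)
  dyn <- dynamic_spectrum_metrics(spec)

  core <- c(
    aal_region_counts(th, atlas),
    mask_percentages(th, maskset),
    sm[["kurtosis"]], sm[["skewness"]], sm[["entropy"]],
    cl$avg_peak_distance, cl$cluster_size_min, cl$cluster_size_max,
    cl$cluster_size_mean,
    mirror_symmetry(th),
    tm[["kurtosis"]], tm[["skewness"]], tm[["entropy"]], tm[["mean"]],
    high_freq_fraction(spec),
    ex,
    band_power(spec),
    autocorrelation(comp$timecourse),
    dyn
  )
  ext_fns <- attr(registry, "extensions")
  if (length(ext_fns) > 0) {
    context <- list(zmap_norm = zn, thmap = th, spectrum = spec,
                    atlas = atlas, maskset = maskset)
    ext_vals <- vapply(ext_fns, function(f) as.numeric(f(comp, context)), 0)
    core <- c(core, ext_vals)
  }
  vals <- unname(as.numeric(core))
  if (length(vals) != nrow(registry)) {
    nc_abort("extracted value count does not match registry size", "consistency")
  }
  if (any(!is.finite(vals))) {
    bad <- registry$identifier[!is.finite(vals)]
    nc_abort(sprintf("non-finite feature value(s): %s", paste(bad, collapse = ", ")),
             "degenerate")
  }
  vals
}

#' Normalize a training feature matrix
#'
#' Centers and scales every feature column to mean 0, SD 1 (sample SD),
#' learning the statistics from this matrix only. Zero-variance columns are
#' mapped to all-zeros and flagged (rather than dropped) so the column
#' geometry stays fixed for model files.
#'
#' @param matrix Feature tibble from [extract_all()] (may include `label`).
#' @return List with `matrix` (normalized tibble) and `stats`
#'   (`nc_normstats`: per-column mean, sd, and zero-variance flags).
#' @export
normalize_features <- function(matrix) {
  feat_cols <- setdiff(names(matrix), c("component_id", "label"))
  if (nrow(matrix) < 2L) nc_abort("need at least 2 rows to normalize", "input")
  mu <- vapply(feat_cols, function(cn) mean(matrix[[cn]]), 0)
  sg <- vapply(feat_cols, function(cn) stats::sd(matrix[[cn]]), 0)
  zero_var <- feat_cols[sg == 0]
  stats <- structure(
    list(mean = mu, sd = sg, zero_variance = zero_var,
         fingerprint = attr(matrix, "fingerprint")),
    class = "nc_normstats"
  )
  list(matrix = apply_normalization(matrix, stats), stats = stats)
}

#' Apply stored normalization statistics
#'
#' Transforms a feature matrix with training-time statistics only (never
#' re-estimating from the new data). Zero-variance training columns map to 0.
#'
#' @param matrix Feature tibble.
#' @param stats An `nc_normstats` from [normalize_features()].
#' @return Normalized tibble.
#' @export
apply_normalization <- function(matrix, stats) {
  feat_cols <- setdiff(names(matrix), c("component_id", "label"))
  if (!identical(feat_cols, names(stats$mean))) {
    nc_abort("feature columns do not match normalization statistics", "schema")
  }
  out <- matrix
  for (cn in feat_cols) {
    if (stats$sd[[cn]] == 0) {
      out[[cn]] <- rep(0, nrow(matrix))
    } else {
      out[[cn]] <- (matrix[[cn]] - stats$mean[[cn]]) / stats$sd[[cn]]
    }
  }
  out
}
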