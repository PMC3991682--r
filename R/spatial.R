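# Spatial descriptors of a component Z-map: normalization, top-fraction
# thresholding, atlas region counts, tissue mask percentages, distribution
# moments/entropy, local-maxima/region-growing cluster metrics, and
# left-right mirror symmetry.
#
# The analysis domain is always the set of finite voxels. Moments and entropy
# are computed on the full normalized map (pre-threshold); everything else on
# the suprathreshold voxel set.

#' Z-normalize a spatial map
#'
#' Subtracts the mean and divides by the standard deviation (sample, n-1
#' convention) over the finite voxels, so different decomposition orders
#' become comparable. Non-finite voxels are passed through untouched.
#'
#' @param zmap 3D numeric array.
#' @return The normalized array (mean 0, SD 1 over finite voxels).
#' @export
znormalize_map <- function(zmap) {
  fin <- is.finite(zmap)
  v <- zmap[fin]
  if (length(v) < 2L) nc_abort("need at least 2 finite voxels", "degenerate")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    nc_abort("constant map: zero variance over finite voxels", "degenerate")
  }
  zmap[fin] <- (v - mean(v)) / s
  zmap
}

#' Threshold a Z-map to its top fraction of voxels by |Z|
#'
#' Retains exactly `floor(fraction * N)` voxels with the largest absolute
#' Z-scores, where N counts the finite voxels. Ties at the cut are broken by
#' ascending linear voxel index, making the retained set deterministic.
#'
#' @param zmap 3D numeric array (typically the normalized map).
#' @param fraction Fraction of voxels to retain, in (0, 1); default 0.05.
#' @param voxel_dims Voxel edge lengths in mm (carried for distance metrics).
#' @return An `nc_thmap`: list with `voxels` (ascending linear indices),
#'   `zvalues` (their Z-scores), `dim`, `voxel_dims`, `n_analysis`.
#' @export
threshold_top_fraction <- function(zmap, fraction = 0.05, voxel_dims = c(1, 1, 1)) {
  if (!(fraction > 0 && fraction < 1)) {
    nc_abort("`fraction` must be in (0, 1)", "input")
  }
  fin_idx <- which(is.finite(zmap))
  n <- length(fin_idx)
  m <- floor(fraction * n)
  if (m < 1L) {
    nc_abort(sprintf("fraction %g of %d voxels retains no voxel", fraction, n), "input")
  }
  v <- zmap[fin_idx]
  if (max(v) == min(v)) nc_abort("constant map cannot be thresholded", "degenerate")
  ord <- order(-abs(v), fin_idx)
  keep <- fin_idx[ord[seq_len(m)]]
  keep_sorted <- sort(keep)
  structure(
    list(
      voxels = keep_sorted,
      zvalues = zmap[keep_sorted],
      dim = dim(zmap),
      voxel_dims = as.numeric(voxel_dims),
      n_analysis = n
    ),
    class = "nc_thmap"
  )
}

#' Per-region suprathreshold voxel counts
#'
#' Counts suprathreshold voxels falling in each atlas region, in the atlas
#' table's order (the order of the regional features in the registry).
#'
#' @param thmap An `nc_thmap`.
#' @param atlas An `nc_atlas` on the same grid.
#' @return Named integer vector, one count per region.
#' @export
aal_region_counts <- function(thmap, atlas) {
  if (!identical(as.integer(thmap$dim), dim(atlas$labelmap))) {
    nc_abort("atlas grid does not match map grid", "consistency")
  }
  labs <- atlas$labelmap[thmap$voxels]
  counts <- vapply(atlas$regions$code, function(code) sum(labs == code), 0L)
  names(counts) <- atlas$regions$name
  counts
}

#' Tissue/region activation percentages
#'
#' For each of the 10 mask roles, the percentage of suprathreshold voxels
#' falling inside that mask. The denominator is the suprathreshold voxel
#' count, so percentages are comparable across decomposition orders.
#'
#' @param thmap An `nc_thmap`.
#' @param maskset An `nc_maskset` on the same grid.
#' @return Named numeric vector of 10 percentages in [0, 100].
#' @export
mask_percentages <- function(thmap, maskset) {
  if (!identical(as.integer(thmap$dim), dim(maskset[[1]]))) {
    nc_abort("mask grid does not match map grid", "consistency")
  }
  nv <- length(thmap$voxels)
  vapply(maskset, function(m) 100 * sum(m[thmap$voxels]) / nv, 0)
}

#' Distribution moments and spatial entropy of a Z-map
#'
#' Kurtosis is the Pearson moment ratio m4/m2^2 (normal = 3) and skewness
#' m3/m2^1.5, both with population (biased) moment estimators. Entropy is the
#' Shannon entropy (natural log) of a 100-bin equal-width histogram over
#' [min, max]; empty bins are skipped.
#'
#' @param zmap 3D numeric array; computed over finite voxels.
#' @return Named numeric vector `(kurtosis, skewness, entropy)`.
#' @export
map_moments <- function(zmap) {
  v <- zmap[is.finite(zmap)]
  moments_entropy(v, what = "map")
}

moments_entropy <- function(v, what = "map", n_bins = 100L) {
  if (length(unique(v)) < 2L) {
    nc_abort(sprintf("constant %s: moments undefined", what), "degenerate")
  }
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  if (m2 == 0) nc_abort(sprintf("constant %s: zero variance", what), "degenerate")
  kurt <- m4 / m2^2
  skew <- m3 / m2^1.5
  brk <- seq(min(v), max(v), length.out = n_bins + 1L)
  cuts <- findInterval(v, brk, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(cuts, nbins = n_bins) / length(v)
  p <- p[p > 0]
  entropy <- -sum(p * log(p))
  c(kurtosis = kurt, skewness = skew, entropy = entropy)
}

#' Local-maxima peak and region-growing cluster metrics
#'
#' Peaks are strict local maxima of |Z| over the suprathreshold set
#' (26-neighborhood, neighbors outside the set ignored), ranked by |Z|
#' descending with ties broken by ascending voxel index; up to `n_peaks` are
#' kept. The average peak distance is the mean pairwise Euclidean distance in
#' mm among the peaks (0 if fewer than 2). Each peak seeds region growing
#' over 26-connected voxels of the full map with |Z| >= `grow_thresh`; the
#' per-peak cluster sizes are summarized as (min, max, mean) in voxels. A
#' peak whose own |Z| falls below the growing threshold contributes size 0.
#'
#' @param zmap 3D numeric array (normalized map).
#' @param thmap Matching `nc_thmap`.
#' @param n_peaks Maximum number of peaks (default 10).
#' @param grow_thresh Absolute-Z region-growing threshold (default 2.5).
#' @return An `nc_clusters`: list with `peak_voxels`, `peak_coords_mm`,
#'   `n_peaks`, `avg_peak_distance`, `cluster_sizes`,
#'   `cluster_size_min/max/mean`.
#' @export
peak_cluster_metrics <- function(zmap, thmap, n_peaks = 10L, grow_thresh = 2.5) {
  dm <- as.integer(thmap$dim)
  stopifnot(identical(dim(zmap), dm))
  az <- abs(zmap)
  az[!is.finite(az)] <- -Inf

  vox <- thmap$voxels
  in_set <- logical(prod(dm))
  in_set[vox] <- TRUE

  coords <- arrayInd(vox, dm)
  is_peak <- rep(TRUE, length(vox))
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    relevant <- in_set[nb_lin]
    idx_ok <- which(ok)[relevant]
    if (length(idx_ok) == 0) next
    beaten <- az[vox[idx_ok]] <= az[nb_lin[relevant]]
    is_peak[idx_ok[beaten]] <- FALSE
  }
  cand <- vox[is_peak]
  ord <- order(-az[cand], cand)
  peaks <- cand[ord][seq_len(min(n_peaks, length(cand)))]

  pk_coords <- arrayInd(peaks, dm)
  mm <- sweep(pk_coords - 1, 2L, thmap$voxel_dims, "*")
  apd <- if (length(peaks) < 2L) 0 else {
    d <- stats::dist(mm)
    mean(d)
  }

  grow_ok <- az >= grow_thresh & is.finite(az)
  sizes <- vapply(peaks, function(seed) flood_fill_size(seed, grow_ok, dm), 0L)

  structure(
    list(
      peak_voxels = peaks,
      peak_coords_mm = mm,
      n_peaks = length(peaks),
      avg_peak_distance = apd,
      cluster_sizes = sizes,
      cluster_size_min = if (length(sizes)) min(sizes) else 0,
      cluster_size_max = if (length(sizes)) max(sizes) else 0,
      cluster_size_mean = if (length(sizes)) mean(sizes) else 0
    ),
    class = "nc_clusters"
  )
}

neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Iterative 26-connected flood fill; returns the component size of `seed`
# within the eligible set (0 if the seed is ineligible).
flood_fill_size <- function(seed, eligible, dm) {
  if (!eligible[seed]) return(0L)
  offs <- neighbor_offsets_26()
  visited <- new.env(hash = TRUE, parent = emptyenv())
  stack <- seed
  assign(as.character(seed), TRUE, envir = visited)
  size <- 0L
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    size <- size + 1L
    ijk <- arrayInd(cur, dm)[1, ]
    nb <- sweep(offs, 2L, ijk, "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
    for (v in nb_lin) {
      key <- as.character(v)
      if (eligible[v] && !exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        stack <- c(stack, v)
      }
    }
  }
  size
}

#' Left-right mirror symmetry of the suprathreshold set
#'
#' Reflects each suprathreshold voxel about the mid-sagittal voxel plane
#' (first-axis midline, i -> n1 + 1 - i) and reports the percentage whose
#' mirror image is also suprathreshold. Assumes maps registered to a
#' bilaterally symmetric standard space.
#'
#' @param thmap An `nc_thmap`.
#' @return Percentage in [0, 100].
#' @export
mirror_symmetry <- function(thmap) {
  dm <- as.integer(thmap$dim)
  coords <- arrayInd(thmap$voxels, dm)
  refl <- coords
  refl[, 1] <- dm[1] + 1L - refl[, 1]
  refl_lin <- refl[, 1] + (refl[, 2] - 1L) * dm[1] + (refl[, 3] - 1L) * dm[1] * dm[2]
  in_set <- logical(prod(dm))
  in_set[thmap$voxels] <- TRUE
  100 * sum(in_set[refl_lin]) / length(thmap$voxels)
}
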