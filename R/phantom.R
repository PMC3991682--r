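# Synthetic phantom decompositions: a geometric toy brain (atlas + the 10
# role masks) and class-conditional component maps/time courses carrying the
# spatial and spectral signatures that distinguish noise from network
# components (signal outside gray matter, high-frequency time courses vs
# bilateral gray-matter networks with low-frequency dynamics). The phantom is
# geometric, not anatomically realistic: it targets the extractors'
# contracts, not neuroanatomy.

PHANTOM_CLASSES <- c("eyeball", "motion_edge", "ventricle", "generic", "network")
NOISE_CLASSES <- setdiff(PHANTOM_CLASSES, "network")

#' Specify a synthetic phantom dataset
#'
#' @param grid Grid shape (default 32x32x32 voxels); every extent must be
#'   >= 16 so all structures fit.
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @param n_timepoints Time points per component (default 150).
#' @param tr Repetition time in seconds (default 2).
#' @param n_components Number of components (default 40).
#' @param noise_fraction Fraction of components labelled noise (default 0.5);
#'   the noise count is `floor(noise_fraction * n_components)`, remainder
#'   network.
#' @param class_mix Relative weights over the noise subtypes
#'   `eyeball`, `motion_edge`, `ventricle`, `generic`.
#' @param effect_size Separability dial in [0, 1]-ish units: 1 = full
#'   class-conditional signal, 0 = pure noise (labels carry no information).
#' @param seed Integer seed (mandatory).
#' @return An `nc_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 32L), voxel_mm = 3,
                         n_timepoints = 150L, tr = 2,
                         n_components = 40L, noise_fraction = 0.5,
                         class_mix = c(eyeball = 1, motion_edge = 1,
                                       ventricle = 1, generic = 1),
                         effect_size = 1, seed) {
  if (missing(seed)) nc_abort("`seed` is mandatory in a phantom spec", "spec")
  if (length(grid) != 3L || any(grid < 16L)) {
    nc_abort("phantom grid must be 3D with every extent >= 16", "spec")
  }
  if (noise_fraction < 0 || noise_fraction > 1) {
    nc_abort("noise_fraction must be in [0, 1]", "spec")
  }
  if (n_timepoints < MIN_TIMEPOINTS) {
    nc_abort(sprintf("n_timepoints must be >= %d", MIN_TIMEPOINTS), "spec")
  }
  stopifnot(all(names(class_mix) %in% NOISE_CLASSES), all(class_mix >= 0))
  structure(
    list(
      grid = as.integer(grid), voxel_mm = voxel_mm,
      n_timepoints = as.integer(n_timepoints), tr = tr,
      n_components = as.integer(n_components),
      noise_fraction = noise_fraction,
      class_mix = class_mix, effect_size = effect_size,
      seed = as.integer(seed)
    ),
    class = "nc_phantom_spec"
  )
}

#' Build the deterministic phantom geometry
#'
#' Lays out, on the spec's grid, pairwise-disjoint masks for all 10 roles:
#' one-voxel outer edge and skull shells, a CSF shell inside them, two
#' anterior eyeball spheres, a central ventricle block, midbrain and
#' cerebellum blocks, a spinal-cord column, a gray-matter spherical shell and
#' a white-matter core. The gray shell is subdivided into 6 mirror-symmetric
#' bilateral atlas regions (3 slab pairs); atlas regions are a subset of the
#' gray mask. Purely geometric and seed-free: the same spec always yields the
#' same volumes.
#'
#' @param spec An `nc_phantom_spec`.
#' @return List with `atlas` (`nc_atlas`) and `maskset` (`nc_maskset`).
#' @export
make_phantom_space <- function(spec) {
  dm <- spec$grid
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  idx <- arrayInd(seq_len(prod(dm)), dm)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  taken <- logical(prod(dm))
  claim <- function(sel) {
    sel <- sel & !taken
    taken <<- taken | sel
    sel
  }
  shell <- function(k) {
    x == k | x == nx + 1L - k | y == k | y == ny + 1L - k |
      z == k | z == nz + 1L - k
  }
  as_vol <- function(v) array(v, dm)

  edges <- claim(shell(1L))
  skull <- claim(shell(2L))
  csf <- claim(shell(3L))

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  r_eye <- max(2, round(nx / 8))
  ex_l <- 4 + r_eye                      # left eyeball center x (mirrored for right)
  ey <- 4 + r_eye                        # anterior (small y), clear of the shells
  in_sphere <- function(cx0, cy0, cz0, r) {
    (x - cx0)^2 + (y - cy0)^2 + (z - cz0)^2 <= r^2
  }
  eyeballs <- claim(in_sphere(ex_l, ey, cz, r_eye) |
                    in_sphere(nx + 1 - ex_l, ey, cz, r_eye))

  block <- function(xs, ys, zs) {
    x >= xs[1] & x <= xs[2] & y >= ys[1] & y <= ys[2] & z >= zs[1] & z <= zs[2]
  }
  mirror_x <- function(xs) c(nx + 1 - xs[2], nx + 1 - xs[1])
  # symmetric central x band: [cx - w, cx + w] with the same reflection image
  xband <- function(w) c(ceiling(cx - w), floor(cx + w))

  ventricles <- claim(block(xband(1.5), c(floor(cy) - 1, floor(cy) + 2),
                            c(floor(cz), floor(cz) + 3)))
  midbrain <- claim(block(xband(1.5), c(floor(cy) - 1, floor(cy) + 2),
                          c(floor(cz) - 2, floor(cz) - 1)))
  spinal <- claim(block(xband(0.5), c(floor(cy) - 1, floor(cy) + 1),
                        c(4, floor(cz) - 3)))
  cerebellum <- claim(block(xband(3.5), c(ny - 6, ny - 4), c(4, 7)))

  r2 <- min(dm) / 2 - 3.5
  r1 <- 0.6 * r2
  rad <- sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2)
  gray <- claim(rad >= r1 & rad <= r2)
  white <- claim(rad < r1)

  masks <- list(
    gray = as_vol(gray), white = as_vol(white), csf = as_vol(csf),
    eyeballs = as_vol(eyeballs), edges = as_vol(edges),
    midbrain = as_vol(midbrain), skull = as_vol(skull),
    ventricles = as_vol(ventricles), cerebellum = as_vol(cerebellum),
    spinal_cord = as_vol(spinal)
  )
  empty <- names(masks)[!vapply(masks, any, TRUE)]
  if (length(empty) > 0) {
    nc_abort(sprintf(
      "grid too small to place: %s", paste(empty, collapse = ", ")
    ), "spec")
  }

  # atlas: 3 z-slab pairs x 2 hemispheres over the gray shell; for an odd
  # first-axis extent the self-mirroring midline plane stays unlabelled so
  # every region has an exact mirror partner
  gz <- z[gray]
  zbrk <- stats::quantile(gz, c(1 / 3, 2 / 3), type = 1)
  band <- ifelse(z <= zbrk[1], 1L, ifelse(z <= zbrk[2], 2L, 3L))
  left <- x < cx
  right <- x > cx
  lab <- integer(prod(dm))
  for (b in 1:3) {
    lab[gray & band == b & left] <- 2L * b - 1L
    lab[gray & band == b & right] <- 2L * b
  }
  regions <- tibble::tibble(
    code = 1:6,
    name = paste0("gm_slab", rep(1:3, each = 2), c("_l", "_r"))
  )
  atlas <- atlas_parcellation(array(lab, dm), regions)
  list(atlas = atlas, maskset = mask_set(masks))
}

#' Simulate one labelled phantom component
#'
#' The spatial map is unit Gaussian background noise plus class-conditional
#' suprathreshold mass (eyeball -> eyeball spheres; motion_edge -> edge/skull
#' rim; ventricle -> ventricle block; generic noise -> scattered
#' white-matter/CSF voxels; network -> 1-3 bilateral gray region pairs),
#' Z-normalized before return. The time course is white noise plus
#' `effect_size`-scaled sinusoids: 0.01-0.08 Hz for networks, above 0.12 Hz
#' for noise classes.
#'
#' @param class One of `"eyeball"`, `"motion_edge"`, `"ventricle"`,
#'   `"generic"`, `"network"`.
#' @param spec An `nc_phantom_spec`.
#' @param space Output of [make_phantom_space()] for the same spec.
#' @param seed Integer seed; the same (class, seed) always yields the same
#'   record.
#' @return List with `record` (`nc_component`), `label` (1 = noise) and
#'   `class`.
#' @export
simulate_component <- function(class, spec, space, seed) {
  if (!(class %in% PHANTOM_CLASSES)) {
    nc_abort(sprintf("unknown phantom class: %s", class), "input")
  }
  with_seed(seed, {
    dm <- spec$grid
    zmap <- array(stats::rnorm(prod(dm)), dm)
    ms <- space$maskset
    target <- switch(class,
      eyeball = which(ms$eyeballs),
      motion_edge = which(ms$edges | ms$skull),
      ventricle = which(ms$ventricles),
      generic = {
        pool <- which(ms$white | ms$csf)
        sort(sample(pool, size = max(1L, round(0.4 * length(pool)))))
      },
      network = {
        n_pairs <- sample(1:3, 1L)
        pairs <- sort(sample(1:3, n_pairs))
        codes <- c(2L * pairs - 1L, 2L * pairs)
        which(array(space$atlas$labelmap %in% codes, dm))
      }
    )
    amp <- spec$effect_size * (3.5 + abs(stats::rnorm(length(target), 0, 0.5)))
    zmap[target] <- zmap[target] + amp

    tt <- spec$n_timepoints
    tsec <- (seq_len(tt) - 1L) * spec$tr
    nyq <- 1 / (2 * spec$tr)
    freqs <- if (class == "network") {
      stats::runif(3, 0.01, 0.08)
    } else {
      stats::runif(3, 0.12, min(0.24, 0.95 * nyq))
    }
    phases <- stats::runif(3, 0, 2 * pi)
    tc <- stats::rnorm(tt) + spec$effect_size *
      colSums(sin(outer(2 * pi * freqs, tsec) + phases))

    list(
      record = component_record(
        component_index = 0L,
        zmap = znormalize_map(zmap),
        timecourse = tc,
        voxel_dims = rep(spec$voxel_mm, 3),
        tr = spec$tr
      ),
      label = as.integer(class %in% NOISE_CLASSES),
      class = class
    )
  })
}

phantom_class_sequence <- function(spec) {
  n <- spec$n_components
  n_noise <- floor(spec$noise_fraction * n)
  mix <- spec$class_mix[spec$class_mix > 0]
  noise_classes <- rep(names(mix), length.out = n_noise)
  c(noise_classes, rep("network", n - n_noise))
}

#' Simulate a full labelled phantom decomposition on disk
#'
#' Writes a MELODIC-layout directory (`melodic_IC.nii.gz` 4D map,
#' `melodic_mix` T x K text matrix), the mask NIfTIs with their JSON
#' manifest, the atlas labelmap and label table, and a two-column label TSV —
#' everything [read_melodic_dir()], [read_mask_set()], [read_atlas()] and
#' [read_labels()] consume. Exactly `floor(noise_fraction * n)` components
#' are noise.
#'
#' @param spec An `nc_phantom_spec` with `n_components >= 2`.
#' @param dir Output directory (created if needed).
#' @return List: `dir`, per-artifact `paths`, `labels` tibble (with the true
#'   class), and the `spec`.
#' @export
simulate_dataset <- function(spec, dir) {
  if (spec$n_components < 2L) nc_abort("need n_components >= 2", "spec")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  space <- make_phantom_space(spec)
  classes <- phantom_class_sequence(spec)
  n <- spec$n_components
  comp_seeds <- with_seed(spec$seed, sample.int(2147483646L, n))

  sims <- lapply(seq_len(n), function(k) {
    simulate_component(classes[[k]], spec, space, seed = comp_seeds[[k]])
  })
  arr <- array(0, c(spec$grid, n))
  mix <- matrix(0, nrow = spec$n_timepoints, ncol = n)
  for (k in seq_len(n)) {
    arr[, , , k] <- sims[[k]]$record$zmap
    mix[, k] <- sims[[k]]$record$timecourse
  }

  ic_path <- file.path(dir, "melodic_IC.nii.gz")
  write_nifti_mm(arr, ic_path, spec$voxel_mm)
  mix_path <- file.path(dir, "melodic_mix")
  write_mixing_matrix(mix, mix_path)

  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  mask_paths <- vapply(mask_roles(), function(role) {
    p <- file.path(mask_dir, paste0(role, ".nii.gz"))
    write_nifti_mm(array(as.integer(space$maskset[[role]]), spec$grid), p,
                   spec$voxel_mm)
    p
  }, "")
  manifest_path <- file.path(dir, "masks.json")
  write_mask_manifest(mask_paths, manifest_path)

  atlas_path <- file.path(dir, "atlas.nii.gz")
  write_nifti_mm(space$atlas$labelmap, atlas_path, spec$voxel_mm)
  table_path <- file.path(dir, "atlas_labels.txt")
  writeLines(sprintf("%d %s", space$atlas$regions$code, space$atlas$regions$name),
             table_path)

  labels <- tibble::tibble(
    component_id = seq_len(n),
    label = vapply(sims, function(s) s$label, 0L),
    class = classes
  )
  labels_path <- file.path(dir, "labels.tsv")
  write_labels(labels, labels_path)

  list(
    dir = dir,
    paths = list(
      melodic_ic = ic_path, melodic_mix = mix_path,
      mask_manifest = manifest_path, atlas = atlas_path,
      atlas_table = table_path, labels = labels_path
    ),
    labels = labels,
    spec = spec
  )
}

write_nifti_mm <- function(arr, path, voxel_mm) {
  img <- RNifti::asNifti(arr)
  img$pixdim <- c(-1, rep(voxel_mm, 3), if (length(dim(arr)) == 4L) 1 else NULL,
                  rep(0, 8 - 1 - 3 - (length(dim(arr)) == 4L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Simulate a labelled feature matrix with a known signal support
#'
#' Draws an n x p standard-normal feature matrix with balanced 0/1 labels and
#' shifts exactly the named signal columns by `effect_size` standard
#' deviations in the positive class — the ground-truth fixture for
#' feature-recovery experiments (the classifier should select exactly those
#' columns). With `effect_size = 0` the labels carry no information.
#'
#' @param n Number of rows (components).
#' @param p Number of features (ignored when `feature_names` given).
#' @param signal_features Identifiers (or indices) of the signal-bearing
#'   columns; default the first 3.
#' @param effect_size Mean shift in SD units (default 2).
#' @param seed Integer seed.
#' @param feature_names Optional column names (e.g. a registry's
#'   identifiers).
#' @return Feature tibble (`component_id`, features, `label`) with a
#'   fingerprint attribute; attribute `signal_features` records the truth.
#' @export
simulate_feature_matrix <- function(n, p = 20L, signal_features = NULL,
                                    effect_size = 2, seed,
                                    feature_names = NULL) {
  if (missing(seed)) nc_abort("`seed` is mandatory", "spec")
  if (is.null(feature_names)) feature_names <- sprintf("f%02d", seq_len(p))
  p <- length(feature_names)
  if (is.null(signal_features)) signal_features <- feature_names[seq_len(min(3L, p))]
  if (is.numeric(signal_features)) signal_features <- feature_names[signal_features]
  stopifnot(all(signal_features %in% feature_names))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, feature_names))
    y <- rep_len(c(0L, 1L), n)[sample.int(n)]
    X[y == 1L, signal_features] <- X[y == 1L, signal_features] + effect_size
    out <- tibble::as_tibble(as.data.frame(X))
    out <- dplyr::bind_cols(tibble::tibble(component_id = seq_len(n)), out)
    out$label <- y
    attr(out, "fingerprint") <- fnv1a32(paste(feature_names, collapse = "\n"))
    attr(out, "signal_features") <- signal_features
    out
  })
}
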