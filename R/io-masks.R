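# Tissue/region role masks and atlas parcellations. Ten fixed mask roles
# define the tissue-specific activation-percentage features; an integer
# labelmap plus a "code name" table defines the regional voxel-count features.

#' The ten tissue/region mask roles
#'
#' Fixed role names, in the order their activation-percentage features appear
#' in the feature registry.
#' @return Character vector of length 10.
#' @export
mask_roles <- function() {
  c("gray", "white", "csf", "eyeballs", "edges",
    "midbrain", "skull", "ventricles", "cerebellum", "spinal_cord")
}

#' Read a mask set from a JSON manifest
#'
#' The manifest is a JSON object mapping each of the 10 role names (see
#' [mask_roles()]) to a NIfTI path. Masks are binarized at `> 0`, so
#' externally thresholded probabilistic tissue maps are acceptable.
#'
#' @param manifest_path Path to the JSON manifest.
#' @param reference_grid Optional integer length-3 grid shape to validate
#'   against.
#' @return An `nc_maskset`: a named list of logical 3D arrays.
#' @export
read_mask_set <- function(manifest_path, reference_grid = NULL) {
  if (!file.exists(manifest_path)) {
    nc_abort(sprintf("no such manifest: %s", manifest_path), "input")
  }
  man <- jsonlite::fromJSON(manifest_path)
  missing <- setdiff(mask_roles(), names(man))
  if (length(missing) > 0) {
    nc_abort(sprintf(
      "mask manifest missing roles: %s", paste(missing, collapse = ", ")
    ), "config")
  }
  base <- dirname(manifest_path)
  masks <- lapply(mask_roles(), function(role) {
    p <- as.character(man[[role]])
    if (!file.exists(p)) p <- file.path(base, as.character(man[[role]]))
    if (!file.exists(p)) {
      nc_abort(sprintf("mask file for role '%s' not found: %s", role, man[[role]]), "input")
    }
    arr <- as.array(RNifti::readNifti(p)) > 0
    if (length(dim(arr)) != 3L) {
      nc_abort(sprintf("mask '%s' must be a 3D volume", role), "input")
    }
    arr
  })
  names(masks) <- mask_roles()
  mask_set(masks, reference_grid = reference_grid)
}

#' Construct a mask set from in-memory arrays
#'
#' @param masks Named list of 3D arrays (coerced to logical at `> 0`), one per
#'   role in [mask_roles()].
#' @param reference_grid Optional grid shape to validate against.
#' @return An `nc_maskset`.
#' @export
mask_set <- function(masks, reference_grid = NULL) {
  missing <- setdiff(mask_roles(), names(masks))
  if (length(missing) > 0) {
    nc_abort(sprintf("missing mask roles: %s", paste(missing, collapse = ", ")), "config")
  }
  masks <- lapply(masks[mask_roles()], function(m) {
    storage.mode(m) <- "logical"
    m
  })
  shapes <- vapply(masks, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    nc_abort("all masks must share one grid shape", "consistency")
  }
  if (!is.null(reference_grid) &&
      !identical(dim(masks[[1]]), as.integer(reference_grid))) {
    nc_abort(sprintf(
      "mask grid %s does not match reference grid %s",
      shapes[[1]], paste(reference_grid, collapse = "x")
    ), "consistency")
  }
  empty <- names(masks)[vapply(masks, function(m) !any(m), TRUE)]
  if (length(empty) > 0) {
    nc_abort(sprintf("empty mask(s): %s", paste(empty, collapse = ", ")), "validation")
  }
  structure(masks, class = "nc_maskset")
}

#' Read an atlas parcellation
#'
#' @param labelmap_path NIfTI integer volume; 0 is background.
#' @param table_path Text file, one "code name" pair per line. The table order
#'   fixes the order of regional count features.
#' @param reference_grid Optional grid shape to validate against.
#' @return An `nc_atlas`: list with `labelmap` (integer 3D array) and
#'   `regions` (tibble of `code`, `name`).
#' @export
read_atlas <- function(labelmap_path, table_path, reference_grid = NULL) {
  for (p in c(labelmap_path, table_path)) {
    if (!file.exists(p)) nc_abort(sprintf("no such file: %s", p), "input")
  }
  lab <- as.array(RNifti::readNifti(labelmap_path))
  lines <- readLines(table_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  codes <- integer(length(lines))
  rnames <- character(length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(toks) < 2L) {
      nc_abort(sprintf("bad atlas table line: '%s'", lines[[i]]), "parse")
    }
    code <- suppressWarnings(as.integer(toks[[1]]))
    if (is.na(code)) {
      nc_abort(sprintf("non-integer atlas code: '%s'", toks[[1]]), "parse")
    }
    codes[[i]] <- code
    rnames[[i]] <- paste(toks[-1], collapse = "_")
  }
  if (anyDuplicated(codes)) nc_abort("duplicate atlas codes in table", "parse")
  atlas_parcellation(lab, tibble::tibble(code = codes, name = rnames),
                     reference_grid = reference_grid)
}

#' Construct an atlas parcellation from in-memory objects
#'
#' @param labelmap 3D integer array (0 = background).
#' @param regions Data frame with columns `code` (unique integers) and `name`.
#' @param reference_grid Optional grid shape to validate against.
#' @return An `nc_atlas`.
#' @export
atlas_parcellation <- function(labelmap, regions, reference_grid = NULL) {
  if (length(dim(labelmap)) != 3L) nc_abort("labelmap must be 3D", "input")
  storage.mode(labelmap) <- "integer"
  regions <- tibble::as_tibble(regions)
  if (anyDuplicated(regions$code)) nc_abort("duplicate atlas codes", "parse")
  present <- setdiff(unique(as.vector(labelmap)), 0L)
  unknown <- setdiff(present, regions$code)
  if (length(unknown) > 0) {
    nc_abort(sprintf(
      "labelmap contains codes absent from the table: %s",
      paste(sort(unknown), collapse = ", ")
    ), "consistency")
  }
  if (!is.null(reference_grid) &&
      !identical(dim(labelmap), as.integer(reference_grid))) {
    nc_abort("atlas grid does not match reference grid", "consistency")
  }
  structure(list(labelmap = labelmap, regions = regions), class = "nc_atlas")
}

write_mask_manifest <- function(paths, manifest_path) {
  jsonlite::write_json(as.list(paths), manifest_path, auto_unbox = TRUE)
  invisible(manifest_path)
}
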