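# Reading MELODIC-style decomposition directories: a 4D NIfTI of component
# Z-maps plus a whitespace-delimited T x K mixing matrix whose column k is
# component k's time course.

#' Read a MELODIC-style decomposition directory
#'
#' Expects a directory containing a 4D component-map NIfTI (`melodic_IC.nii.gz`
#' or `.nii`) and a plain-text mixing matrix (`melodic_mix`, T rows by K
#' whitespace-delimited columns). Component k's map is volume k and its time
#' course is mixing-matrix column k. Components are indexed 0-based internally;
#' user-facing output is 1-based (MELODIC display convention). The repetition
#' time is supplied by the caller: mixing matrices carry no timing metadata.
#'
#' @param path Directory containing the decomposition.
#' @param tr Repetition time in seconds.
#' @param ic_file,mix_file Optional file names overriding the defaults.
#' @return An `nc_decomposition`.
#' @export
read_melodic_dir <- function(path, tr, ic_file = NULL, mix_file = NULL) {
  if (!dir.exists(path)) nc_abort(sprintf("no such directory: %s", path), "input")
  ic_path <- find_one(path, ic_file %||% c("melodic_IC.nii.gz", "melodic_IC.nii"))
  mix_path <- find_one(path, mix_file %||% "melodic_mix")

  img <- RNifti::readNifti(ic_path)
  dm <- dim(img)
  if (length(dm) != 4L) {
    nc_abort(sprintf("component map must be 4D, got %dD", length(dm)), "input")
  }
  vdim <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vdim)) || any(vdim <= 0)) vdim <- c(1, 1, 1)

  mix <- read_mixing_matrix(mix_path)
  if (ncol(mix) != dm[4]) {
    nc_abort(sprintf(
      "volume count (%d) does not match mixing-matrix column count (%d)",
      dm[4], ncol(mix)
    ), "consistency")
  }

  arr <- as.array(img)
  comps <- lapply(seq_len(dm[4]), function(k) {
    component_record(
      component_index = k - 1L,
      zmap = arr[, , , k, drop = TRUE],
      timecourse = mix[, k],
      voxel_dims = vdim,
      tr = tr
    )
  })
  decomposition(comps)
}

find_one <- function(path, candidates) {
  for (f in candidates) {
    p <- file.path(path, f)
    if (file.exists(p)) return(p)
  }
  nc_abort(sprintf(
    "missing file in %s: expected one of %s",
    path, paste(candidates, collapse = ", ")
  ), "input")
}

# Mixing-matrix dialect: any run of spaces/tabs separates fields, blank lines
# ignored, scientific notation accepted.
read_mixing_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) nc_abort(sprintf("empty mixing matrix: %s", path), "parse")
  rows <- lapply(lines, function(ln) {
    toks <- strsplit(trimws(ln), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      nc_abort(sprintf("non-numeric field in mixing matrix: %s", path), "parse")
    }
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    nc_abort(sprintf("non-rectangular mixing matrix: %s", path), "parse")
  }
  do.call(rbind, rows)
}

write_mixing_matrix <- function(mat, path) {
  lines <- apply(mat, 1L, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
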