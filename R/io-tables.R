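# Tabular artifacts: two-column label files and TSV feature matrices.
# Feature matrices round-trip losslessly (%.17g serialization); every written
# table carries tool version, registry fingerprint and seed in '#'-prefixed
# header lines so outputs are self-describing and byte-reproducible.

#' Read a component label file
#'
#' Two tab-separated columns: component index (1-based, MELODIC display
#' convention) and label in {0, 1}; 1 marks the positive class of the model
#' being built (e.g. noise). Lines starting with `#` are ignored.
#'
#' @param path Path to the label TSV.
#' @param decomposition Optional `nc_decomposition` (or integer K) to validate
#'   indices against.
#' @return Tibble with columns `component_id` (1-based integer) and `label`.
#' @export
read_labels <- function(path, decomposition = NULL) {
  if (!file.exists(path)) nc_abort(sprintf("no such file: %s", path), "input")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  ids <- integer(length(lines))
  labs <- integer(length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(toks) != 2L) {
      nc_abort(sprintf("label line must have 2 fields: '%s'", lines[[i]]), "parse")
    }
    id <- suppressWarnings(as.integer(toks[[1]]))
    lb <- suppressWarnings(as.integer(toks[[2]]))
    if (is.na(id)) nc_abort(sprintf("bad component index: '%s'", toks[[1]]), "parse")
    if (is.na(lb) || !(lb %in% c(0L, 1L))) {
      nc_abort(sprintf("label must be 0 or 1, got '%s'", toks[[2]]), "parse")
    }
    ids[[i]] <- id
    labs[[i]] <- lb
  }
  if (anyDuplicated(ids)) nc_abort("duplicate component indices in label file", "consistency")
  if (!is.null(decomposition)) {
    k <- if (inherits(decomposition, "nc_decomposition")) {
      decomposition$n_components
    } else {
      as.integer(decomposition)
    }
    bad <- ids[ids < 1L | ids > k]
    if (length(bad) > 0) {
      nc_abort(sprintf(
        "label indices outside decomposition (K=%d): %s",
        k, paste(bad, collapse = ", ")
      ), "consistency")
    }
  }
  tibble::tibble(component_id = ids, label = labs)
}

write_labels <- function(labels, path) {
  writeLines(sprintf("%d\t%d", labels$component_id, labels$label), path)
  invisible(path)
}

#' Write a feature matrix to TSV
#'
#' First column `component_id`, then one column per registry feature (and an
#' optional trailing `label` column). Values are serialized with 17
#' significant digits so that [read_feature_matrix()] reproduces them exactly.
#' Header comment lines record the tool version, registry fingerprint and
#' seed.
#'
#' @param matrix Tibble as produced by [extract_all()].
#' @param path Output path.
#' @param fingerprint Registry fingerprint to embed (defaults to the tibble's
#'   `fingerprint` attribute, if any).
#' @param seed Seed to embed (optional).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path, fingerprint = NULL, seed = NULL) {
  fingerprint <- fingerprint %||% attr(matrix, "fingerprint") %||% "none"
  seed <- seed %||% attr(matrix, "seed") %||% "none"
  stopifnot(names(matrix)[1] == "component_id")
  feat_cols <- setdiff(names(matrix), c("component_id", "label"))
  has_label <- "label" %in% names(matrix)
  hdr <- c(
    sprintf("# tool\ticnoise %s", tool_version()),
    sprintf("# registry_fingerprint\t%s", fingerprint),
    sprintf("# seed\t%s", seed),
    paste(c("component_id", feat_cols, if (has_label) "label"), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    vals <- vapply(feat_cols, function(cn) fmt_num(matrix[[cn]][[i]]), "")
    paste(c(
      as.character(matrix$component_id[[i]]), vals,
      if (has_label) as.character(matrix$label[[i]])
    ), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input path.
#' @param registry Optional `nc_registry`; when given, the file's feature
#'   columns must match the registry's identifiers in order (schema error
#'   otherwise).
#' @return Tibble with `component_id`, features, optional `label`; attributes
#'   `fingerprint` and `seed` carry the embedded metadata.
#' @export
read_feature_matrix <- function(path, registry = NULL) {
  if (!file.exists(path)) nc_abort(sprintf("no such file: %s", path), "input")
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) nc_abort("feature matrix has no header row", "parse")
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  if (header[[1]] != "component_id") {
    nc_abort("first feature-matrix column must be component_id", "schema")
  }
  has_label <- header[[length(header)]] == "label"
  feat_cols <- header[-c(1L, if (has_label) length(header))]
  if (!is.null(registry)) {
    if (!identical(feat_cols, registry$identifier)) {
      nc_abort("feature-matrix header does not match the registry's identifiers", "schema")
    }
  }
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header))) {
    nc_abort("ragged feature-matrix row", "parse")
  }
  mat <- do.call(rbind, rows)
  out <- tibble::tibble(component_id = as.integer(mat[, 1L]))
  for (j in seq_along(feat_cols)) {
    out[[feat_cols[[j]]]] <- as.numeric(mat[, j + 1L])
  }
  if (has_label) out$label <- as.integer(mat[, length(header)])
  attr(out, "fingerprint") <- meta_value(meta, "registry_fingerprint")
  attr(out, "seed") <- meta_value(meta, "seed")
  out
}

meta_value <- function(meta, key) {
  ln <- grep(sprintf("^# %s\t", key), meta, value = TRUE)
  if (length(ln) == 0) return(NULL)
  strsplit(ln[[1]], "\t", fixed = TRUE)[[1]][[2]]
}
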