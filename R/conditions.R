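# Classed conditions: every user-facing failure carries one of a fixed set of
# error classes so the CLI can report a machine-parseable class on exit.

NC_ERROR_CLASSES <- c(
  "input", "parse", "consistency", "config", "validation",
  "schema", "degenerate", "spec", "registration"
)

nc_abort <- function(message, class) {
  stopifnot(class %in% NC_ERROR_CLASSES)
  rlang::abort(message, class = c(paste0("icnoise_", class, "_error"), "icnoise_error"))
}

#' Extract the short error class of an icnoise condition
#'
#' Returns e.g. `"input"`, `"consistency"`, `"schema"` for conditions raised by
#' this package, or `"error"` for anything else.
#'
#' @param cnd A condition object.
#' @return A single string.
#' @export
nc_error_class <- function(cnd) {
  cls <- grep("^icnoise_.*_error$", class(cnd), value = TRUE)
  if (length(cls) == 0) return("error")
  sub("_error$", "", sub("^icnoise_", "", cls[[1]]))
}
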