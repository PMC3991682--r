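# broom-style tidiers so fitted objects drop straight into dplyr/ggplot2
# pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an elastic-net fit
#'
#' @param x An `nc_enet`.
#' @param ... Unused.
#' @return Tibble of `term`, `estimate`, `selected` (the intercept appears as
#'   term `"(Intercept)"`).
#' @exportS3Method generics::tidy
tidy.nc_enet <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", estimate = x$intercept, selected = NA),
    tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                   selected = unname(x$beta) != 0)
  )
}

#' @exportS3Method generics::glance
glance.nc_enet <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, lambda = x$lambda, family = x$family,
    n_selected = length(x$selected), n_features = length(x$beta),
    converged = x$converged %||% NA, sweeps = x$sweeps %||% NA_integer_
  )
}

#' Tidy a trained classifier: one row per selected feature
#'
#' @param x An `nc_classifier`.
#' @param ... Unused.
#' @return Tibble of `term`, `enet_weight` (on normalized features),
#'   `logistic_coef`.
#' @exportS3Method generics::tidy
tidy.nc_classifier <- function(x, ...) {
  tibble::tibble(
    term = x$selected,
    enet_weight = unname(x$enet$beta[x$selected]),
    logistic_coef = unname(x$logistic$coef[x$selected])
  )
}

#' @exportS3Method generics::glance
glance.nc_classifier <- function(x, ...) {
  tibble::tibble(
    alpha = x$enet$alpha, lambda = x$enet$lambda,
    cva = x$cv$best_cva, cva_fold_mean = x$cv$best_cva_fold_mean,
    folds = x$cv$folds, n_selected = length(x$selected),
    threshold = x$threshold, family = x$family, seed = x$seed,
    fingerprint = x$fingerprint
  )
}

#' @exportS3Method generics::tidy
tidy.nc_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.nc_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = nrow(x$points))
}

#' Tidy an evaluation report: one row per metric with its 95% CI
#'
#' @param x An `nc_eval`.
#' @param ... Unused.
#' @return Tibble of `metric`, `estimate`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.nc_eval <- function(x, ...) {
  row <- function(metric, v) {
    tibble::tibble(metric = metric, estimate = v[["point"]],
                   conf.low = v[["lo"]], conf.high = v[["hi"]])
  }
  dplyr::bind_rows(
    row("sensitivity", x$sensitivity),
    row("specificity", x$specificity),
    row("accuracy", x$accuracy),
    tibble::tibble(metric = "auc", estimate = x$auc,
                   conf.low = NA_real_, conf.high = NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.nc_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n, threshold = x$threshold,
    tp = x$counts[["TP"]], fp = x$counts[["FP"]],
    tn = x$counts[["TN"]], fn = x$counts[["FN"]],
    sensitivity = x$sensitivity[["point"]],
    specificity = x$specificity[["point"]],
    accuracy = x$accuracy[["point"]],
    auc = x$auc
  )
}

#' @exportS3Method generics::tidy
tidy.nc_cv_grid <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.nc_cv_grid <- function(x, ...) {
  tibble::tibble(
    best_alpha = x$best_alpha, best_lambda = x$best_lambda,
    best_cva = x$best_cva, best_cva_fold_mean = x$best_cva_fold_mean,
    folds = x$folds, seed = x$seed, n = x$n
  )
}
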