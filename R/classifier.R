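# The two-stage classifier: elastic-net feature selection (via CV grid
# search), a maximum-likelihood logistic refit on the selected features, and
# an operating threshold chosen on the ROC curve. A trained model is bound to
# a registry fingerprint and carries its normalization statistics, so
# prediction on a mismatched feature geometry fails loudly.

#' Maximum-likelihood logistic refit on selected features
#'
#' Iteratively reweighted least squares with a small ridge jitter (1e-8) on
#' the normal equations for numerical stability; iteration cap 100. On
#' separable data the coefficients are bounded by the iteration cap and
#' predicted probabilities are clipped to [1e-12, 1 - 1e-12].
#'
#' @param X Numeric matrix of selected (normalized) features.
#' @param y 0/1 labels.
#' @param ridge Jitter added to the normal-equation diagonal.
#' @param max_iter IRLS iteration cap.
#' @return An `nc_logistic`: `intercept`, `coef` (named), `iterations`,
#'   `converged`.
#' @export
refit_logistic <- function(X, y, ridge = 1e-8, max_iter = 100L) {
  xy <- as_xy(X, y)
  X <- xy$X; y <- xy$y
  if (ncol(X) < 1L) {
    nc_abort(paste(
      "no selected features: the logistic stage needs at least one nonzero",
      "elastic-net coefficient (fall back to the elastic-net linear score)"
    ), "degenerate")
  }
  if (length(unique(y)) < 2L) nc_abort("both classes must be present", "input")
  Xd <- cbind(`(Intercept)` = 1, X)
  m <- ncol(Xd)
  coef <- numeric(m)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- as.vector(Xd %*% coef)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd * w, Xd) + diag(ridge, m)
    b <- crossprod(Xd * w, z)
    new_coef <- as.vector(solve(A, b))
    delta <- max(abs(new_coef - coef))
    coef <- new_coef
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  structure(
    list(
      intercept = coef[[1]],
      coef = stats::setNames(coef[-1], colnames(X)),
      iterations = it,
      converged = converged
    ),
    class = "nc_logistic"
  )
}

logistic_prob <- function(logistic, X) {
  eta <- logistic$intercept + as.vector(X[, names(logistic$coef), drop = FALSE] %*%
                                          logistic$coef)
  pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
}

#' Train the full noise classifier
#'
#' Runs the complete modelling stage on a labelled feature matrix:
#' normalization (statistics learned here only), cross-validated grid search
#' over (alpha, lambda), an elastic-net fit at the winning pair, a logistic
#' refit on the selected features, and ROC-based operating-threshold
#' selection on the training probabilities.
#'
#' @param features Feature tibble from [extract_all()] including a `label`
#'   column (or supply `labels`).
#' @param labels Optional tibble (`component_id`, `label`) joined by
#'   component id.
#' @param alpha_grid,n_lambda,folds,family Passed to [cv_grid_search()].
#' @param seed Integer seed (required; controls fold assignment).
#' @param threshold `"auto-roc"` (maximize accuracy; default), a fixed
#'   numeric in [0, 1], or `"max-specificity"` (maximize specificity, ties
#'   toward higher sensitivity — the conservative reviewer-workflow policy).
#' @return An `nc_classifier` model object.
#' @export
train_classifier <- function(features, labels = NULL,
                             alpha_grid = seq(0, 1, by = 0.1),
                             n_lambda = 50L, folds = 10L, seed,
                             threshold = "auto-roc",
                             family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (missing(seed)) nc_abort("`seed` is required", "input")
  fingerprint <- attr(features, "fingerprint") %||% "none"
  if (!is.null(labels)) {
    features <- features[setdiff(names(features), "label")]
    features <- dplyr::inner_join(features, labels, by = "component_id")
  }
  if (!("label" %in% names(features))) {
    nc_abort("no labels: supply a `label` column or `labels` table", "input")
  }
  y <- features$label
  if (length(unique(y)) < 2L) nc_abort("both classes must be present", "input")

  norm <- normalize_features(features)
  Xn <- norm$matrix

  cv <- cv_grid_search(Xn, y, alpha_grid = alpha_grid, n_lambda = n_lambda,
                       folds = folds, seed = seed, family = family)
  enet <- fit_elastic_net(Xn, y, alpha = cv$best_alpha, lambda = cv$best_lambda,
                          family = family)
  if (length(enet$selected) == 0) {
    nc_abort(paste(
      "elastic net selected no features at the CV optimum;",
      "no signal to refit (fall back to the elastic-net linear score)"
    ), "degenerate")
  }
  Xsel <- as.matrix(Xn[enet$selected])
  logistic <- refit_logistic(Xsel, y)
  probs <- logistic_prob(logistic, Xsel)
  roc <- roc_analysis(probs, y)
  tau <- resolve_threshold(threshold, roc)

  structure(
    list(
      fingerprint = fingerprint,
      normalization = norm$stats,
      enet = enet,
      logistic = logistic,
      selected = enet$selected,
      threshold = tau,
      threshold_policy = if (is.numeric(threshold)) "fixed" else threshold,
      cv = cv,
      training_roc = roc,
      seed = as.integer(seed),
      family = family,
      version = tool_version()
    ),
    class = "nc_classifier"
  )
}

resolve_threshold <- function(threshold, roc) {
  if (is.numeric(threshold)) {
    if (threshold < 0 || threshold > 1) {
      nc_abort("fixed threshold must be in [0, 1]", "input")
    }
    return(threshold)
  }
  if (identical(threshold, "auto-roc")) return(choose_threshold(roc))
  if (identical(threshold, "max-specificity")) {
    pts <- roc$points
    best <- pts[order(-pts$specificity, -pts$sensitivity, pts$threshold), ][1, ]
    return(best$threshold)
  }
  nc_abort(sprintf("unknown threshold policy: %s", threshold), "config")
}

#' Predict noise probabilities for new components
#'
#' Applies the stored normalization statistics, subsets the selected
#' features, and evaluates the logistic stage `p = 1/(1 + exp(-(b0 +
#' x_selected . b)))`. The feature matrix must match the model's registry
#' fingerprint (when both carry one) and column geometry.
#'
#' @param model An `nc_classifier`.
#' @param features Raw (un-normalized) feature tibble from [extract_all()] or
#'   [read_feature_matrix()].
#' @return Tibble: `component_id`, `probability`, `predicted` (1 = positive
#'   class at the model's operating threshold).
#' @export
predict_probability <- function(model, features) {
  fp <- attr(features, "fingerprint")
  if (!is.null(fp) && !identical(fp, "none") &&
      !identical(model$fingerprint, "none") &&
      !identical(fp, model$fingerprint)) {
    nc_abort(sprintf(
      "registry fingerprint mismatch: features %s vs model %s",
      fp, model$fingerprint
    ), "schema")
  }
  Xn <- apply_normalization(features, model$normalization)
  missing_cols <- setdiff(model$selected, names(Xn))
  if (length(missing_cols) > 0) {
    nc_abort(sprintf(
      "feature matrix lacks selected features: %s",
      paste(missing_cols, collapse = ", ")
    ), "schema")
  }
  probs <- logistic_prob(model$logistic, as.matrix(Xn[model$selected]))
  tibble::tibble(
    component_id = features$component_id %||% seq_along(probs),
    probability = probs,
    predicted = as.integer(probs >= model$threshold)
  )
}

#' @export
predict.nc_classifier <- function(object, newdata, ...) {
  predict_probability(object, newdata)
}

#' @export
print.nc_classifier <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<icnoise classifier v%s>\n",
      "  fingerprint: %s   seed: %d   loss: %s\n",
      "  alpha=%g lambda=%.6g  CVA=%.4f (%d-fold)\n",
      "  %d selected features; threshold tau=%.4f (%s)\n"
    ),
    x$version, x$fingerprint, x$seed, x$family,
    x$enet$alpha, x$enet$lambda, x$cv$best_cva, x$cv$folds,
    length(x$selected), x$threshold, x$threshold_policy
  ))
  invisible(x)
}

# --- model persistence ------------------------------------------------------
# Doubles are serialized as %.17g strings so that save -> load -> predict is
# bit-for-bit identical (plain JSON numbers need not round-trip exactly).

num_out <- function(x) {
  if (is.null(names(x))) fmt_num(x) else as.list(stats::setNames(fmt_num(x), names(x)))
}

num_in <- function(x) {
  if (is.list(x)) {
    stats::setNames(as.numeric(unlist(x, use.names = FALSE)), names(x))
  } else {
    as.numeric(x)
  }
}

#' Save a trained classifier to JSON
#'
#' @param model An `nc_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  payload <- list(
    tool = "icnoise",
    version = model$version,
    fingerprint = model$fingerprint,
    seed = model$seed,
    family = model$family,
    normalization = list(
      mean = num_out(model$normalization$mean),
      sd = num_out(model$normalization$sd),
      zero_variance = as.list(model$normalization$zero_variance)
    ),
    alpha = num_out(model$enet$alpha),
    lambda = num_out(model$enet$lambda),
    beta = num_out(model$enet$beta),
    enet_intercept = num_out(model$enet$intercept),
    selected = as.list(model$selected),
    logistic = list(
      intercept = num_out(model$logistic$intercept),
      coef = num_out(model$logistic$coef)
    ),
    threshold = num_out(model$threshold),
    threshold_policy = model$threshold_policy,
    cv = list(
      best_cva = num_out(model$cv$best_cva),
      best_cva_fold_mean = num_out(model$cv$best_cva_fold_mean),
      folds = model$cv$folds
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path Model JSON path.
#' @return An `nc_classifier` (sufficient for prediction and evaluation).
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) nc_abort(sprintf("no such model file: %s", path), "input")
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$tool, "icnoise")) nc_abort("not an icnoise model file", "schema")
  beta <- num_in(as.list(p$beta))
  structure(
    list(
      fingerprint = p$fingerprint,
      normalization = structure(
        list(
          mean = num_in(as.list(p$normalization$mean)),
          sd = num_in(as.list(p$normalization$sd)),
          zero_variance = unlist(p$normalization$zero_variance) %||% character(0)
        ),
        class = "nc_normstats"
      ),
      enet = structure(
        list(
          beta = beta,
          intercept = num_in(p$enet_intercept),
          alpha = num_in(p$alpha),
          lambda = num_in(p$lambda),
          family = p$family,
          selected = unlist(p$selected)
        ),
        class = "nc_enet"
      ),
      logistic = structure(
        list(
          intercept = num_in(p$logistic$intercept),
          coef = num_in(as.list(p$logistic$coef))
        ),
        class = "nc_logistic"
      ),
      selected = unlist(p$selected),
      threshold = num_in(p$threshold),
      threshold_policy = p$threshold_policy,
      cv = list(
        best_cva = num_in(p$cv$best_cva),
        best_cva_fold_mean = num_in(p$cv$best_cva_fold_mean),
        folds = p$cv$folds
      ),
      seed = p$seed,
      family = p$family,
      version = p$version
    ),
    class = "nc_classifier"
  )
}
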