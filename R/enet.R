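# Elastic-net feature selection: squared-error (default) or logistic loss
# with the penalty lambda * [alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2],
# solved by cyclic coordinate descent with soft-thresholding (covariance
# updates). The intercept is unpenalized.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

as_xy <- function(X, y = NULL) {
  if (is.data.frame(X)) {
    if (is.null(y) && "label" %in% names(X)) y <- X$label
    feat_cols <- setdiff(names(X), c("component_id", "label"))
    X <- as.matrix(X[feat_cols])
  }
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (any(!is.finite(X))) nc_abort("non-finite values in feature matrix", "input")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) nc_abort("length(y) != nrow(X)", "input")
    if (!all(y %in% c(0, 1))) nc_abort("labels must be 0/1", "input")
  }
  list(X = X, y = y)
}

# Cyclic coordinate descent on the centered covariance form.
# XtX = Xc'Xc / n, Xty = Xc'yc / n (already scaled). Converged when the
# largest coefficient update in a sweep is < tol. The hot loop lives in the
# compiled kernel (src/enet_cd.cpp); enet_cd_ref is the identical pure-R
# reference used to validate it.
enet_cd <- function(XtX, Xty, alpha, lambda, beta, tol = 1e-6, max_sweeps = 1e5) {
  out <- enet_cd_cpp(XtX, as.numeric(Xty), alpha, lambda, as.numeric(beta),
                     tol, as.integer(max_sweeps))
  list(beta = as.numeric(out$beta), sweeps = out$sweeps,
       converged = out$converged)
}

enet_cd_ref <- function(XtX, Xty, alpha, lambda, beta, tol = 1e-6, max_sweeps = 1e5) {
  p <- length(Xty)
  dg <- diag(XtX)
  denom <- dg + lambda * (1 - alpha)
  thr <- lambda * alpha
  sweeps <- 0L
  converged <- FALSE
  repeat {
    sweeps <- sweeps + 1L
    maxdel <- 0
    for (j in seq_len(p)) {
      bj <- beta[[j]]
      rho <- Xty[[j]] - sum(XtX[j, ] * beta) + dg[[j]] * bj
      bnew <- if (denom[[j]] > 0) soft_threshold(rho, thr) / denom[[j]] else 0
      if (bnew != bj) {
        beta[[j]] <- bnew
        maxdel <- max(maxdel, abs(bnew - bj))
      }
    }
    if (maxdel < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  list(beta = beta, sweeps = sweeps, converged = converged)
}

enet_objective <- function(X, y, beta, intercept, alpha, lambda) {
  n <- length(y)
  r <- y - intercept - as.vector(X %*% beta)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Largest penalty strength with a non-null solution
#'
#' `lambda_max = max_j |X_j' (y - mean(y))| / (n * max(alpha, 0.001))`; at or
#' above this value every penalized coefficient is zero.
#'
#' @param X Numeric matrix (or feature tibble).
#' @param y 0/1 labels.
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @return A positive scalar.
#' @export
lambda_max <- function(X, y, alpha) {
  xy <- as_xy(X, y)
  n <- nrow(xy$X)
  max(abs(crossprod(xy$X, xy$y - mean(xy$y)))) / (n * max(alpha, 0.001))
}

lambda_path <- function(lmax, n_lambda, lambda_min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit an elastic-net model at fixed (alpha, lambda)
#'
#' Minimizes `(1/2n) sum_i (y_i - b0 - x_i b)^2 + lambda * [alpha ||b||_1 +
#' (1-alpha)/2 ||b||_2^2]` by cyclic coordinate descent with
#' soft-thresholding; the intercept is unpenalized. With
#' `family = "binomial"` the squared loss is replaced by the penalized
#' logistic negative log-likelihood, solved by outer IRLS around the same
#' coordinate-descent core.
#'
#' @param X Normalized feature matrix (numeric matrix or feature tibble).
#' @param y 0/1 labels (taken from the `label` column when `X` is a tibble).
#' @param alpha Mixing parameter in [0, 1] (1 = LASSO, 0 = ridge).
#' @param lambda Penalty strength > 0.
#' @param family `"gaussian"` (default two-stage flow) or `"binomial"`.
#' @param tol Convergence tolerance on the largest coefficient update.
#' @param max_sweeps Sweep cap.
#' @return An `nc_enet`: coefficients `beta` (named), `intercept`, `alpha`,
#'   `lambda`, `selected` identifiers, convergence info.
#' @export
fit_elastic_net <- function(X, y = NULL, alpha, lambda,
                            family = c("gaussian", "binomial"),
                            tol = 1e-6, max_sweeps = 1e5) {
  family <- match.arg(family)
  xy <- as_xy(X, y)
  X <- xy$X; y <- xy$y
  if (is.null(y)) nc_abort("labels required", "input")
  if (alpha < 0 || alpha > 1) nc_abort("alpha must be in [0, 1]", "input")
  if (lambda <= 0) nc_abort("lambda must be > 0", "input")
  n <- nrow(X)
  if (n < 2L) nc_abort("need at least 2 samples", "input")

  if (family == "gaussian") {
    pre <- enet_precompute(X, y)
    fit <- enet_cd(pre$XtX, pre$Xty, alpha, lambda,
                   beta = numeric(ncol(X)), tol = tol, max_sweeps = max_sweeps)
    beta <- fit$beta
    intercept <- pre$ym - sum(pre$xm * beta)
    obj <- enet_objective(X, y, beta, intercept, alpha, lambda)
    obj0 <- enet_objective(X, y, numeric(ncol(X)), mean(y), alpha, lambda)
    conv <- fit$converged
    sweeps <- fit$sweeps
  } else {
    fit <- enet_irls_binomial(X, y, alpha, lambda, tol = tol,
                              max_sweeps = max_sweeps)
    beta <- fit$beta
    intercept <- fit$intercept
    obj <- fit$objective
    obj0 <- fit$objective0
    conv <- fit$converged
    sweeps <- fit$sweeps
  }
  names(beta) <- colnames(X)
  structure(
    list(
      beta = beta,
      intercept = intercept,
      alpha = alpha,
      lambda = lambda,
      family = family,
      selected = names(beta)[beta != 0],
      converged = conv,
      sweeps = sweeps,
      objective = obj,
      null_objective = obj0
    ),
    class = "nc_enet"
  )
}

enet_precompute <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  list(
    XtX = crossprod(Xc) / n,
    Xty = as.vector(crossprod(Xc, y - ym)) / n,
    xm = xm, ym = ym, n = n
  )
}

# Penalized logistic loss: outer IRLS re-quadratization, inner weighted
# coordinate descent. Weights are clamped below at 1e-5 (glmnet-style) so the
# quadratic surrogate stays well-posed on separable data.
enet_irls_binomial <- function(X, y, alpha, lambda, tol = 1e-6,
                               max_sweeps = 1e5, max_outer = 25L) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  intercept <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  sweeps_total <- 0L
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    eta <- intercept + as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    sw <- sum(w)
    xmw <- as.vector(crossprod(X, w)) / sw
    zmw <- sum(w * z) / sw
    Xc <- sweep(X, 2L, xmw)
    XtX <- crossprod(Xc * w, Xc) / n
    Xty <- as.vector(crossprod(Xc * w, z - zmw)) / n
    fit <- enet_cd(XtX, Xty, alpha, lambda, beta, tol = tol,
                   max_sweeps = max_sweeps)
    sweeps_total <- sweeps_total + fit$sweeps
    delta <- max(abs(fit$beta - beta))
    beta <- fit$beta
    intercept <- zmw - sum(xmw * beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  obj_at <- function(b, b0) {
    eta <- b0 + as.vector(X %*% b)
    -mean(y * eta - log1p(exp(eta))) +
      lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  }
  list(beta = beta, intercept = intercept, converged = converged,
       sweeps = sweeps_total,
       objective = obj_at(beta, intercept),
       objective0 = obj_at(numeric(p), stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))))
}

#' @export
print.nc_enet <- function(x, ...) {
  cat(sprintf(
    "<icnoise elastic net (%s): alpha=%g, lambda=%.6g, %d/%d nonzero, %s>\n",
    x$family, x$alpha, x$lambda, length(x$selected), length(x$beta),
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Cross-validated grid search over (alpha, lambda)
#'
#' Stratified, seeded 10-fold (by default) cross-validation maximizing the
#' out-of-fold classification accuracy (CVA). For each alpha the lambda path
#' is log-spaced over `[1e-3 * lambda_max, lambda_max]` computed on the full
#' data, and fits are warm-started from the previous lambda. Out-of-fold
#' predictions use the fixed rule score >= 0.5. CVA ties are broken toward
#' larger lambda, then larger alpha (prefer the sparser model). Pooled
#' out-of-fold accuracy is the selection criterion; the per-fold mean is also
#' reported.
#'
#' @param X Normalized feature matrix (matrix or feature tibble).
#' @param y 0/1 labels (or taken from the tibble's `label` column).
#' @param alpha_grid Mixing-parameter grid (default `seq(0, 1, 0.1)`).
#' @param n_lambda Number of lambda path points per alpha (default 50).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment (required).
#' @param family Loss passed to [fit_elastic_net()].
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @return An `nc_cv_grid`: list with `best_alpha`, `best_lambda`,
#'   `best_cva`, `grid` (tibble of alpha, lambda, cva, cva_fold_mean,
#'   nonzero), `folds`, `seed`.
#' @export
cv_grid_search <- function(X, y = NULL, alpha_grid = seq(0, 1, by = 0.1),
                           n_lambda = 50L, folds = 10L, seed,
                           family = c("gaussian", "binomial"),
                           lambda_min_ratio = 1e-3) {
  family <- match.arg(family)
  if (missing(seed)) nc_abort("`seed` is required for fold assignment", "input")
  xy <- as_xy(X, y)
  X <- xy$X; y <- xy$y
  if (is.null(y)) nc_abort("labels required", "input")
  n <- nrow(X)
  if (length(unique(y)) < 2L) nc_abort("both classes must be present", "input")
  if (n < folds) nc_abort("fewer samples than folds", "input")

  fold_id <- stratified_folds(y, folds, seed)
  fold_data <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    c(enet_precompute(Xtr, ytr),
      list(Xtr = Xtr, ytr = ytr,
           Xte = X[!tr, , drop = FALSE], yte = y[!tr], test_idx = which(!tr)))
  })

  grid_rows <- list()
  for (a in alpha_grid) {
    lmax <- lambda_max(X, y, a)
    lpath <- lambda_path(lmax, n_lambda, lambda_min_ratio)
    # correct[l, ] accumulates out-of-fold hits per lambda
    hits <- matrix(0, nrow = n_lambda, ncol = folds)
    nz <- numeric(n_lambda)
    for (f in seq_len(folds)) {
      fd <- fold_data[[f]]
      beta <- numeric(ncol(X))
      for (l in seq_along(lpath)) {
        if (family == "gaussian") {
          fit <- enet_cd(fd$XtX, fd$Xty, a, lpath[[l]], beta)
          beta <- fit$beta
          b0 <- fd$ym - sum(fd$xm * beta)
          score <- b0 + as.vector(fd$Xte %*% beta)
        } else {
          bf <- enet_irls_binomial(fd$Xtr, fd$ytr, a, lpath[[l]])
          beta <- bf$beta
          score <- stats::plogis(bf$intercept + as.vector(fd$Xte %*% beta))
        }
        pred <- as.integer(score >= 0.5)
        hits[l, f] <- sum(pred == fd$yte)
        nz[[l]] <- nz[[l]] + sum(beta != 0)
      }
    }
    fold_sizes <- vapply(fold_data, function(fd) length(fd$yte), 0L)
    grid_rows[[length(grid_rows) + 1L]] <- tibble::tibble(
      alpha = a,
      lambda = lpath,
      path_index = seq_along(lpath),
      cva = rowSums(hits) / n,
      cva_fold_mean = rowMeans(sweep(hits, 2L, fold_sizes, "/")),
      nonzero = nz / folds
    )
  }
  grid <- dplyr::bind_rows(grid_rows)
  # CVA ties break toward the sparser model: fewest mean out-of-fold nonzero
  # coefficients, then larger alpha, then larger lambda (by path position —
  # raw lambda values are incommensurable across alphas because lambda_max
  # scales with 1/alpha).
  best <- grid[order(-grid$cva, grid$nonzero, -grid$alpha, grid$path_index), ][1, ]
  structure(
    list(
      best_alpha = best$alpha,
      best_lambda = best$lambda,
      best_cva = best$cva,
      best_cva_fold_mean = best$cva_fold_mean,
      grid = grid,
      folds = folds,
      seed = as.integer(seed),
      family = family,
      fold_id = fold_id,
      n = n
    ),
    class = "nc_cv_grid"
  )
}

# Seeded stratified fold assignment: within each class, shuffle and deal
# round-robin so every fold sees both classes whenever feasible.
stratified_folds <- function(y, folds, seed) {
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' @export
print.nc_cv_grid <- function(x, ...) {
  cat(sprintf(
    "<icnoise CV grid: %d folds, %d points; best alpha=%g, lambda=%.6g, CVA=%.4f>\n",
    x$folds, nrow(x$grid), x$best_alpha, x$best_lambda, x$best_cva
  ))
  invisible(x)
}
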