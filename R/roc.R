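# ROC threshold analysis, AUC, operating-threshold selection, and
# binomially-bounded performance reporting. Classification rule throughout:
# score >= threshold -> positive (label 1).

#' ROC curve over all score thresholds
#'
#' Sweeps the thresholds `{0} U sorted unique scores U {1}`; at each, a
#' component is called positive when its score is >= the threshold.
#' Sensitivity is therefore nonincreasing in the threshold, and the curve
#' includes the all-positive (threshold 0) and near-all-negative
#' (threshold 1) operating points. AUC is the trapezoidal area over
#' (1 - specificity, sensitivity).
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels 0/1 labels (both classes required).
#' @return An `nc_roc`: list with `points` (tibble of threshold, sensitivity,
#'   specificity, accuracy) and `auc`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) nc_abort("scores/labels length mismatch", "input")
  if (length(unique(labels)) < 2L) nc_abort("both classes must be present", "input")
  if (any(scores < 0 | scores > 1)) nc_abort("scores must be in [0, 1]", "input")
  thresholds <- sort(unique(c(0, scores, 1)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  pts <- purrr::map_dfr(thresholds, function(th) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred == 1L & labels == 1L)
    tn <- sum(pred == 0L & labels == 0L)
    tibble::tibble(
      threshold = th,
      sensitivity = tp / n_pos,
      specificity = tn / n_neg,
      accuracy = (tp + tn) / length(labels)
    )
  })
  fpr <- 1 - pts$specificity
  ord <- order(fpr, pts$sensitivity)
  x <- fpr[ord]; yy <- pts$sensitivity[ord]
  auc <- sum(diff(x) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "nc_roc")
}

#' Operating threshold maximizing accuracy
#'
#' Picks the ROC threshold with the highest accuracy; ties are broken toward
#' higher specificity (and then toward the larger threshold, for
#' determinism).
#'
#' @param roc An `nc_roc`.
#' @return Threshold in [0, 1].
#' @export
choose_threshold <- function(roc) {
  pts <- roc$points
  best <- pts[order(-pts$accuracy, -pts$specificity, -pts$threshold), ][1, ]
  best$threshold
}

#' Binomial proportion with 95% confidence interval
#'
#' `p_hat = k/n`, `SE = sqrt(p_hat (1 - p_hat) / n)`, interval
#' `p_hat +/- 1.96 SE` clipped to [0, 1] — the normal-approximation interval
#' for k correctly identified out of n.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @return Named vector `(point, lo, hi)`.
#' @export
binomial_ci <- function(k, n) {
  if (n < 1) nc_abort("n must be >= 1", "input")
  if (k < 0 || k > n) nc_abort("k must be in [0, n]", "input")
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  c(point = p, lo = max(0, p - 1.96 * se), hi = min(1, p + 1.96 * se))
}

#' Evaluate a classifier on labelled test data
#'
#' Computes the confusion matrix at the operating threshold, sensitivity
#' (TP/(TP+FN)), specificity (TN/(TN+FP)) and accuracy ((TP+TN)/n), each
#' with a binomial 95% CI over its own denominator, plus the AUC of the
#' score-based ROC curve.
#'
#' @param model An `nc_classifier`.
#' @param features Raw feature tibble for the test components.
#' @param labels Tibble (`component_id`, `label`) or vector of 0/1 labels.
#' @param threshold Operating threshold (default: the model's stored tau).
#' @return An `nc_eval` report.
#' @export
evaluate_classifier <- function(model, features, labels, threshold = NULL) {
  preds <- predict_probability(model, features)
  if (is.data.frame(labels)) {
    merged <- dplyr::inner_join(preds, labels, by = "component_id")
    y <- merged$label
    scores <- merged$probability
  } else {
    y <- as.integer(labels)
    scores <- preds$probability
  }
  evaluate_scores(scores, y, threshold %||% model$threshold)
}

#' Evaluate prediction scores against labels
#'
#' @param scores Probabilities in [0, 1].
#' @param labels 0/1 labels (both classes required).
#' @param threshold Operating threshold in [0, 1].
#' @return An `nc_eval`: counts TP/FP/TN/FN, sensitivity/specificity/accuracy
#'   each with 95% binomial CI, and AUC.
#' @export
evaluate_scores <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) nc_abort("both classes must be present", "input")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  structure(
    list(
      threshold = threshold,
      counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
      sensitivity = binomial_ci(tp, tp + fn),
      specificity = binomial_ci(tn, tn + fp),
      accuracy = binomial_ci(tp + tn, length(labels)),
      auc = roc_analysis(scores, labels)$auc,
      n = length(labels)
    ),
    class = "nc_eval"
  )
}

#' @export
print.nc_eval <- function(x, ...) {
  fmt_ci <- function(v) sprintf("%.4f [%.4f, %.4f]", v[["point"]], v[["lo"]], v[["hi"]])
  cat(sprintf(
    paste0(
      "<icnoise evaluation: n=%d, threshold=%.4f>\n",
      "  TP=%d FP=%d TN=%d FN=%d\n",
      "  sensitivity %s\n  specificity %s\n  accuracy    %s\n  AUC         %.4f\n"
    ),
    x$n, x$threshold,
    x$counts[["TP"]], x$counts[["FP"]], x$counts[["TN"]], x$counts[["FN"]],
    fmt_ci(x$sensitivity), fmt_ci(x$specificity), fmt_ci(x$accuracy), x$auc
  ))
  invisible(x)
}

write_roc_tsv <- function(roc, path, seed = NULL, fingerprint = NULL) {
  hdr <- c(
    sprintf("# tool\ticnoise %s", tool_version()),
    sprintf("# registry_fingerprint\t%s", fingerprint %||% "none"),
    sprintf("# seed\t%s", seed %||% "none"),
    sprintf("# auc\t%s", fmt_num(roc$auc)),
    "threshold\tsensitivity\tspecificity"
  )
  body <- sprintf(
    "%s\t%s\t%s",
    fmt_num(roc$points$threshold),
    fmt_num(roc$points$sensitivity),
    fmt_num(roc$points$specificity)
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

eval_to_json <- function(ev, path, seed = NULL, fingerprint = NULL) {
  payload <- list(
    tool = "icnoise",
    version = tool_version(),
    registry_fingerprint = fingerprint %||% "none",
    seed = seed %||% "none",
    n = ev$n,
    threshold = num_out(ev$threshold),
    counts = as.list(ev$counts),
    sensitivity = as.list(num_out(ev$sensitivity)),
    specificity = as.list(num_out(ev$specificity)),
    accuracy = as.list(num_out(ev$accuracy)),
    auc = num_out(ev$auc)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
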