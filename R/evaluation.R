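#' Stratified k-fold cross-validation with pooled predictions
#'
#' Partitions the pairs into k disjoint folds (stratified by label, sizes
#' differing by at most one); each fold is predicted by a model trained on
#' the remaining folds, so every pair receives exactly one out-of-fold
#' probability.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param k Number of folds (default 5); `k = n` gives leave-one-out.
#' @param seed Master seed controlling fold assignment and per-fold models.
#' @param stratified Stratify folds by label (default `TRUE`).
#' @param fit Fitting function, `fit(x, y, seed = s, ...)` (default
#'   [dti_rf()]; [dti_nb()] ignores the seed).
#' @param ... Passed to `fit` (e.g. `ntree`, `mtry`).
#' @return Object of class `cv_result`: data frame columns `prob`, `fold`,
#'   `y` (row order = input order).
#' @export
kfold_cv <- function(x, y, k = 5L, seed = 1L, stratified = TRUE,
                     fit = dti_rf, ...) {
  d <- .check_xy(x, y)
  n <- nrow(d$x)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  fold <- integer(n)
  .with_seed(derive_seed(seed, "folds"), {
    if (stratified) {
      offset <- 0L
      for (cl in c(1L, 0L)) {
        idx <- sample(which(d$y == cl))
        m <- length(idx)
        fold[idx] <- ((seq_len(m) - 1L + offset) %% k) + 1L
        offset <- (offset + m) %% k
      }
    } else {
      fold <- sample(rep_len(1:k, n))
    }
  })
  prob <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- fit(d$x[!test, , drop = FALSE], d$y[!test],
                 seed = derive_seed(seed, paste0("fold", f)), ...)
    prob[test] <- stats::predict(model, d$x[test, , drop = FALSE])
  }
  structure(data.frame(prob = prob, fold = fold, y = d$y),
            class = c("cv_result", "data.frame"))
}

#' ROC and precision-recall curves with areas
#'
#' Computes the ROC curve (trapezoidal auROC; ties counted one half) and
#' the precision-recall curve with area as average precision (step-wise
#' integral of precision over recall increments).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive).
#' @return Object of class `curve_summary`: list with `roc` (data frame
#'   fpr, tpr, threshold), `pr` (recall, precision, threshold), `auroc`,
#'   `auprc`.
#' @export
curves_and_areas <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single operating points
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1L - l)[!duplicated(grp, fromLast = TRUE)]
  thr <- s[!duplicated(grp)]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(
    roc = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
    pr = data.frame(recall = recall, precision = precision, threshold = thr),
    auroc = auroc, auprc = auprc), class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("<curve_summary> auROC = %.4f, auPRC = %.4f (%d ROC points)\n",
              x$auroc, x$auprc, nrow(x$roc)))
  invisible(x)
}

#' Plot ROC and precision-recall curves
#'
#' @param x A `curve_summary`.
#' @param which `"roc"`, `"pr"` or `"both"` (default, side by side).
#' @param ... Passed to `plot()`.
#' @method plot curve_summary
#' @export
plot.curve_summary <- function(x, which = c("both", "roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if (which != "pr") {
    plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
         ylab = "True positive rate",
         main = sprintf("ROC (auROC = %.3f)", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which != "roc")
    plot(x$pr$recall, x$pr$precision, type = "l", xlab = "Recall",
         ylab = "Precision", ylim = c(0, 1),
         main = sprintf("P-R (auPRC = %.3f)", x$auprc), ...)
  invisible(x)
}

#' Confusion summary at a probability threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row data frame: TP, FN, TN, FP counts and Sen, Spe, Acc
#'   percentages.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  data.frame(TP = tp, FN = fn, TN = tn, FP = fp,
             Sen = tp * 100 / (tp + fn),
             Spe = tn * 100 / (tn + fp),
             Acc = (tp + tn) * 100 / length(labels))
}

#' Cross-validated performance across Ki labelling thresholds
#'
#' Relabels the interaction table at each Ki threshold, runs k-fold CV, and
#' reports auROC/auPRC per threshold.  Thresholds that leave a single class
#' are skipped with a warning.
#'
#' @param interactions Ki record data frame.
#' @param fingerprints,protein_feats Feature matrices as in
#'   [build_pair_dataset()].
#' @param thresholds_uM Ki thresholds in micromolar (default 10 to 90 by 5).
#' @param k,seed,... Passed to [kfold_cv()].
#' @return Data frame: threshold_uM, n_pos, n_neg, auroc, auprc.
#' @export
threshold_sweep <- function(interactions, fingerprints, protein_feats,
                            thresholds_uM = seq(10, 90, by = 5),
                            k = 5L, seed = 1L, ...) {
  if (any(thresholds_uM <= 0))
    stop("thresholds must be positive", call. = FALSE)
  rows <- lapply(thresholds_uM, function(th) {
    ds <- build_pair_dataset(interactions, fingerprints, protein_feats,
                             threshold_nM = th * 1000)
    if (length(unique(ds$y)) < 2L) {
      warning("threshold ", th, " uM yields a single class; skipped",
              call. = FALSE)
      return(NULL)
    }
    cv <- kfold_cv(ds$x, ds$y, k = k, seed = seed, ...)
    cs <- curves_and_areas(cv$prob, cv$y)
    data.frame(threshold_uM = th, n_pos = sum(ds$y == 1L),
               n_neg = sum(ds$y == 0L), auroc = cs$auroc, auprc = cs$auprc)
  })
  do.call(rbind, rows)
}

#' Correlation between binding affinity and predicted probability
#'
#' Pearson correlation of log10(Ki) against the predicted interaction
#' probability.  Tight binders (low Ki) receiving high probabilities give a
#' negative r; the magnitude is the relevant statistic.
#'
#' @param ki_nM Positive Ki values (nM).
#' @param prob Predicted probabilities.
#' @return Signed Pearson correlation coefficient.
#' @export
ki_probability_correlation <- function(ki_nM, prob) {
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0))
    stop("Ki values must be positive", call. = FALSE)
  if (length(ki_nM) != length(prob))
    stop("length mismatch", call. = FALSE)
  lk <- log10(ki_nM)
  if (stats::sd(lk) == 0 || stats::sd(prob) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  stats::cor(lk, prob)
}

#' Remove one protein property block from a pair feature matrix
#'
#' Drops the 21 CTD columns of the named property (or the 20 AAC columns)
#' from the protein block of a pair feature matrix, for per-property
#' omission studies.
#'
#' @param x Pair feature matrix whose final 167 columns are the protein
#'   descriptor block.
#' @param property_id One of [property_names()] or `"AAC"`.
#' @return `x` without the property's columns; attribute `removed`
#'   holds the dropped column names.
#' @export
ablate_property <- function(x, property_id) {
  x <- as.matrix(x)
  im <- protein_index_map()
  if (!property_id %in% names(im))
    stop("unknown property '", property_id, "'; expected one of: ",
         paste(names(im), collapse = ", "), call. = FALSE)
  if (ncol(x) < 167L)
    stop("matrix has fewer than 167 columns", call. = FALSE)
  offset <- ncol(x) - 167L
  drop_idx <- offset + im[[property_id]]
  out <- x[, -drop_idx, drop = FALSE]
  attr(out, "removed") <- colnames(x)[drop_idx]
  out
}
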