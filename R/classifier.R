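# Derive a stable child seed (< 2^31) from a master seed and a salt string.
derive_seed <- function(seed, salt) {
  h <- 7
  for (cd in utf8ToInt(salt)) h <- (h * 131 + cd) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 48611 * 44449 + h) %% 2147483629)
}

# Evaluate expr under a temporary RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("empty feature matrix", call. = FALSE)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in y", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  list(x = x, y = y)
}

#' Fit the drug-target interaction random forest
#'
#' Grows an ensemble of classification trees, each on a bootstrap sample of
#' the pairs, considering `mtry` randomly selected features per split with
#' the Gini criterion.  The out-of-bag (OOB) misclassification rate is the
#' built-in generalization estimate; predicted probabilities are the
#' fraction of tree votes for the positive class.
#'
#' @param x Pair feature matrix (rows = drug-target pairs).
#' @param y Binary labels (1 = interaction).
#' @param mtry Features sampled per split; default `floor(sqrt(ncol(x)))`.
#' @param ntree Number of trees (default 600).
#' @param seed Master seed; the full train/predict/importance path is
#'   reproducible given this seed.
#' @param importance If `TRUE`, compute OOB permutation importance (each
#'   feature perturbed in turn; the drop in OOB quality is its score).
#' @param class_weights Optional numeric length-2 weights (negative,
#'   positive) for imbalanced training; default unweighted.
#' @return Object of class `dti_rf` with elements `fit` (ranger forest),
#'   `mtry`, `ntree`, `seed`, `oob_error`, `importances`, `feature_names`.
#' @seealso [predict.dti_rf()], [tune_mtry()], [feature_importance()]
#' @export
dti_rf <- function(x, y, mtry = NULL, ntree = 600L, seed = 1L,
                   importance = FALSE, class_weights = NULL) {
  d <- .check_xy(x, y)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry < 1L || mtry > p)
    stop("mtry must lie in [1, ", p, "]", call. = FALSE)
  if (ntree < 1L) stop("ntree must be >= 1", call. = FALSE)
  yf <- factor(d$y, levels = c(0L, 1L))
  fit <- ranger::ranger(
    x = d$x, y = yf,
    num.trees = as.integer(ntree), mtry = as.integer(mtry),
    splitrule = "gini", replace = TRUE,
    importance = if (importance) "permutation" else "none",
    class.weights = class_weights,
    seed = derive_seed(seed, "forest"), num.threads = 1L)
  structure(list(fit = fit,
                 mtry = as.integer(mtry), ntree = as.integer(ntree),
                 seed = as.integer(seed),
                 oob_error = fit$prediction.error,
                 importances = if (importance) fit$variable.importance,
                 feature_names = colnames(d$x),
                 probability = "fraction of tree votes for the positive class"),
            class = "dti_rf")
}

#' @export
print.dti_rf <- function(x, ...) {
  cat("Drug-target interaction random forest\n")
  cat(sprintf("  trees: %d   mtry: %d   features: %d\n",
              x$ntree, x$mtry, length(x$feature_names)))
  cat(sprintf("  OOB misclassification rate: %.4f\n", x$oob_error))
  invisible(x)
}

#' @method summary dti_rf
#' @export
summary.dti_rf <- function(object, ...) {
  print(object)
  if (!is.null(object$importances)) {
    top <- sort(object$importances, decreasing = TRUE)[1:min(10,
                length(object$importances))]
    cat("  top features by permutation importance:\n")
    for (nm in names(top)) cat(sprintf("    %-28s %.5f\n", nm, top[nm]))
  }
  invisible(object)
}

#' Predict interaction probabilities from a fitted forest
#'
#' @param object A `dti_rf` model.
#' @param x Feature matrix with the training feature count.
#' @param type `"prob"` (vote fraction for the positive class) or
#'   `"class"` (probability >= 0.5).
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\] (or 0/1 labels).
#' @export
predict.dti_rf <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (ncol(x) != length(object$feature_names))
    stop("feature count mismatch: model has ",
         length(object$feature_names), ", input has ", ncol(x),
         call. = FALSE)
  colnames(x) <- object$feature_names
  pr <- stats::predict(object$fit, data = x, predict.all = TRUE,
                       num.threads = 1L)$predictions
  # per-tree codes index into forest$levels
  pos_code <- match("1", object$fit$forest$levels)
  prob <- rowMeans(pr == pos_code)
  if (type == "class") as.integer(prob >= 0.5) else prob
}

#' Tune mtry by out-of-bag error
#'
#' Screens a grid of `mtry` values (default 5 to 100 by 5); each candidate
#' is fit `repeats` times with distinct derived seeds and scored by its
#' mean OOB misclassification rate.  Ties break toward smaller `mtry`.
#'
#' @param x,y Training data as in [dti_rf()].
#' @param grid Candidate `mtry` values.
#' @param ntree Trees per fit (default 600).
#' @param repeats Fits per candidate (default 5).
#' @param seed Master seed.
#' @return List with `best_mtry` and `profile` (data frame: mtry,
#'   mean_oob_error, sd_oob_error).
#' @export
tune_mtry <- function(x, y, grid = seq(5L, 100L, by = 5L), ntree = 600L,
                      repeats = 5L, seed = 1L) {
  d <- .check_xy(x, y)
  if (length(grid) == 0L) stop("empty mtry grid", call. = FALSE)
  if (any(grid < 1L) || any(grid > ncol(d$x)))
    stop("grid values must lie in [1, ", ncol(d$x), "]", call. = FALSE)
  grid <- sort(unique(as.integer(grid)))
  prof <- t(vapply(grid, function(m) {
    errs <- vapply(seq_len(repeats), function(r) {
      dti_rf(d$x, d$y, mtry = m, ntree = ntree,
             seed = derive_seed(seed, paste0("mtry", m, "rep", r)))$oob_error
    }, 0)
    c(mean(errs), stats::sd(errs))
  }, c(0, 0)))
  profile <- data.frame(mtry = grid, mean_oob_error = prof[, 1],
                        sd_oob_error = prof[, 2])
  best <- grid[which.min(profile$mean_oob_error)]
  list(best_mtry = best, profile = profile)
}

#' Permutation importance scores of a fitted forest
#'
#' @param model A `dti_rf` fitted with `importance = TRUE`.
#' @return Named numeric vector, one score per feature (training order).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "dti_rf"))
  if (is.null(model$importances))
    stop("model was fitted with importance = FALSE; refit with ",
         "importance = TRUE", call. = FALSE)
  model$importances
}

#' Select the k most important features
#'
#' @param importances Numeric importance scores (named or not).
#' @param k Number of features to keep (default 300).
#' @return Integer indices of the k largest scores, ties broken toward the
#'   smaller index.
#' @export
select_top_features <- function(importances, k = 300L) {
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  if (k > length(importances))
    stop("k exceeds the number of features", call. = FALSE)
  order(-importances, seq_along(importances))[seq_len(k)]
}

#' Naive Bayes baseline for pair feature vectors
#'
#' Independent per-feature class-conditional model: binary features (the
#' fingerprint bits) get a Bernoulli likelihood with Laplace smoothing,
#' continuous features (the protein descriptors) a Gaussian likelihood.
#' Posteriors are accumulated in log space.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param laplace Laplace pseudo-count for Bernoulli features (default 1).
#' @param var_floor Lower bound on Gaussian variances (default 1e-9).
#' @return Object of class `dti_nb`.
#' @export
dti_nb <- function(x, y, laplace = 1, var_floor = 1e-9) {
  d <- .check_xy(x, y)
  x <- d$x; y <- d$y
  is_bin <- apply(x, 2L, function(col) all(col %in% c(0, 1)))
  classes <- c(0L, 1L)
  prior <- vapply(classes, function(cl) mean(y == cl), 0)
  par <- lapply(classes, function(cl) {
    xs <- x[y == cl, , drop = FALSE]
    nc <- nrow(xs)
    p1 <- (colSums(xs[, is_bin, drop = FALSE]) + laplace) /
      (nc + 2 * laplace)
    mu <- colMeans(xs[, !is_bin, drop = FALSE])
    v <- apply(xs[, !is_bin, drop = FALSE], 2L, stats::var)
    v[!is.finite(v) | v < var_floor] <- var_floor
    list(p1 = p1, mu = mu, var = v)
  })
  names(par) <- c("neg", "pos")
  structure(list(prior = stats::setNames(prior, c("neg", "pos")),
                 par = par, is_binary = is_bin,
                 feature_names = colnames(x)),
            class = "dti_nb")
}

#' @export
print.dti_nb <- function(x, ...) {
  cat("Naive Bayes drug-target baseline\n")
  cat(sprintf("  features: %d (%d Bernoulli, %d Gaussian)   priors: %.3f/%.3f\n",
              length(x$is_binary), sum(x$is_binary), sum(!x$is_binary),
              x$prior["neg"], x$prior["pos"]))
  invisible(x)
}

#' Predict posterior interaction probabilities from the Naive Bayes baseline
#'
#' @param object A `dti_nb` model.
#' @param x Feature matrix with the training feature count.
#' @param ... Unused.
#' @return Numeric vector of posterior probabilities of the positive class.
#' @export
predict.dti_nb <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != length(object$is_binary))
    stop("feature count mismatch", call. = FALSE)
  ib <- object$is_binary
  xb <- x[, ib, drop = FALSE]
  xg <- x[, !ib, drop = FALSE]
  loglik <- vapply(c("neg", "pos"), function(cl) {
    p <- object$par[[cl]]
    ll <- rep(log(object$prior[cl]), nrow(x))
    if (ncol(xb))
      ll <- ll + xb %*% log(p$p1) + (1 - xb) %*% log(1 - p$p1)
    if (ncol(xg)) {
      ll <- ll - 0.5 * colSums((t(xg) - p$mu)^2 / p$var) -
        0.5 * sum(log(2 * pi * p$var))
    }
    as.numeric(ll)
  }, numeric(nrow(x)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1L)
  m <- pmax(loglik[, 1], loglik[, 2])
  as.numeric(exp(loglik[, 2] - m) /
               (exp(loglik[, 1] - m) + exp(loglik[, 2] - m)))
}
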