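test_that("folds partition the data with near-equal stratified sizes", {
  d <- planted_data(n = 100, p = 4, seed = 1)
  cv <- kfold_cv(d$x, d$y, k = 5, seed = 2, ntree = 30)
  expect_identical(sort(unique(cv$fold)), 1:5)
  expect_true(all(table(cv$fold) == 20))
  expect_identical(length(cv$prob), 100L)       # every sample predicted once
  expect_identical(cv$y, d$y)
  # stratification: class balance per fold within one sample
  tab <- table(cv$fold, cv$y)
  expect_true(max(tab[, 2]) - min(tab[, 2]) <= 1)
  # fold assignment reproducible
  cv2 <- kfold_cv(d$x, d$y, k = 5, seed = 2, ntree = 30)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$prob, cv2$prob)
  expect_error(kfold_cv(d$x, d$y, k = 101), "must not exceed")
  expect_error(kfold_cv(d$x, d$y, k = 1), ">= 2")
})

test_that("k = n cross-validation is leave-one-out", {
  set.seed(5)
  x <- matrix(rnorm(48), 12, 4); colnames(x) <- paste0("f", 1:4)
  y <- rep(c(0L, 1L), 6)
  cv <- kfold_cv(x, y, k = 12, seed = 3, fit = function(x, y, seed, ...)
    dti_nb(x, y))
  expect_identical(sort(cv$fold), 1:12)  # each fold is a single sample
})

test_that("auROC and auPRC match hand-derived values", {
  cs <- curves_and_areas(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))
  expect_equal(cs$auroc, 2 / 3, tolerance = 1e-12)
  perfect <- curves_and_areas(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$auprc, 1)
  expect_error(curves_and_areas(1:3 / 3, c(1, 1, 1)), "both classes")
  # ROC endpoints
  expect_equal(cs$roc$fpr[1], 0); expect_equal(cs$roc$tpr[1], 0)
  expect_equal(cs$roc$fpr[nrow(cs$roc)], 1)
  expect_equal(cs$roc$tpr[nrow(cs$roc)], 1)
})

test_that("auROC equals brute-force concordant-pair counting", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    s <- round(runif(n), 2)  # induce ties
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    expect_equal(curves_and_areas(s, y)$auroc, brute_auroc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("auROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  s <- runif(300); y <- rbinom(300, 1, plogis(3 * s - 1.5))
  expect_equal(curves_and_areas(s, y)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("auROC is invariant under strictly monotone score transforms", {
  set.seed(12)
  s <- runif(200); y <- rbinom(200, 1, s)
  a <- curves_and_areas(s, y)$auroc
  expect_equal(curves_and_areas(s^3, y)$auroc, a, tolerance = 1e-12)
  expect_equal(curves_and_areas(qlogis(s / 1.001 + 1e-4), y)$auroc, a,
               tolerance = 1e-12)
})

test_that("label-independent scores give chance-level auROC", {
  set.seed(14)
  s <- runif(2000); y <- rbinom(2000, 1, 0.4)
  P <- sum(y); N <- 2000 - P
  se <- sqrt((P + N + 1) / (12 * P * N))
  expect_lt(abs(curves_and_areas(s, y)$auroc - 0.5), 3 * se)
})

test_that("confusion summaries satisfy their identities", {
  cm <- confusion_at_threshold(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0), 0.5)
  expect_identical(c(cm$TP, cm$FN, cm$TN, cm$FP), c(1L, 1L, 1L, 1L))
  expect_equal(cm$Acc, 50)
  zero <- confusion_at_threshold(runif(20), rbinom(20, 1, 0.5), 0)
  expect_identical(zero$FN + zero$TN, 0L)  # everything predicted positive
  set.seed(16)
  for (i in 1:100) {
    s <- runif(30); y <- rbinom(30, 1, 0.5); t <- runif(1)
    cm <- confusion_at_threshold(s, y, t)
    expect_identical(cm$TP + cm$FN + cm$TN + cm$FP, 30L)
    expect_equal(cm$Acc, (cm$TP + cm$TN) * 100 / 30)
    if (cm$TP + cm$FN > 0)
      expect_equal(cm$Sen, cm$TP * 100 / (cm$TP + cm$FN))
  }
  expect_error(confusion_at_threshold(0.5, 1, 2), "0, 1")
})

test_that("Ki-probability correlation behaves at the extremes", {
  ki <- 10^(1:10)
  prob <- 1 - (1:10) / 10  # linear in log10(Ki)
  expect_equal(ki_probability_correlation(ki, prob), -1, tolerance = 1e-12)
  set.seed(18)
  expect_lt(abs(ki_probability_correlation(10^runif(1000, 1, 6),
                                           runif(1000))), 0.1)
  expect_error(ki_probability_correlation(c(-1, 2), c(0.1, 0.2)),
               "positive")
  expect_error(ki_probability_correlation(c(10, 10), c(0.1, 0.2)),
               "zero variance")
})

test_that("property ablation removes exactly the property's columns", {
  b <- make_benchmark(config = small_config(seed = 9))
  fpm <- fingerprint_matrix(b$drugs)
  pfm <- protein_feature_matrix(b$proteins)
  ds <- build_pair_dataset(b$interactions, fpm, pfm)
  h <- ablate_property(ds$x, "hydrophobicity")
  expect_identical(ncol(h), 1170L)
  expect_length(attr(h, "removed"), 21L)
  expect_true(all(grepl("^hydrophobicity", attr(h, "removed"))))
  a <- ablate_property(ds$x, "AAC")
  expect_identical(ncol(a), 1171L)
  expect_error(ablate_property(ds$x, "charge2"), "unknown property")
})

test_that("threshold sweep relabels, skips degenerate thresholds and
          reduces to plain CV for one threshold", {
  b <- make_benchmark(config = small_config(seed = 11))
  fpm <- fingerprint_matrix(b$drugs)
  pfm <- protein_feature_matrix(b$proteins)
  nbfit <- function(x, y, seed, ...) dti_nb(x, y)
  sw <- threshold_sweep(b$interactions, fpm, pfm,
                        thresholds_uM = c(1, 10, 100), k = 3, seed = 5,
                        fit = nbfit)
  expect_true(all(diff(sw$n_pos) >= 0))  # positives monotone in threshold
  single <- threshold_sweep(b$interactions, fpm, pfm, thresholds_uM = 10,
                            k = 3, seed = 5, fit = nbfit)
  ds <- build_pair_dataset(b$interactions, fpm, pfm, threshold_nM = 1e4)
  cv <- kfold_cv(ds$x, ds$y, k = 3, seed = 5, fit = nbfit)
  expect_equal(single$auroc, curves_and_areas(cv$prob, cv$y)$auroc)
  # a threshold below every Ki yields one class and is skipped
  expect_warning(
    sw0 <- threshold_sweep(b$interactions, fpm, pfm,
                           thresholds_uM = c(1e-6, 10), k = 3, seed = 5,
                           fit = nbfit),
    "single class")
  expect_identical(nrow(sw0), 1L)
})
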