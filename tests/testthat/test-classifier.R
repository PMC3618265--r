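test_that("the forest learns a planted single-feature rule", {
  d <- planted_data(n = 500, p = 20, seed = 42)
  m <- dti_rf(d$x, d$y, ntree = 300, seed = 1)
  expect_lte(m$oob_error, 0.02)
  p <- predict(m, d$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean(p[d$y == 1]), 0.9)
  # decisively positive rows (away from the decision boundary) are near 1
  expect_true(all(p[d$x[, 1] > 0.5] >= 0.9))
})

test_that("permuted labels give chance-level OOB error", {
  d <- planted_data(n = 500, p = 20, seed = 42)
  set.seed(99)
  yperm <- sample(d$y)
  m <- dti_rf(d$x, yperm, ntree = 300, seed = 1)
  se <- sqrt(0.25 / 500)
  expect_lt(abs(m$oob_error - 0.5), 3 * se)
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- planted_data(n = 200, p = 10, seed = 7)
  m1 <- dti_rf(d$x, d$y, ntree = 100, seed = 5)
  m2 <- dti_rf(d$x, d$y, ntree = 100, seed = 5)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  expect_identical(m1$oob_error, m2$oob_error)
})

test_that("input contracts are enforced", {
  d <- planted_data(n = 50, p = 5, seed = 1)
  expect_error(dti_rf(d$x, rep(1L, 50)), "both classes")
  expect_error(dti_rf(d$x, d$y, mtry = 6), "mtry")
  expect_error(predict(dti_rf(d$x, d$y, ntree = 20), d$x[, 1:3]),
               "feature count mismatch")
  expect_error(dti_rf(d$x, d$y[1:10]), "length")
})

test_that("all-identical rows give identical probabilities", {
  d <- planted_data(n = 100, p = 5, seed = 2)
  m <- dti_rf(d$x, d$y, ntree = 50, seed = 3)
  xc <- matrix(1, 8, 5)
  expect_length(unique(predict(m, xc)), 1L)
})

test_that("mtry tuning screens the grid and returns the profile minimum", {
  d <- planted_data(n = 150, p = 100, seed = 11)
  tuned <- tune_mtry(d$x, d$y, ntree = 60, repeats = 1, seed = 4)
  expect_identical(nrow(tuned$profile), 20L)  # 5,10,...,100
  expect_identical(tuned$profile$mtry, seq(5L, 100L, by = 5L))
  i <- which.min(tuned$profile$mean_oob_error)
  expect_identical(tuned$best_mtry, tuned$profile$mtry[i])
  single <- tune_mtry(d$x, d$y, grid = 30, ntree = 40, repeats = 1)
  expect_identical(single$best_mtry, 30L)
  expect_error(tune_mtry(d$x, d$y, grid = integer(0)), "empty")
  expect_error(tune_mtry(d$x, d$y, grid = 200), "grid values")
})

test_that("OOB error converges between 400 and 600 trees", {
  d <- planted_data(n = 300, p = 30, seed = 13)
  e400 <- dti_rf(d$x, d$y, ntree = 400, seed = 8)$oob_error
  e600 <- dti_rf(d$x, d$y, ntree = 600, seed = 8)$oob_error
  expect_lt(abs(e400 - e600), 0.01)
})

test_that("permutation importance ranks the planted feature first", {
  d <- planted_data(n = 400, p = 25, seed = 17)
  m <- dti_rf(d$x, d$y, ntree = 200, seed = 2, importance = TRUE)
  imp <- feature_importance(m)
  expect_length(imp, 25)
  expect_identical(unname(which.max(imp)), 1L)
  # pure-noise features hover near zero importance
  expect_lt(abs(mean(imp[-1])), 0.01)
  # stable under the same seed
  m2 <- dti_rf(d$x, d$y, ntree = 200, seed = 2, importance = TRUE)
  expect_identical(feature_importance(m2), imp)
  expect_error(feature_importance(dti_rf(d$x, d$y, ntree = 20)),
               "importance = TRUE")
})

test_that("top-k selection is deterministic with index tie-breaks", {
  expect_identical(select_top_features(c(3, 1, 2), k = 3), c(1L, 3L, 2L))
  expect_identical(select_top_features(c(1, 2, 2), k = 2), c(2L, 3L))
  expect_error(select_top_features(1:3, k = 0), "positive")
  expect_error(select_top_features(1:3, k = 4), "exceeds")
  d <- planted_data(n = 400, p = 25, seed = 17)
  m <- dti_rf(d$x, d$y, ntree = 200, seed = 2, importance = TRUE)
  expect_identical(select_top_features(feature_importance(m), k = 1), 1L)
  # retraining on the informative subset does not hurt accuracy
  top <- select_top_features(feature_importance(m), k = 5)
  mk <- dti_rf(d$x[, top, drop = FALSE], d$y, ntree = 200, seed = 2)
  expect_lte(mk$oob_error, m$oob_error + 0.05)
})

test_that("naive Bayes posterior matches a hand-computed Bayes rule", {
  set.seed(21)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(g1 = rnorm(n, mean = ifelse(y == 1, 1, -1)),
             g2 = rnorm(n, mean = ifelse(y == 1, 0.5, -0.5)))
  m <- dti_nb(x, y)
  xt <- rbind(c(0.3, -0.2), c(-1.5, 0.8))
  # hand computation from the estimated parameters
  mu0 <- colMeans(x[y == 0, ]); v0 <- apply(x[y == 0, ], 2, var)
  mu1 <- colMeans(x[y == 1, ]); v1 <- apply(x[y == 1, ], 2, var)
  hand <- apply(xt, 1, function(r) {
    l0 <- prod(dnorm(r, mu0, sqrt(v0))) * 0.5
    l1 <- prod(dnorm(r, mu1, sqrt(v1))) * 0.5
    l1 / (l0 + l1)
  })
  expect_equal(predict(m, xt), hand, tolerance = 1e-9)
})

test_that("naive Bayes treats binary features as smoothed Bernoulli", {
  x <- cbind(b = c(1, 1, 1, 0, 0, 0, 0, 0))
  y <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  m <- dti_nb(x, y)
  # Laplace-smoothed: P(b=1|pos) = (3+1)/(4+2), P(b=1|neg) = (0+1)/(4+2)
  p1_pos <- 4 / 6; p1_neg <- 1 / 6
  post1 <- (0.5 * p1_pos) / (0.5 * p1_pos + 0.5 * p1_neg)
  expect_equal(predict(m, cbind(b = 1)), post1, tolerance = 1e-12)
})

test_that("uninformative features leave the posterior at the prior", {
  x <- matrix(1, 40, 3)
  y <- rep(c(0L, 1L), each = 20)  # balanced classes
  m <- dti_nb(x, y)
  expect_equal(predict(m, matrix(1, 5, 3)), rep(0.5, 5), tolerance = 1e-12)
  expect_error(dti_nb(x, rep(1L, 40)), "both classes")
})

test_that("naive Bayes agrees with e1071 on Gaussian-only data", {
  skip_if_not_installed("e1071")
  set.seed(31)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  x <- cbind(a = rnorm(n, y), b = rnorm(n, -y), c = rnorm(n))
  m <- dti_nb(x, y)
  ref <- e1071::naiveBayes(data.frame(x), factor(y))
  pref <- predict(ref, data.frame(x), type = "raw")[, "1"]
  expect_equal(predict(m, x), unname(pref), tolerance = 1e-6)
})

test_that("probabilities are invariant to consistent column permutation", {
  set.seed(41)
  d <- planted_data(n = 300, p = 10, seed = 3)
  perm <- sample(10)
  # exact for naive Bayes (order-free likelihood product)
  nb1 <- predict(dti_nb(d$x, d$y), d$x)
  nb2 <- predict(dti_nb(d$x[, perm], d$y), d$x[, perm])
  expect_equal(nb1, nb2, tolerance = 1e-12)
  # distributional for the forest: discrimination is preserved
  rf1 <- predict(dti_rf(d$x, d$y, ntree = 200, seed = 6), d$x)
  rf2 <- predict(dti_rf(d$x[, perm], d$y, ntree = 200, seed = 6),
                 d$x[, perm])
  a1 <- curves_and_areas(rf1, d$y)$auroc
  a2 <- curves_and_areas(rf2, d$y)$auroc
  expect_lt(abs(a1 - a2), 0.02)
})

test_that("the forest agrees with an independent ensemble implementation", {
  skip_if_not_installed("randomForest")
  d <- planted_data(n = 300, p = 15, seed = 23)
  m <- dti_rf(d$x, d$y, ntree = 300, seed = 1)
  set.seed(1)
  ref <- randomForest::randomForest(d$x, factor(d$y), ntree = 300)
  pm <- predict(m, d$x)
  pr <- predict(ref, d$x, type = "prob")[, "1"]
  expect_lt(abs(curves_and_areas(pm, d$y)$auroc -
                  curves_and_areas(pr, d$y)$auroc), 0.02)
  expect_lt(abs(m$oob_error - ref$err.rate[300, "OOB"]), 0.05)
})
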