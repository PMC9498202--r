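test_that("k = 1 returns the exact nearest neighbour's label", {
  set.seed(13)
  # >= 3 columns: correlation distance on 2-D points is degenerate (+/- 1)
  X <- matrix(rnorm(90), 30, 3)
  y <- sample(c("healthy", "septic"), 30, replace = TRUE)
  # a query equal to a training point gets that point's label
  expect_identical(knn_predict(X, y, X[7, , drop = FALSE], k = 1), y[7])
  # k = 1 equals a brute-force nearest scan for every metric
  Q <- matrix(rnorm(30), 10, 3)
  for (m in knn_metrics) {
    expect_identical(knn_predict(X, y, Q, k = 1, metric = m),
                     oracle_knn(X, y, Q, 1, m),
                     info = m)
  }
})

test_that("KNN matches an exhaustive all-pairs oracle for all nine metrics", {
  set.seed(14)
  X <- matrix(rnorm(200), 50, 4)
  # inject zeros and ties so jaccard/hamming paths are exercised
  X[sample(length(X), 40)] <- 0
  y <- sample(c("healthy", "septic"), 50, replace = TRUE)
  Q <- rbind(matrix(rnorm(48), 12, 4), X[3, ], X[44, ])
  Q[c(2, 5), c(1, 3)] <- 0
  for (m in knn_metrics) {
    for (k in c(1L, 3L, 7L)) {
      expect_identical(knn_predict(X, y, Q, k = k, metric = m),
                       oracle_knn(X, y, Q, k, m),
                       info = paste(m, "k =", k))
    }
  }
  expect_error(knn_predict(X, y, Q, k = 0), "k must")
  expect_error(knn_predict(X, y, Q, k = 51), "k must")
  Xz <- X
  Xz[, 2] <- 1
  expect_error(knn_predict(Xz, y, Q, metric = "standardized_euclidean"),
               "zero-variance")
})

test_that("the Gaussian SVM separates separable clouds and validates inputs", {
  set.seed(15)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  y <- rep(c("healthy", "septic"), each = 30)
  fit <- svm_train(X, y, kernel_scale = 10, box_constraint = 100)
  expect_identical(predict(fit, X), y)
  expect_error(svm_train(X, y, kernel_scale = -1), "positive")
  expect_error(svm_train(X, rep("healthy", 60)), "both classes")
  expect_error(predict(fit, X[, 1, drop = FALSE]), "dimensionality")
})

test_that("the Gaussian kernel matrix is symmetric positive semidefinite", {
  set.seed(16)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    K <- gaussian_kernel(X, kernel_scale = runif(1, 0.5, 5))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_equal(diag(K), rep(1, 30))
  }
})

test_that("the Bayesian optimiser respects its budget and finds a convex optimum", {
  space <- hyperparameter_space("SVM")
  tr1 <- bayesian_optimize(function(p) 0.5, space, budget = 1, seed = 1)
  expect_identical(nrow(tr1$evaluations), 1L)
  expect_equal(tr1$best_objective, 0.5)
  tr30 <- bayesian_optimize(function(p) log10(p$kernel_scale)^2, space,
                            budget = 30, seed = 2)
  expect_identical(nrow(tr30$evaluations), 30L)
  # incumbent trace is non-increasing
  expect_true(all(diff(tr30$evaluations$incumbent) <= 0))
  # minimum of (log10 sigma)^2 is sigma = 1; 30 evaluations should land
  # within +/- 0.3 decades in at least 95 of 100 seeded runs
  hits <- sum(vapply(1:100, function(s) {
    tr <- bayesian_optimize(function(p) log10(p$kernel_scale)^2, space,
                            budget = 30, seed = s)
    abs(log10(tr$best_params$kernel_scale)) <= 0.3
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("non-finite objectives are penalised, not fatal", {
  space <- hyperparameter_space("SVM")
  tr <- bayesian_optimize(function(p) {
    if (p$kernel_scale > 1) NaN else log10(p$kernel_scale)^2
  }, space, budget = 15, seed = 3)
  expect_identical(nrow(tr$evaluations), 15L)
  expect_true(is.finite(tr$best_objective))
  expect_lte(tr$best_params$kernel_scale, 1)
})

test_that("the optimiser tunes KNN's categorical metric too", {
  set.seed(17)
  # objective prefers small k and the cosine metric
  tr <- bayesian_optimize(function(p) {
    0.1 * p$k + ifelse(p$metric == "cosine", 0, 1)
  }, hyperparameter_space("KNN"), budget = 30, seed = 4)
  expect_identical(tr$best_params$metric, "cosine")
  expect_lte(tr$best_params$k, 3L)
})

test_that("stratified folds balance classes and are row-order invariant", {
  tab <- toy_feature_table(n_per_class = 23, seed = 18)
  fold <- assign_folds(tab$id, tab$label, folds = 5, seed = 9)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 2)  # one per class at most
  for (f in 1:5) {
    per_class <- table(tab$label[fold == f])
    expect_lte(abs(diff(as.numeric(per_class))), 1)
  }
  perm <- sample(nrow(tab))
  fold_perm <- assign_folds(tab$id[perm], tab$label[perm], folds = 5,
                            seed = 9)
  expect_identical(fold_perm[order(perm)], fold)
  expect_error(assign_folds(c("a", "b"), c("healthy", "septic"), folds = 5),
               "fewer samples than folds")
})

test_that("cross-validation reports per-fold and aggregate metrics", {
  tab <- toy_feature_table(n_per_class = 30, n_informative = 2, n_noise = 1,
                           effect = 4, seed = 19)
  rep <- cross_validate(tab, "KNN", folds = 5, seed = 2, bhpo_budget = 6)
  expect_identical(length(rep$per_fold), 5L)
  expect_gte(unname(rep$aggregate$accuracy["mean"]), 0.9)
  expect_true(all(c("mean", "sd") %in% names(rep$aggregate$mcc)))
  # shuffling rows leaves the metrics unchanged (id-hashed folds)
  perm <- sample(nrow(tab))
  tab_perm <- tab[perm, ]
  class(tab_perm) <- class(tab)
  rep_perm <- cross_validate(tab_perm, "KNN", folds = 5, seed = 2,
                             bhpo_budget = 6)
  expect_equal(rep_perm$aggregate, rep$aggregate, tolerance = 1e-12)
  # JSON serialisation round-trips the headline numbers
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$aggregate$accuracy$mean,
               unname(rep$aggregate$accuracy["mean"]), tolerance = 1e-12)
  expect_identical(length(back$per_fold), 5L)
})

test_that("per-fold FE selection trims the feature set inside CV", {
  tab <- toy_feature_table(n_per_class = 30, n_informative = 2, n_noise = 4,
                           effect = 4, seed = 20)
  rep <- cross_validate(tab, "KNN", folds = 5, seed = 3, bhpo_budget = 4,
                        select_fe = TRUE)
  expect_true(all(rep$n_features < 6))
  expect_gte(unname(rep$aggregate$accuracy["mean"]), 0.9)
})

test_that("paper-mode tuning shares one configuration across folds", {
  tab <- toy_feature_table(n_per_class = 20, effect = 4, seed = 22)
  rep <- cross_validate(tab, "KNN", folds = 5, seed = 4, bhpo_budget = 5,
                        paper_mode = TRUE)
  params <- unique(vapply(rep$tuned, function(p) {
    paste(p$k, p$metric)
  }, ""))
  expect_identical(length(params), 1L)
})
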