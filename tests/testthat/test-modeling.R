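# PCA reduction, classifiers, cross-validation, confusion metrics.

test_that("two perfectly correlated features collapse to one component", {
  set.seed(1)
  a <- rnorm(30)
  m <- cbind(f1 = a, f2 = 2 * a + 5)
  fit <- pca_fit_reduce(m)
  expect_equal(fit$k, 1)
  expect_equal(fit$cum_var[1], 1.0, tolerance = 1e-12)
})

test_that("independent standardized features need most components", {
  set.seed(2)
  n <- 400
  m <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  fit <- pca_fit_reduce(m, 0.85)
  # eigen-decomposition oracle at this fixed n and seed
  ev <- sort(eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.85)[1]
  expect_equal(fit$k, k_oracle)
  expect_gte(fit$k, 6)
  expect_equal(fit$var_frac * 8, ev, tolerance = 1e-10)
})

test_that("full-rank reconstruction reproduces the standardized table", {
  set.seed(3)
  m <- matrix(rnorm(25 * 5), 25, dimnames = list(NULL, paste0("f", 1:5)))
  fit <- pca_fit_reduce(m, 1.0)
  z <- scale(m)
  recon <- fit$scores %*% t(fit$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)
})

test_that("explained-variance fractions are nonincreasing and sum to 1", {
  set.seed(4)
  m <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("f", 1:6)))
  fit <- pca_fit_reduce(m)
  expect_true(all(diff(fit$var_frac) <= 1e-12))
  expect_equal(sum(fit$var_frac), 1, tolerance = 1e-12)
  expect_error(pca_fit_reduce(cbind(m, const = rep(1, 40))), "constant")
})

test_that("confusion metrics: hand-worked 2x2 values", {
  perfect <- confusion_metrics(matrix(c(11, 0, 0, 16), 2, byrow = TRUE))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$fp_rate, 0)

  cm <- matrix(c(9, 2, 3, 13), 2, byrow = TRUE)
  out <- confusion_metrics(cm)
  expect_equal(out$accuracy, 22 / 27, tolerance = 1e-12)
  expect_equal(out$mcc, 111 / sqrt(31680), tolerance = 1e-12)
  expect_equal(out$mcc, 0.6236, tolerance = 1e-3)

  degen <- confusion_metrics(matrix(c(11, 0, 16, 0), 2, byrow = TRUE))
  expect_equal(degen$mcc, 0)
  expect_true(degen$flagged)
  expect_equal(degen$accuracy, 11 / 27)
})

test_that("weighted TP rate equals accuracy for two classes", {
  set.seed(5)
  for (i in 1:5) {
    cm <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (sum(cm) == 0) next
    out <- confusion_metrics(cm)
    expect_equal(out$tp_rate, out$accuracy, tolerance = 1e-12)
  }
})

test_that("stratified folds spread both classes and are seed-stable", {
  labels <- c(rep("IFR", 11), rep("NPD", 16))
  f1 <- radrecur:::stratified_folds(labels, 10, 42)
  f2 <- radrecur:::stratified_folds(labels, 10, 42)
  expect_identical(f1, f2)
  expect_false(identical(f1, radrecur:::stratified_folds(labels, 10, 43)))
  # every fold receives at least one minority case or stays within balance
  tab <- table(fold = f1, label = labels)
  expect_true(all(rowSums(tab) >= 2))
  expect_true(all(tab[, "NPD"] >= 1))
})

test_that("perfectly separated clusters give accuracy 1 for all models", {
  set.seed(6)
  n <- 14
  m <- rbind(matrix(rnorm(n * 3, -6, 0.3), n),
             matrix(rnorm(n * 3, 6, 0.3), n))
  colnames(m) <- paste0("f", 1:3)
  rownames(m) <- sprintf("c%02d", 1:(2 * n))
  labels <- rep(c("IFR", "NPD"), each = n)
  cv <- run_cv(m, labels, folds = 10, seed = 1)
  expect_true(all(cv$metrics$accuracy == 1))
  expect_true(all(cv$metrics$mcc == 1))
})

test_that("CV is reproducible bit-for-bit and case-order invariant", {
  set.seed(7)
  m <- matrix(rnorm(27 * 4), 27, dimnames = list(sprintf("c%02d", 1:27),
                                                 paste0("f", 1:4)))
  m[1:11, 1] <- m[1:11, 1] + 2
  labels <- c(rep("IFR", 11), rep("NPD", 16))
  cv1 <- run_cv(m, labels, seed = 5)
  cv2 <- run_cv(m, labels, seed = 5)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$predictions, cv2$predictions)

  perm <- sample(27)
  cv3 <- run_cv(m[perm, ], labels[perm], seed = 5)
  expect_equal(dplyr::arrange(cv3$metrics, .data$model),
               dplyr::arrange(cv1$metrics, .data$model))
})

test_that("training fits never see test-fold labels", {
  set.seed(8)
  m <- matrix(rnorm(27 * 3), 27, dimnames = list(sprintf("c%02d", 1:27),
                                                 paste0("f", 1:3)))
  labels <- c(rep("IFR", 11), rep("NPD", 16))
  cv1 <- run_cv(m, labels, models = "svm", seed = 3)
  # corrupt the labels of fold-1 test cases only: predictions for that fold
  # come from a model trained without them, so they cannot change
  f1 <- cv1$fold_assign == 1
  labels2 <- labels
  labels2[f1] <- rev(labels[f1])
  cv2 <- run_cv(m, labels2, models = "svm", seed = 3)
  same_assign <- identical(cv1$fold_assign, cv2$fold_assign)
  if (same_assign) {
    p1 <- cv1$predictions$prediction[cv1$predictions$fold == 1]
    p2 <- cv2$predictions$prediction[cv2$predictions$fold == 1]
    expect_identical(p1, p2)
  } else {
    succeed()  # fold layout changed with the label permutation; not comparable
  }
})

test_that("null-label permutations keep mean accuracy near chance", {
  set.seed(9)
  m <- matrix(rnorm(27 * 3), 27, dimnames = list(sprintf("c%02d", 1:27),
                                                 paste0("f", 1:3)))
  base <- c(rep("IFR", 11), rep("NPD", 16))
  accs <- replicate(40, {
    labs <- sample(base)
    cv <- run_cv(m, labs, models = c("knn", "svm"), seed = 1)
    mean(cv$metrics$accuracy)
  })
  # majority-class rate is 16/27 = 0.593; chance-level CV should sit within
  # 0.1 of it on average
  expect_lt(abs(mean(accs) - 16 / 27), 0.1)
})

test_that("paper-faithful mode fits PCA once on the full table", {
  set.seed(10)
  m <- matrix(rnorm(27 * 5), 27, dimnames = list(sprintf("c%02d", 1:27),
                                                 paste0("f", 1:5)))
  m[1:11, ] <- m[1:11, ] + 1.5
  labels <- c(rep("IFR", 11), rep("NPD", 16))
  cv_safe <- run_cv(m, labels, models = "knn", seed = 2)
  cv_pf <- run_cv(m, labels, models = "knn", seed = 2, paper_faithful = TRUE)
  expect_s3_class(cv_pf, "cv_report")
  expect_identical(cv_safe$fold_assign, cv_pf$fold_assign)
})

test_that("tidy and glance summarize a CV report", {
  set.seed(11)
  m <- matrix(rnorm(20 * 3), 20, dimnames = list(sprintf("c%02d", 1:20),
                                                 paste0("f", 1:3)))
  labels <- rep(c("IFR", "NPD"), each = 10)
  cv <- run_cv(m, labels, models = c("knn", "svm"), seed = 1)
  expect_equal(nrow(tidy(cv)), 2)
  g <- glance(cv)
  expect_equal(g$n_models, 2)
  expect_true(g$best_model %in% c("knn", "svm"))
})
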