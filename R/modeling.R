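#' PCA reduction to a cumulative explained-variance threshold
#'
#' Standardizes the features (zero mean, unit variance), performs PCA, and
#' retains the smallest number of components whose cumulative explained
#' variance reaches the threshold (default 85 percent). Component signs are
#' fixed by making each loading vector's largest-magnitude entry positive.
#'
#' @param x numeric matrix or feature tibble (cases x features), typically
#'   the significant-feature subset.
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @return A `pca_reduction`: loadings (features x k), per-component and
#'   cumulative explained-variance fractions, `k`, centering/scaling
#'   vectors, and the per-case `scores`.
#' @export
pca_fit_reduce <- function(x, variance_threshold = 0.85) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  stopifnot(ncol(m) >= 2, nrow(m) >= 3)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(head(colnames(m)[sds == 0], 3), collapse = ", "),
         "; remove upstream")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  cum_var <- cumsum(var_frac)
  k <- which(cum_var >= variance_threshold)[1]
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(
    list(loadings = rot[, seq_len(k), drop = FALSE],
         var_frac = var_frac, cum_var = cum_var, k = k,
         center = pc$center, scale = pc$scale,
         scores = scores[, seq_len(k), drop = FALSE],
         all_loadings = rot),
    class = "pca_reduction"
  )
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat("<pca_reduction> k =", x$k, "components, cumulative variance",
      sprintf("%.2f%%", 100 * x$cum_var[x$k]), "\n")
  invisible(x)
}

#' @describeIn pca_fit_reduce Per-component variance table.
#' @param x a `pca_reduction`.
#' @param ... unused.
#' @method tidy pca_reduction
#' @export
tidy.pca_reduction <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_frac),
                 var_fraction = x$var_frac,
                 cum_var_fraction = x$cum_var,
                 retained = seq_along(x$var_frac) <= x$k)
}

#' @describeIn pca_fit_reduce One-row summary (k, cumulative variance).
#' @method glance pca_reduction
#' @export
glance.pca_reduction <- function(x, ...) {
  tibble::tibble(k = x$k, cum_var = x$cum_var[x$k],
                 n_features = nrow(x$loadings))
}

# project new data onto a fitted reduction
pca_transform <- function(fit, newdata) {
  scale(newdata, center = fit$center, scale = fit$scale) %*% fit$loadings
}

#' Metrics of a pooled 2 x 2 confusion matrix
#'
#' Computes the standard two-class evaluation metrics with the weighted
#' per-class convention: TP rate (recall), FP rate, precision and
#' F-measure are computed per class and averaged weighted by class
#' prevalence; MCC uses the covariance formula on the pooled counts;
#' accuracy is trace over total. A zero MCC denominator yields MCC = 0
#' with `flagged = TRUE`.
#'
#' @param confusion 2 x 2 matrix of counts, rows = truth, columns =
#'   prediction, same class order.
#' @return One-row tibble: `tp_rate`, `fp_rate`, `precision`, `f_measure`,
#'   `mcc`, `accuracy`, `flagged`.
#' @export
confusion_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(all(dim(cm) == 2), all(cm >= 0), sum(cm) > 0)
  total <- sum(cm)
  wts <- rowSums(cm) / total
  per_class <- function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (prec + recall > 0) 2 * prec * recall / (prec + recall) else 0
    c(recall, fpr, prec, f)
  }
  m1 <- per_class(1)
  m2 <- per_class(2)
  w <- wts[1] * m1 + wts[2] * m2
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  flagged <- den == 0
  mcc <- if (flagged) 0 else (tp * tn - fp * fn) / den
  tibble::tibble(tp_rate = w[1], fp_rate = w[2], precision = w[3],
                 f_measure = w[4], mcc = mcc,
                 accuracy = sum(diag(cm)) / total, flagged = flagged)
}

# deterministic stratified fold assignment: class-wise round robin after a
# seeded shuffle
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  assign <- integer(length(labels))
  set.seed(seed)
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

fit_predict <- function(model, train_x, train_y, test_x, seed, config) {
  train_y <- factor(train_y)
  set.seed(seed)
  if (model == "ann") {
    size <- config$ann_size %||% ceiling((ncol(train_x) + 2) / 2)
    fit <- nnet::nnet(train_x, nnet::class.ind(train_y), size = size,
                      maxit = config$ann_maxit %||% 500,
                      decay = config$ann_decay %||% 1e-4,
                      entropy = TRUE, trace = FALSE)
    pred <- levels(train_y)[max.col(predict(fit, test_x))]
  } else if (model == "knn") {
    pred <- as.character(class::knn(train_x, test_x, train_y,
                                    k = config$knn_k %||% 3))
  } else if (model == "svm") {
    fit <- e1071::svm(train_x, train_y, kernel = "linear",
                      cost = config$svm_cost %||% 1, scale = FALSE,
                      probability = FALSE)
    pred <- as.character(predict(fit, test_x))
  } else stop("unknown model: ", model)
  pred
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validated classification
#'
#' Evaluates one or more classifiers (single-hidden-layer neural network,
#' k-nearest neighbors, linear support vector machine) by stratified
#' k-fold cross-validation. By default the standardization and PCA
#' reduction are refit inside each training fold and applied to the
#' held-out fold (no information leakage); `paper_faithful = TRUE` instead
#' fits PCA once on the full table before splitting, reproducing the
#' protocol in which components are derived from all cases. Metrics come
#' from the confusion matrix pooled across folds.
#'
#' @param x feature tibble or matrix (cases x features) of the selected
#'   features.
#' @param labels class label per case (2 classes).
#' @param models subset of `c("ann", "knn", "svm")`.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling fold assignment and model
#'   initialization; the whole CV is reproducible bit-for-bit given it.
#' @param variance_threshold PCA cumulative-variance threshold.
#' @param paper_faithful fit PCA on the full table before CV (see above).
#' @param config optional list of hyperparameters: `ann_size`,
#'   `ann_maxit`, `ann_decay`, `knn_k`, `svm_cost`.
#' @return A `cv_report`: `metrics` (tibble, one row per model),
#'   `predictions` (case, fold, truth, prediction, model), `fold_assign`,
#'   `seed`.
#' @export
run_cv <- function(x, labels, models = c("ann", "knn", "svm"), folds = 10,
                   seed = 1L, variance_threshold = 0.85,
                   paper_faithful = FALSE, config = list()) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, all(table(labels) >= 2))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  # canonical case order (by id when available) so results do not depend on
  # row order
  ord <- if (!is.null(rownames(m)) && !anyDuplicated(rownames(m)))
    order(rownames(m)) else seq_len(nrow(m))
  inv <- order(ord)
  m <- m[ord, , drop = FALSE]
  labels <- labels[ord]
  fold_assign <- stratified_folds(labels, folds, seed)

  # merge folds whose training set would miss a class
  for (f in sort(unique(fold_assign))) {
    if (nlevels(droplevels(labels[fold_assign != f])) < 2) {
      warning("fold ", f, " merged with neighbor (training class missing)")
      fold_assign[fold_assign == f] <- ifelse(f == 1, 2, f - 1)
    }
  }

  global_pca <- if (paper_faithful && ncol(m) >= 2)
    pca_fit_reduce(m, variance_threshold) else NULL

  preds <- list()
  for (model in models) {
    pred_all <- character(length(labels))
    for (f in sort(unique(fold_assign))) {
      tr <- fold_assign != f
      if (!is.null(global_pca)) {
        sc_tr <- global_pca$scores[tr, , drop = FALSE]
        sc_te <- global_pca$scores[!tr, , drop = FALSE]
      } else if (ncol(m) >= 2) {
        fit <- pca_fit_reduce(m[tr, , drop = FALSE], variance_threshold)
        sc_tr <- fit$scores
        sc_te <- pca_transform(fit, m[!tr, , drop = FALSE])
      } else {
        mu <- mean(m[tr, 1]); s <- sd(m[tr, 1])
        sc_tr <- matrix((m[tr, 1] - mu) / s)
        sc_te <- matrix((m[!tr, 1] - mu) / s)
      }
      pred_all[!tr] <- fit_predict(model, sc_tr, labels[tr], sc_te,
                                   seed + f, config)
    }
    preds[[model]] <- pred_all
  }

  metrics <- dplyr::bind_rows(lapply(models, function(mod) {
    cm <- table(truth = labels, pred = factor(preds[[mod]],
                                              levels = levels(labels)))
    dplyr::bind_cols(tibble::tibble(model = mod), confusion_metrics(cm))
  }))
  predictions <- dplyr::bind_rows(lapply(models, function(mod)
    tibble::tibble(model = mod, case = seq_along(labels),
                   fold = fold_assign[inv],
                   truth = as.character(labels[inv]),
                   prediction = preds[[mod]][inv])))
  structure(list(metrics = metrics, predictions = predictions,
                 fold_assign = fold_assign[inv], seed = seed,
                 paper_faithful = paper_faithful),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> stratified ", length(unique(x$fold_assign)),
      "-fold CV, seed ", x$seed, "\n", sep = "")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @describeIn run_cv Model-by-metric table.
#' @param x a `cv_report`.
#' @param ... unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$metrics

#' @describeIn run_cv One-row summary: best model and accuracy range.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$metrics),
    best_model = x$metrics$model[which.max(x$metrics$accuracy)],
    best_accuracy = max(x$metrics$accuracy),
    worst_accuracy = min(x$metrics$accuracy)
  )
}
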