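#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between
#' raters (columns of `ratings`), computed from the ANOVA mean squares.
#'
#' @param ratings numeric matrix, subjects x raters.
#' @return ICC scalar (NaN when between-subject variance is zero).
#' @export
icc_single <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  stopifnot(n >= 3, k >= 2)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Reproducibility (ICC) feature filter
#'
#' Computes the per-feature ICC(2,1) across two observers' feature tables
#' and retains features with ICC at or above the threshold. Features whose
#' ICC is undefined (zero between-subject variance) are removed with a
#' warning.
#'
#' @param obs1,obs2 feature tibbles (same cases, same feature columns), as
#'   from [extract_observer_pair()].
#' @param threshold retention threshold (default 0.8, "excellent"
#'   reproducibility).
#' @return List with `icc` (tibble: feature, icc) and `retained` (feature
#'   keys).
#' @export
icc_filter <- function(obs1, obs2, threshold = 0.8) {
  m1 <- feature_matrix(obs1)
  m2 <- feature_matrix(obs2)
  stopifnot(identical(colnames(m1), colnames(m2)),
            identical(rownames(m1), rownames(m2)))
  if (nrow(m1) < 3) stop("ICC needs at least 3 cases")
  icc <- vapply(seq_len(ncol(m1)), function(j)
    icc_single(cbind(m1[, j], m2[, j])), 0)
  undef <- !is.finite(icc)
  if (any(undef))
    warning(sum(undef), " features with undefined ICC removed")
  retained <- colnames(m1)[!undef & icc >= threshold]
  list(icc = tibble::tibble(feature = colnames(m1), icc = icc),
       retained = retained)
}

#' Redundancy pruning by pairwise Pearson correlation
#'
#' Iterative greedy pruning: while any retained pair correlates with
#' `|PCC| >=` the threshold, take the most correlated pair and drop the
#' member whose mean absolute correlation with all other retained features
#' is larger (ties broken by lexicographic feature key, dropping the later
#' key). Constant features are removed first with a warning.
#'
#' @param features feature tibble or numeric matrix (cases x features).
#' @param threshold correlation threshold (default 0.80).
#' @return Character vector of surviving feature keys.
#' @export
pcc_prune <- function(features, threshold = 0.80) {
  m <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(m) < 3) stop("need at least 3 cases")
  const <- apply(m, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))
  if (any(const)) {
    warning(sum(const), " constant features removed before pruning")
    m <- m[, !const, drop = FALSE]
  }
  keys <- colnames(m)
  if (length(keys) < 2) return(keys)
  r <- abs(cor(m))
  diag(r) <- 0
  repeat {
    if (max(r) < threshold) break
    idx <- which(r == max(r), arr.ind = TRUE)
    # deterministic pair choice: lexicographically first pair
    pair_keys <- t(apply(idx, 1, function(ij)
      sort(c(rownames(r)[ij[1]], rownames(r)[ij[2]]))))
    ord <- order(pair_keys[, 1], pair_keys[, 2])
    a <- pair_keys[ord[1], 1]
    b <- pair_keys[ord[1], 2]
    mean_a <- mean(r[a, setdiff(colnames(r), a)])
    mean_b <- mean(r[b, setdiff(colnames(r), b)])
    drop <- if (mean_a > mean_b) a
            else if (mean_b > mean_a) b
            else max(a, b)           # tie: drop the later key
    keep <- setdiff(colnames(r), drop)
    r <- r[keep, keep, drop = FALSE]
    if (length(keep) < 2) break
  }
  colnames(r)
}

#' Kruskal-Wallis screening with Benjamini-Hochberg correction
#'
#' Tests each feature for a class difference with the Kruskal-Wallis rank
#' test (tie-corrected H, chi-squared p-value), adjusts p-values by the
#' Benjamini-Hochberg step-up procedure, and marks features with adjusted
#' p below `alpha` as significant.
#'
#' @param features feature tibble or matrix (cases x features).
#' @param labels class label per case (2 classes, each with >= 2 cases).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return Tibble: `feature`, `p`, `p_adjusted`, `significant`.
#' @export
kw_bh_test <- function(features, labels, alpha = 0.05) {
  m <- if (is.matrix(features)) features else feature_matrix(features)
  labels <- as.factor(labels)
  if (any(table(labels) < 2) || nlevels(labels) < 2)
    stop("each class needs at least 2 cases")
  p <- vapply(seq_len(ncol(m)), function(j)
    suppressWarnings(kruskal.test(m[, j], labels)$p.value), 0)
  # a feature identical across all cases has H = 0/0; report p = 1
  p[!is.finite(p)] <- 1
  p_adj <- p.adjust(p, method = "BH")
  tibble::tibble(feature = colnames(m), p = p, p_adjusted = p_adj,
                 significant = p_adj < alpha)
}

#' ROC analysis of a single feature
#'
#' Empirical ROC by threshold sweep. The AUC equals the Mann-Whitney
#' statistic scaled to \[0, 1\] with half credit for ties, oriented so AUC
#' >= 0.5. The standard error follows Hanley and McNeil (1982), the 95
#' percent CI is `AUC +/- 1.96 SE` truncated to \[0, 1\], and sensitivity /
#' specificity are reported at the Youden-optimal threshold (ties resolved
#' toward the lower threshold).
#'
#' @param values numeric feature values.
#' @param labels two-class labels; `positive` names the class to detect
#'   (defaults to `"IFR"` when present, else the first level).
#' @param positive positive-class label.
#' @return One-row tibble: `auc`, `se`, `ci_lo`, `ci_hi`, `sensitivity`,
#'   `specificity`, `direction`, `flagged` (degenerate input).
#' @export
roc_analysis <- function(values, labels, positive = NULL) {
  labels <- as.character(labels)
  if (is.null(positive))
    positive <- if ("IFR" %in% labels) "IFR" else labels[1]
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  n1 <- length(pos)
  n2 <- length(neg)
  stopifnot(n1 > 0, n2 > 0)
  flagged <- FALSE
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  direction <- ">="
  if (auc < 0.5) {
    auc <- 1 - auc
    direction <- "<="
  }
  if (length(unique(values)) == 1) {
    auc <- 0.5
    flagged <- TRUE
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)

  thr <- sort(unique(values))
  best <- c(j = -Inf, sens = NA, spec = NA, t = NA)
  for (t in thr) {
    pred_pos <- if (direction == ">=") values >= t else values <= t
    sens <- sum(pred_pos & labels == positive) / n1
    spec <- sum(!pred_pos & labels != positive) / n2
    j <- sens + spec - 1
    if (j > best["j"]) best <- c(j = j, sens = sens, spec = spec, t = t)
  }
  tibble::tibble(auc = auc, se = se, ci_lo = ci[1], ci_hi = ci[2],
                 sensitivity = unname(best["sens"]),
                 specificity = unname(best["spec"]),
                 direction = direction, flagged = flagged)
}

#' The full feature-selection cascade
#'
#' Runs the fixed selection order: reproducibility filter (ICC across two
#' observers), redundancy pruning (pairwise Pearson), Kruskal-Wallis class
#' screening with Benjamini-Hochberg correction, and per-feature ROC
#' analysis of the significant survivors. Each stage consumes only the
#' previous stage's survivors.
#'
#' @param obs1,obs2 observer feature tibbles from
#'   [extract_observer_pair()]; `obs1` carries the class labels.
#' @param icc_threshold,pcc_threshold,alpha stage thresholds.
#' @return A `selection_report`: icc table, retained key sets, test table,
#'   ROC table of significant features, and `significant_features`.
#' @export
select_features <- function(obs1, obs2, icc_threshold = 0.8,
                            pcc_threshold = 0.8, alpha = 0.05) {
  labels <- obs1$label
  st1 <- icc_filter(obs1, obs2, icc_threshold)
  m <- feature_matrix(obs1)[, st1$retained, drop = FALSE]
  st2 <- suppressWarnings(pcc_prune(m, pcc_threshold))
  tests <- kw_bh_test(m[, st2, drop = FALSE], labels, alpha)
  sig <- tests$feature[tests$significant]
  roc <- dplyr::bind_rows(lapply(sig, function(k) {
    dplyr::bind_cols(tibble::tibble(feature = k),
                     roc_analysis(m[, k], labels))
  }))
  structure(
    list(icc = st1$icc, retained_after_icc = st1$retained,
         retained_after_pcc = st2, tests = tests,
         significant_features = sig, roc = roc,
         thresholds = c(icc = icc_threshold, pcc = pcc_threshold,
                        alpha = alpha)),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n",
      " features in:        ", nrow(x$icc), "\n",
      " after ICC filter:   ", length(x$retained_after_icc), "\n",
      " after PCC pruning:  ", length(x$retained_after_pcc), "\n",
      " significant (BH):   ", length(x$significant_features), "\n", sep = "")
  invisible(x)
}

#' @describeIn select_features Per-feature table of the tested survivors:
#'   p-values, BH-adjusted p-values, and ROC columns for significant ones.
#' @param x a `selection_report`.
#' @param ... unused.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  out <- x$tests
  if (nrow(x$roc)) out <- dplyr::left_join(out, x$roc, by = "feature")
  dplyr::arrange(out, .data$p_adjusted)
}

#' @describeIn select_features One-row summary of the cascade.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$icc),
    n_after_icc = length(x$retained_after_icc),
    n_after_pcc = length(x$retained_after_pcc),
    n_significant = length(x$significant_features),
    min_p_adjusted = if (nrow(x$tests)) min(x$tests$p_adjusted) else NA_real_,
    max_auc = if (nrow(x$roc)) max(x$roc$auc) else NA_real_
  )
}

#' Write a selection report to disk
#'
#' Writes the report as JSON plus a CSV shaped like a significant-feature
#' table (feature, p, SE, CI, AUC, sensitivity, specificity).
#'
#' @param report a `selection_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_selection_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(retained_after_icc = report$retained_after_icc,
         retained_after_pcc = report$retained_after_pcc,
         significant_features = report$significant_features,
         thresholds = as.list(report$thresholds),
         tests = report$tests, roc = report$roc),
    file.path(dir, "selection_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(tidy(report), file.path(dir, "significant_features.csv"),
            row.names = FALSE)
  invisible(dir)
}
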