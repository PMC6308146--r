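# Feature-selection cascade: ICC, PCC pruning, KW + BH, ROC.

fake_features <- function(m, ids = NULL) {
  ids <- ids %||% sprintf("c%02d", seq_len(nrow(m)))
  dplyr::bind_cols(tibble::tibble(case_id = ids,
                                  label = rep(c("IFR", "NPD"),
                                              length.out = nrow(m))),
                   tibble::as_tibble(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("perfect agreement gives ICC 1 and retains everything", {
  set.seed(1)
  m <- matrix(rnorm(50 * 4), 50, dimnames = list(NULL, paste0("f", 1:4)))
  t1 <- fake_features(m)
  out <- icc_filter(t1, t1)
  expect_true(all(abs(out$icc$icc - 1) < 1e-12))
  expect_setequal(out$retained, paste0("f", 1:4))
})

test_that("independent-noise observer drives ICC toward zero", {
  set.seed(2)
  m1 <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, paste0("f", 1:6)))
  m2 <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, paste0("f", 1:6)))
  out <- icc_filter(fake_features(m1), fake_features(m2))
  expect_true(mean(abs(out$icc$icc) < 0.3) >= 0.95 ||
                all(abs(out$icc$icc) < 0.3))
  expect_length(out$retained, 0)
})

test_that("4-case, 2-rater hand example matches the mean-squares oracle", {
  r <- cbind(c(9, 6, 8, 7), c(8, 5, 9, 6))
  expect_equal(icc_single(r), oracle_icc21(r), tolerance = 1e-10)
  # and against pROC-independent published-style closed form by irr logic:
  # two-way random absolute agreement single measures
  expect_equal(icc_single(cbind(1:4, 1:4)), 1)
})

test_that("duplicated feature: exactly one of the pair is pruned", {
  set.seed(3)
  a <- rnorm(30)
  cc <- rnorm(30)
  m <- cbind(A = a, B = a, C = cc)
  kept <- suppressWarnings(pcc_prune(m))
  expect_true("C" %in% kept)
  expect_equal(sum(c("A", "B") %in% kept), 1)
  # tie on mean absolute correlation: the later key drops
  expect_true("A" %in% kept)
})

test_that("independent features survive pruning untouched", {
  set.seed(4)
  m <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, paste0("f", 1:5)))
  expect_setequal(pcc_prune(m), paste0("f", 1:5))
})

test_that("greedy pruning matches an independent re-implementation", {
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    base <- matrix(rnorm(30 * 4), 30, 4)
    mix <- matrix(rnorm(4 * 10, sd = 0.6), 4, 10) +
      matrix(rep(diag(4), length.out = 4 * 10), 4, 10)
    m <- base %*% mix + matrix(rnorm(30 * 10, sd = 0.3), 30, 10)
    colnames(m) <- sprintf("f%02d", 1:10)
    expect_identical(sort(pcc_prune(m)), sort(oracle_pcc_prune(m)))
  }
})

test_that("Kruskal-Wallis screen: null feature not significant, separated one is", {
  labels <- c(rep("IFR", 11), rep("NPD", 16))
  m <- cbind(null_f = rep(1, 27),
             sep_f = c(seq(10, 11, length.out = 11),
                       seq(20, 21, length.out = 16)))
  out <- suppressWarnings(kw_bh_test(m, labels))
  expect_false(out$significant[out$feature == "null_f"])
  expect_true(out$significant[out$feature == "sep_f"])
  # closed-form rank statistic for perfect separation at n = 11 + 16
  n <- 27; n1 <- 11; n2 <- 16
  r1 <- sum(1:11); r2 <- sum(12:27)
  H <- 12 / (n * (n + 1)) * (r1^2 / n1 + r2^2 / n2) - 3 * (n + 1)
  p_oracle <- pchisq(H, df = 1, lower.tail = FALSE)
  expect_equal(out$p[out$feature == "sep_f"], p_oracle, tolerance = 1e-12)
})

test_that("BH step-up reproduces the hand-evaluated adjustment", {
  p <- c(0.01, 0.02, 0.04, 0.80)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04 * 4 / 3, 0.80),
               tolerance = 1e-12)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  # adjustment never decreases p; significance set nests in raw set
  set.seed(8)
  pr <- runif(40)
  expect_true(all(p.adjust(pr, "BH") >= pr))
  expect_true(all(which(p.adjust(pr, "BH") < 0.05) %in% which(pr < 0.05)))
})

test_that("ROC on the 3-vs-3 toy set matches exhaustive pair counting", {
  vals <- c(1, 2, 3, 2.5, 4, 5)
  labs <- c("NPD", "NPD", "NPD", "IFR", "IFR", "IFR")
  out <- roc_analysis(vals, labs, positive = "IFR")
  expect_equal(out$auc, oracle_auc(c(2.5, 4, 5), c(1, 2, 3)))
  expect_equal(out$auc, 8 / 9, tolerance = 1e-12)
  # Hanley-McNeil SE at these counts
  a <- 8 / 9
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 2 * (q1 - a^2) + 2 * (q2 - a^2)) / 9)
  expect_equal(out$se, se, tolerance = 1e-12)
  expect_equal(out$ci_lo, max(0, a - 1.96 * se), tolerance = 1e-12)
})

test_that("perfectly separated feature: AUC 1, sens = spec = 1", {
  out <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                      c("NPD", "NPD", "NPD", "IFR", "IFR", "IFR"))
  expect_equal(out$auc, 1)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
})

test_that("AUC orientation keeps AUC at or above one half", {
  out <- roc_analysis(c(10, 11, 12, 1, 2, 3),
                      c("NPD", "NPD", "NPD", "IFR", "IFR", "IFR"))
  expect_equal(out$auc, 1)
  expect_equal(out$direction, "<=")
})

test_that("null labels give an AUC near one half at n = 200", {
  set.seed(9)
  vals <- rnorm(200)
  labs <- rep(c("IFR", "NPD"), 100)
  out <- roc_analysis(vals, labs)
  expect_gte(out$auc, 0.40)
  expect_lte(out$auc, 0.60)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  vals <- rnorm(40)
  labs <- rep(c("IFR", "NPD"), 20)
  ours <- roc_analysis(vals, labs, positive = "IFR")
  ref <- pROC::roc(response = labs, predictor = vals, levels = c("NPD", "IFR"),
                   direction = if (ours$direction == ">=") "<" else ">",
                   quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("degenerate constant feature flags AUC 0.5", {
  out <- roc_analysis(rep(2, 8), rep(c("IFR", "NPD"), 4))
  expect_equal(out$auc, 0.5)
  expect_true(out$flagged)
})

test_that("the cascade keeps its stages nested and ordered", {
  set.seed(11)
  n <- 20
  labels <- rep(c("IFR", "NPD"), each = 10)
  sig <- c(rnorm(10, 0), rnorm(10, 3))
  m1 <- cbind(sig = sig, sig_dup = sig + rnorm(n, sd = 0.05),
              noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(m1) <- c("sig", "sig_dup", "noise1", "noise2")
  obs1 <- fake_features(m1)
  obs1$label <- labels
  m2 <- m1 + matrix(rnorm(length(m1), sd = 0.05), nrow(m1))
  obs2 <- obs1
  obs2[, colnames(m1)] <- tibble::as_tibble(m2)
  rep_ <- select_features(obs1, obs2)
  expect_true(all(rep_$retained_after_pcc %in% rep_$retained_after_icc))
  expect_true(all(rep_$significant_features %in% rep_$retained_after_pcc))
  expect_true(any(c("sig", "sig_dup") %in% rep_$significant_features))
  expect_true(all(rep_$tests$p_adjusted >= rep_$tests$p))
  td <- tidy(rep_)
  expect_true(all(c("p", "p_adjusted", "significant") %in% names(td)))
  g <- glance(rep_)
  expect_equal(g$n_features, 4)
})
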