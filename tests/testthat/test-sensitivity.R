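test_that("Fisher discriminant with isotropic covariance is the mean-difference axis", {
  xc <- isotropic_class(c(0, 0))
  xt <- isotropic_class(c(0, -1))
  m <- fit_lda(xc, xt, features = c("f1", "f2"))
  expect_equal(unname(m$weights), c(0, 1), tolerance = 1e-12)
  # treated projects low, threshold at the midpoint
  expect_lte(m$projected_mean_treated, m$projected_mean_control)
  expect_equal(m$offset, -0.5)
  expect_error(fit_lda(xc[1, , drop = FALSE], xt, features = c("f1", "f2")),
               "at least 2")
})

test_that("identical class means leave the classes unseparated (AUC ~ 0.5)", {
  set.seed(71)
  rc <- sample_records(400)
  rt <- sample_records(400)
  cls <- classify_pair(rc, rt)
  expect_lt(abs(cls$auc - 0.5), 0.08)
})

test_that("a constant feature is handled by ridge regularization", {
  set.seed(5)
  xc <- cbind(rep(50, 30), rnorm(30, 5, 2))
  xt <- cbind(rep(50, 30), rnorm(30, -3, 2))
  expect_warning(m <- fit_lda(xc, xt, features = c("mass", "mar")),
                 "ridge")
  # discriminant collapses onto the varying (MAR) coordinate
  expect_gt(abs(m$weights[2]), 0.99)
})

test_that("pair-counting AUC matches brute force and handles ties", {
  expect_equal(roc_auc(c(1, 2), c(3, 4))$auc, 1)
  expect_equal(roc_auc(c(1, 3), c(2, 4))$auc, 0.75)  # 3 of 4 ordered pairs
  x <- c(1, 2, 2, 5)
  expect_equal(roc_auc(x, x)$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("trapezoidal area under the emitted ROC equals the pair-count AUC", {
  set.seed(31)
  for (i in 1:20) {
    sc <- round(rnorm(sample(2:40, 1)), sample(0:2, 1))  # force some ties
    st <- round(rnorm(sample(2:40, 1), 0.5), sample(0:2, 1))
    r <- roc_auc(sc, st)
    trapz <- sum(diff(r$roc$fpr) * (utils::head(r$roc$tpr, -1) +
                                      utils::tail(r$roc$tpr, -1)) / 2)
    expect_equal(trapz, r$auc, tolerance = 1e-12)
    expect_true(!is.unsorted(r$roc$fpr) && !is.unsorted(r$roc$tpr))
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(80)
  st <- rnorm(60, 0.8)
  ours <- roc_auc(sc, st)$auc
  ref <- pROC::auc(pROC::roc(
    response = rep(c(0, 1), c(80, 60)), predictor = c(sc, st),
    direction = "<", quiet = TRUE))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("LDA direction agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  rc <- sample_records(100)
  rt <- sample_records(100, mar_mean = 1)
  m <- fit_lda(rc, rt)
  d <- data.frame(grp = rep(c("c", "t"), each = 100),
                  mass = c(rc$mean_mass_pg, rt$mean_mass_pg),
                  mar = c(rc$mar_pg_per_h, rt$mar_pg_per_h))
  ref <- MASS::lda(grp ~ mass + mar, data = d)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  ours <- unname(m$weights)
  expect_equal(abs(sum(ours * ref)), 1, tolerance = 1e-8)  # colinear axes
})

test_that("classification is invariant to affine maps of the feature plane", {
  set.seed(19)
  rc <- as.matrix(sample_records(120)[, c("mean_mass_pg", "mar_pg_per_h")])
  rt <- as.matrix(sample_records(120, drug_effect = 3)[,
                    c("mean_mass_pg", "mar_pg_per_h")])
  a1 <- classify_pair(rc, rt, features = colnames(rc))$auc
  A <- matrix(c(2, 0.5, -1, 3), 2)
  b <- c(100, -7)
  map <- function(x) sweep(x %*% t(A), 2, -b)
  a2 <- classify_pair(map(rc), map(rt), features = colnames(rc))$auc
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("Welch's test reproduces hand-computed statistics", {
  w <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$welch_df, 4, tolerance = 1e-12)
  expect_equal(w$p_raw, 2 * stats::pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(w$p_raw, 0.0213, tolerance = 2e-3)

  w2 <- welch_test(1:4, c(2, 4, 6, 8))
  expect_equal(w2$t_statistic, -1.732, tolerance = 1e-3)
  expect_equal(w2$welch_df, 4.41, tolerance = 1e-2)

  x <- c(1.5, 2.5, 9)
  expect_equal(welch_test(x, x)$t_statistic, 0)
  expect_equal(welch_test(x, x)$p_raw, 1)
})

test_that("Welch's test is antisymmetric in its arguments", {
  set.seed(12)
  x <- rnorm(20)
  y <- rnorm(25, 0.4)
  a <- welch_test(x, y)
  b <- welch_test(y, x)
  expect_equal(a$t_statistic, -b$t_statistic, tolerance = 1e-12)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  expect_equal(a$welch_df, b$welch_df, tolerance = 1e-12)
})

test_that("zero-variance degenerate inputs follow the documented conventions", {
  expect_equal(welch_test(c(2, 2, 2), c(2, 2))$p_raw, 1)
  expect_error(welch_test(c(2, 2), c(3, 3)), "zero variance")
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("Bonferroni correction caps at 1 and enforces the family size", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.001, 0.2), 5), c(0.005, 1))
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
  expect_error(bonferroni(0.1, 0), "'m'")
  expect_error(bonferroni(1.2, 2), "p-values")
})

test_that("sensitivity calls separate strong effects from null effects", {
  set.seed(42)
  rc <- sample_records(60)
  rt_sens <- sample_records(60, drug_effect = 8)
  call_s <- call_sensitivity(rc, rt_sens, alpha = 0.05, m = 9,
                             sample_id = "P1", condition = "combo")
  expect_equal(call_s$call, "sensitive")
  expect_lt(call_s$p_corrected, 0.05)
  expect_gt(call_s$auc, 0.9)

  rt_res <- sample_records(60, drug_effect = 0)
  call_r <- call_sensitivity(rc, rt_res, alpha = 0.05, m = 9)
  expect_equal(call_r$call, "resistant")

  expect_error(call_sensitivity(rc, NULL), "missing treated")
  expect_error(call_sensitivity(NULL, rt_res), "missing control")
})

test_that("type-I error of the raw Welch test is calibrated at the null", {
  set.seed(777)
  n_sims <- 1000
  hits <- 0L
  for (i in seq_len(n_sims)) {
    x <- sample_records(60)$mar_per_mass_per_h
    y <- sample_records(60)$mar_per_mass_per_h
    if (welch_test(x, y)$p_raw < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / n_sims - 0.05), 0.02)
})

test_that("median AUC is non-decreasing in the drug effect (dose response)", {
  effects <- c(0, 1, 2, 3, 5, 8)
  set.seed(314)
  med <- vapply(effects, function(e) {
    aucs <- vapply(1:15, function(i) {
      classify_pair(sample_records(60), sample_records(60, drug_effect = e))$auc
    }, numeric(1))
    stats::median(aucs)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_lt(abs(med[1] - 0.5), 0.1)
  expect_gt(med[6], 0.95)
})
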