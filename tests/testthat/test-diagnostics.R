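test_that("ROC handles perfect separation and degenerate score sets", {
  roc <- suppressWarnings(
    roc_curve(c(1, 2, 3, 4), c("patient", "patient", "control", "control"),
              "lower_is_positive"))
  i <- which(roc$sens == 1 & roc$spec == 1)
  expect_length(i, 1)
  expect_equal(roc$thresholds[i], 2.5)
  expect_equal(roc$auc, 1)
  expect_equal(roc$cutoff, 2.5)
  expect_equal(c(roc$cutoff_sens, roc$cutoff_spec), c(1, 1))

  tied <- suppressWarnings(
    roc_curve(rep(5, 6), rep(c("patient", "control"), 3)))
  expect_setequal(paste(tied$sens, tied$spec), c("0 1", "1 0"))

  expect_error(roc_curve(1:3, rep("patient", 3)), "both classes")
})

test_that("ROC sensitivities/specificities match exhaustive confusion counting", {
  set.seed(17)
  for (i in 1:20) {
    n_p <- sample(2:12, 1); n_c <- sample(2:12, 1)
    scores <- c(round(rnorm(n_p, 40, 25)), round(rnorm(n_c, 70, 25)))
    labels <- c(rep("patient", n_p), rep("control", n_c))
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    roc <- suppressWarnings(roc_curve(scores, labels, dir))
    pts <- brute_roc_points(scores, labels, dir)
    expect_equal(roc$thresholds, pts[, "threshold"])
    expect_equal(roc$sens, pts[, "sens"])
    expect_equal(roc$spec, pts[, "spec"])
  }
})

test_that("trapezoid AUC equals the Mann-Whitney pair statistic and flips with direction", {
  expect_equal(auc(c(1, 3, 2, 4), c("patient", "patient", "control", "control"),
                   "lower_is_positive"), 0.75)
  set.seed(23)
  for (i in 1:60) {
    n_p <- sample(2:10, 1); n_c <- sample(2:10, 1)
    scores <- c(sample(1:8, n_p, TRUE), sample(1:8, n_c, TRUE)) # many ties
    labels <- c(rep("patient", n_p), rep("healthy", n_c))
    a_lo <- auc(scores, labels, "lower_is_positive")
    expect_equal(a_lo, brute_pair_auc(scores, labels, "lower_is_positive"))
    expect_equal(auc(scores, labels, "higher_is_positive"), 1 - a_lo)
  }
})

test_that("optimal cutoff minimizes squared distance to the corner with the stated tie-breaks", {
  set.seed(29)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    n_p <- sample(2:(n - 2), 1)
    scores <- sample(1:10, n, TRUE)
    labels <- c(rep("patient", n_p), rep("control", n - n_p))
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    roc <- suppressWarnings(roc_curve(scores, labels, dir))
    expect_equal(optimal_cutoff(roc), unname(brute_cutoff(scores, labels, dir)))
  }

  # single misclassified positive at the best threshold
  roc <- suppressWarnings(roc_curve(
    c(1, 2, 10, 5, 6, 7), rep(c("patient", "control"), each = 3),
    "lower_is_positive"))
  expect_equal(roc$cutoff, 3.5)
  expect_equal(roc$cutoff_sens, 2 / 3)
  expect_equal(roc$cutoff_spec, 1)

  # equal-distance tie resolved toward higher sensitivity:
  # patients {1, 3}, controls {2, 4} -> threshold 1.5 gives (sens, spec) =
  # (0.5, 1) and threshold 3.5 gives (1, 0.5), both d2 = 0.25; the sens=1
  # candidate (3.5) must win
  roc <- suppressWarnings(roc_curve(c(1, 3, 2, 4),
                                    c("patient", "patient", "control", "control"),
                                    "lower_is_positive"))
  expect_equal(roc$cutoff, 3.5)
  expect_equal(roc$cutoff_sens, 1)
  expect_equal(roc$cutoff_spec, 0.5)
})

test_that("confusion-count sensitivity/specificity are reported to 2 dp", {
  expect_equal(as.vector(sens_spec_from_counts(14, 1, 15, 3)), c(0.93, 0.83))
  expect_equal(as.vector(sens_spec_from_counts(13, 2, 16, 2)), c(0.87, 0.89))
  expect_equal(as.vector(sens_spec_from_counts(9, 0, 12, 0)), c(1, 1))
  expect_equal(unname(attr(sens_spec_from_counts(14, 1, 15, 3), "raw")),
               c(14 / 15, 15 / 18))
  expect_error(sens_spec_from_counts(0, 0, 5, 1), "patient class")
  expect_error(sens_spec_from_counts(1.5, 1, 5, 1), "integers")
})

test_that("DeLong CI agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (i in 1:10) {
    scores <- c(rnorm(12, 35, 20), rnorm(15, 70, 20))
    labels <- c(rep("patient", 12), rep("control", 15))
    a <- auc(scores, labels, "lower_is_positive")
    if (a %in% c(0, 1)) next # degenerate variance handled separately
    ci <- auc_ci(scores, labels, "lower_is_positive", method = "delong")
    ref <- pROC::roc(response = labels, predictor = scores,
                     levels = c("control", "patient"), direction = ">",
                     quiet = TRUE)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(ci[1], max(0, ref_ci[1]), tolerance = 1e-8)
    expect_equal(ci[2], min(1, ref_ci[3]), tolerance = 1e-8)
  }
})

test_that("AUC confidence intervals behave: contain the point, shrink with separation, reproduce under a seed", {
  scores <- c(rnorm(15, 40, 15), rnorm(18, 70, 15))
  labels <- c(rep("patient", 15), rep("control", 18))
  set.seed(41)

  b1 <- auc_ci(scores, labels, method = "bootstrap", seed = 99)
  b2 <- auc_ci(scores, labels, method = "bootstrap", seed = 99)
  expect_identical(b1, b2)
  expect_error(auc_ci(scores, labels, method = "bootstrap"), "seed")

  a <- auc(scores, labels)
  d <- auc_ci(scores, labels, method = "delong")
  expect_true(d[1] <= a && a <= d[2])
  expect_true(b1[1] <= a && a <= b1[2])

  # Monte Carlo: wider class separation -> narrower DeLong CI on average
  width_at <- function(gap) {
    mean(vapply(1:30, function(r) {
      set.seed(5000 + r)
      sc <- c(rnorm(15, 50 - gap / 2, 10), rnorm(18, 50 + gap / 2, 10))
      ci <- suppressWarnings(auc_ci(sc, labels, method = "delong"))
      ci[2] - ci[1]
    }, numeric(1)))
  }
  expect_lt(width_at(30), width_at(5))
})

test_that("spearman correlation matches hand ranks and the stats oracle", {
  expect_equal(spearman_cor(1:6, (1:6)^3)[["rho"]], 1)
  expect_equal(spearman_cor(1:6, -(1:6))[["rho"]], -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))[["rho"]], 0.8)

  set.seed(43)
  x <- rnorm(20); y <- x + rnorm(20)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got[["rho"]], unname(ref$estimate))

  expect_error(spearman_cor(rep(1, 5), 1:5), "rank variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("ICC matches a from-scratch ANOVA and is 1 for consistent columns", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)
  r <- icc(m)
  expect_equal(r$icc, anova_icc_oracle(m))
  expect_equal(r$icc, 1) # second column is first + 1: perfectly consistent

  set.seed(47)
  noisy <- matrix(rnorm(60, rep(rnorm(20, 0, 3), 3)), ncol = 3)
  r2 <- icc(noisy)
  expect_equal(r2$icc, anova_icc_oracle(noisy), tolerance = 1e-12)
  expect_true(r2$ci[1] <= r2$icc && r2$icc <= r2$ci[2])
  expect_lte(r2$icc, 1)

  # consistency ICC is invariant to adding a constant to one column
  shifted <- noisy
  shifted[, 2] <- shifted[, 2] + 11
  expect_equal(icc(shifted)$icc, r2$icc, tolerance = 1e-12)
  # and to relabeling subjects
  expect_equal(icc(noisy[sample(20), ])$icc, r2$icc, tolerance = 1e-12)

  ident <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  expect_equal(icc(ident)$icc, 1)

  expect_error(icc(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(icc(matrix(5, 3, 2)), "zero total variance")

  r3 <- icc(noisy, model = "agreement")
  expect_match(r3$model, "agreement")
  expect_true(r3$ci[1] <= r3$icc && r3$icc <= r3$ci[2])
})

test_that("two-sample t test matches the pooled-variance formula and is symmetric", {
  got <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6), "student")
  expect_equal(abs(got[["t"]]), 3.674235, tolerance = 1e-6)

  a <- rnorm(10); b <- rnorm(12, 1)
  s1 <- two_sample_ttest(a, b)
  s2 <- two_sample_ttest(b, a)
  expect_equal(s1[["t"]], -s2[["t"]])
  expect_equal(s1[["p"]], s2[["p"]])

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same[["t"]], 0)
  expect_equal(same[["p"]], 1)

  w <- two_sample_ttest(a, b, "welch")
  expect_equal(w[["p"]], stats::t.test(a, b)$p.value)

  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "zero variance")
})
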