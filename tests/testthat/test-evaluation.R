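test_that("Mann-Whitney test matches the enumeration and tie conventions", {
  mw <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.1)  # 2 of the C(6,3)=20 labelings are as extreme
  expect_equal(mw$statistic, 0)
  expect_equal(mw$method, "exact")

  expect_equal(mann_whitney_test(c(1, 2), c(1, 2))$statistic, 2)
  expect_equal(mann_whitney_test(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(mann_whitney_test(numeric(0), 1), "non-empty")

  # exact/approximate boundary: pooled size 12 without ties is exact,
  # 13 is not, and any tie forces the approximation
  expect_equal(mann_whitney_test(1:6, 7:12)$method, "exact")
  expect_equal(mann_whitney_test(1:6, 7:13)$method, "normal_approx")
  expect_equal(mann_whitney_test(c(1, 2, 2), c(3, 4, 5))$method,
               "normal_approx")
})

test_that("AUC equals brute-force pair counting and U/(n1 n2)", {
  r <- roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(2, 2), c(TRUE, FALSE))$auc, 0.5)  # tie worth 1/2

  for (seed in 1:20) {
    set.seed(seed)
    n1 <- sample(2:10, 1)
    n0 <- sample(2:10, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), 1)  # rounding makes ties
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pair_count(scores, labels))
    u <- mann_whitney_test(scores[labels], scores[!labels])$statistic
    expect_equal(r$auc, u / (n1 * n0))
    # cross-implementation check against pROC
    expect_equal(r$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE))))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Youden threshold selection breaks ties toward specificity", {
  # cases 10, 20; controls 1, 2: several thresholds reach sens+spec = 2
  r <- roc_auc(c(10, 20, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$best_threshold, 6)  # midpoint of 2 and 10
  curve <- r$curve
  youden <- curve$sensitivity + curve$specificity
  best_rows <- which(abs(youden - max(youden)) < 1e-12)
  chosen <- which(curve$threshold == r$best_threshold)
  expect_equal(curve$specificity[chosen],
               max(curve$specificity[best_rows]))
  # ROC points are monotone along the threshold grid
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_true(all(diff(curve$specificity) >= 0))
})

test_that("confusion metrics follow the printed definitions", {
  # counts chosen to give sens 80%, spec 90%, accuracy 85%, LR+ 8
  scores <- c(rep(50, 8), rep(10, 2), rep(10, 9), 50)
  labels <- c(rep(TRUE, 10), rep(FALSE, 10))
  cmx <- confusion_metrics(scores, labels, 38.5)
  expect_equal(c(cmx$tp, cmx$fn, cmx$tn, cmx$fp), c(8, 2, 9, 1))
  expect_equal(cmx$sensitivity[1], 0.8)
  expect_equal(cmx$specificity[1], 0.9)
  expect_equal(cmx$accuracy[1], 0.85)
  expect_equal(cmx$lr_positive, 8)

  # Wilson interval against the closed form
  z <- qnorm(0.975)
  p <- 0.8; n <- 10
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(cmx$sensitivity[2:3], c(center - half, center + half),
               tolerance = 1e-10)

  perfect <- confusion_metrics(c(50, 60, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                               38.5)
  expect_equal(perfect$sensitivity[1], 1)
  expect_equal(perfect$specificity[1], 1)
  expect_false(perfect$lr_defined)

  # the positive call is strict: a score exactly at threshold is negative
  edge <- confusion_metrics(c(38.5, 38.6), c(TRUE, TRUE), 38.5)
  expect_equal(c(edge$tp, edge$fn), c(1, 1))
})

test_that("confusion metrics are invariant under joint monotone transforms", {
  set.seed(42)
  scores <- rlnorm(40, 3, 1)
  labels <- rbinom(40, 1, 0.5) == 1
  labels[1:2] <- c(TRUE, FALSE)
  thr <- median(scores)
  a <- confusion_metrics(scores, labels, thr)
  b <- confusion_metrics(log(scores), labels, log(thr))
  expect_equal(c(a$tp, a$fn, a$tn, a$fp), c(b$tp, b$fn, b$tn, b$fp))
  expect_equal(a$sensitivity, b$sensitivity)
})

test_that("Spearman concordance matches the rank computation", {
  expect_equal(spearman_concordance(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_concordance(1:8, -(1:8))$rho, -1)
  expect_equal(spearman_concordance(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_concordance(1:4, 1:5), "equal length")
  expect_error(spearman_concordance(1:2, 1:2), "at least 3")
})

test_that("cohort evaluation pools controls and honours threshold modes", {
  df <- data.frame(
    cm = c(rep(300, 10), rep(0, 5), rep(2, 5)),
    group_label = c(rep("cancer", 10), rep("benign", 5), rep("normal", 5)))
  ev <- evaluate_cohort(df, threshold = 38.5)
  expect_equal(ev$roc$auc, 1)
  expect_equal(ev$confusion$accuracy[1], 1)
  expect_equal(ev$descriptives$n, c(10, 10))  # benign + normal pooled

  ev2 <- evaluate_cohort(df, threshold = "derive")
  expect_true(ev2$threshold_derived)
  expect_equal(ev2$threshold, ev2$roc$best_threshold)
  curve <- ev2$roc$curve
  best_y <- with(curve, max(sensitivity + specificity))
  at <- curve$threshold == ev2$threshold
  expect_equal(curve$sensitivity[at] + curve$specificity[at], best_y)

  # default threshold comes from the locked assay constant
  expect_equal(evaluate_cohort(df)$threshold, 38.5)
})

test_that("permuted labels give null AUC near one half", {
  set.seed(2024)
  cm <- rlnorm(66, 4, 1.5)
  aucs <- replicate(300, {
    lab <- sample(c(rep(TRUE, 40), rep(FALSE, 26)))
    roc_auc(cm, lab)$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("trajectories are anchored at baseline and labelled by interval", {
  tr <- summarize_trajectory(data.frame(draw_day = c(0, 21, 42),
                                        cm = c(400, 100, 50)))
  expect_equal(tr$delta_baseline, c(0, -300, -350))
  expect_equal(tr$direction, c("baseline", "fall", "fall"))

  flat <- summarize_trajectory(data.frame(draw_day = c(0, 21),
                                          cm = c(60, 60)))
  expect_equal(flat$direction[2], "flat")
  tol <- summarize_trajectory(data.frame(draw_day = c(0, 21),
                                         cm = c(10, 10.5)), tolerance = 1)
  expect_equal(tol$direction[2], "flat")

  # unsorted input is ordered by draw day; baseline is the earliest draw
  mixed <- summarize_trajectory(data.frame(draw_day = c(42, 0, 21),
                                           cm = c(200, 100, 20)))
  expect_equal(mixed$draw_day, c(0, 21, 42))
  expect_equal(attr(mixed, "baseline_cm"), 100)
  expect_equal(mixed$direction, c("baseline", "fall", "rise"))

  expect_error(summarize_trajectory(data.frame(draw_day = 0, cm = 5)),
               "at least two")
})
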