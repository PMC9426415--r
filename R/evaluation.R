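#' Mann-Whitney rank-sum test
#'
#' Two-sided nonparametric comparison of two groups of CM values. The U
#' statistic is computed with average ranks for ties. The p-value is exact
#' (by enumeration of the null rank distribution) when the pooled size is
#' at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used. The p-value
#' machinery is delegated to [stats::wilcox.test()] under exactly that
#' switch.
#'
#' @param group_a,group_b Numeric vectors, each with at least one value.
#' @return List with `statistic` (U for `group_a`), `p_value`, `n_a`,
#'   `n_b`, and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1, exact
#' @export
mann_whitney_test <- function(group_a, group_b) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (!length(group_a) || !length(group_b) ||
      anyNA(group_a) || anyNA(group_b)) {
    stop("both groups must be non-empty with no missing values",
         call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  exact <- (n_a + n_b) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  p <- unname(wt$p.value)
  if (is.nan(p)) p <- 1  # fully tied data: no evidence of separation
  list(statistic = u, p_value = p, n_a = n_a, n_b = n_b,
       method = if (exact) "exact" else "normal_approx")
}

#' ROC analysis with Youden threshold selection
#'
#' Builds the full ROC curve of a score against a binary outcome.
#' Candidate thresholds are the midpoints between consecutive distinct
#' pooled scores, extended by -Inf and +Inf; a sample is called positive
#' when its score is strictly above the threshold. The AUC is computed by
#' pair counting with ties worth one half (identical to the Mann-Whitney
#' U divided by `n_case * n_control`); its 95% CI uses DeLong's method
#' (via [pROC::ci.auc()]). The reported `best_threshold` maximizes
#' sensitivity + specificity (Youden), with ties broken toward higher
#' specificity.
#'
#' @param scores Numeric score vector (e.g. CM).
#' @param labels Logical (or coercible) vector, `TRUE` = case; both
#'   classes must be present.
#' @return Object of class `cm_roc`: list with `auc`, `auc_ci`
#'   (length-2 lower/upper), `curve` (data frame `threshold`,
#'   `sensitivity`, `specificity`), `best_threshold`, `n_case`,
#'   `n_control`.
#' @examples
#' roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  case_scores <- scores[labels]
  ctrl_scores <- scores[!labels]
  sens <- vapply(thr, function(t) mean(case_scores > t), numeric(1))
  spec <- vapply(thr, function(t) mean(ctrl_scores <= t), numeric(1))
  youden <- sens + spec
  best <- which(youden >= max(youden) - 1e-12)
  best <- best[order(spec[best], thr[best], decreasing = TRUE)][1]

  ci <- tryCatch({
    roc_obj <- pROC::roc(response = factor(ifelse(labels, "case", "control"),
                                           levels = c("control", "case")),
                         predictor = scores, direction = "<",
                         quiet = TRUE)
    suppressWarnings(
      as.numeric(pROC::ci.auc(roc_obj, method = "delong"))[c(1, 3)]
    )
  }, error = function(e) c(NA_real_, NA_real_))

  structure(list(auc = auc, auc_ci = ci,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 best_threshold = thr[best],
                 n_case = n1, n_control = n0),
            class = "cm_roc")
}

#' Wilson score confidence interval for a proportion
#'
#' Thin wrapper over [stats::prop.test()] without continuity correction,
#' which inverts the score test (the Wilson interval).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
  ci <- suppressWarnings(
    stats::prop.test(x, n, correct = FALSE, conf.level = conf_level)
  )$conf.int
  c(x / n, ci[1], ci[2])
}

#' Confusion-matrix diagnostic metrics at a CM threshold
#'
#' Calls a sample positive when its score is strictly greater than the
#' threshold, then reports sensitivity, specificity and classification
#' accuracy `(TP + TN) / (TP + TN + FP + FN)` with Wilson 95% intervals,
#' and the positive likelihood ratio `sensitivity / (1 - specificity)`
#' (flagged undefined when specificity is 1).
#'
#' @param scores Numeric score vector.
#' @param labels Logical vector, `TRUE` = case.
#' @param threshold Finite decision threshold (CM units).
#' @return Object of class `cm_confusion`: list with counts `tp`, `fn`,
#'   `tn`, `fp`, the `threshold`, and `sensitivity`, `specificity`,
#'   `accuracy` (each `c(estimate, lower, upper)`), `lr_positive`,
#'   `lr_defined`.
#' @examples
#' confusion_metrics(c(50, 40, 40, 10), c(TRUE, TRUE, FALSE, FALSE), 38.5)
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  pos <- scores > threshold
  tp <- sum(pos & labels)
  fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels)
  fp <- sum(pos & !labels)
  sens <- wilson_ci(tp, tp + fn)
  spec <- wilson_ci(tn, tn + fp)
  acc <- wilson_ci(tp + tn, tp + tn + fp + fn)
  lr_defined <- spec[1] < 1
  lr <- if (isTRUE(lr_defined)) sens[1] / (1 - spec[1]) else NA_real_
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp, threshold = threshold,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 lr_positive = lr, lr_defined = isTRUE(lr_defined)),
            class = "cm_confusion")
}

#' Spearman rank concordance
#'
#' Rank correlation between paired score vectors (e.g. duplicate user
#' measurements, or two assay platforms on the same samples), with
#' average ranks for ties and the t-distribution approximation for the
#' two-sided p-value (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors of equal length, n >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @examples
#' spearman_concordance(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman_concordance <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must be paired vectors of equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) {
    stop("at least 3 complete pairs are required", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value),
       n = length(x))
}

#' Cohort-level diagnostic evaluation
#'
#' The full group-comparison / ROC / confusion analysis of a scored
#' cohort. Benign and normal labels are pooled into one control class and
#' compared against cancer. The classification threshold is either
#' supplied (a locked, training-derived value, default 38.5 CM units) or
#' derived from this cohort by Youden selection when
#' `threshold = "derive"` (training mode).
#'
#' @param scores A `cm_scores` object from [score_batch()], or a data
#'   frame with columns `cm` and `group_label` (invalid samples, `cm`
#'   `NA`, are dropped with a message).
#' @param threshold Numeric CM threshold, or `"derive"`.
#' @param config An [assay_config()] (supplies the default threshold).
#' @return Object of class `cm_evaluation`: list with `descriptives`
#'   (per-class n/min/quartiles/max/mean with 95% CI of the mean),
#'   `mann_whitney`, `roc` (`cm_roc`), `threshold`,
#'   `threshold_derived` flag, and `confusion` (`cm_confusion`).
#' @export
evaluate_cohort <- function(scores, threshold = NULL,
                            config = assay_config()) {
  df <- if (inherits(scores, "cm_scores")) scores$samples else scores
  stopifnot(is.data.frame(df), all(c("cm", "group_label") %in% names(df)))
  if (any(is.na(df$cm))) {
    message("dropping ", sum(is.na(df$cm)), " invalid sample(s) without CM")
    df <- df[!is.na(df$cm), , drop = FALSE]
  }
  if (any(df$group_label == "unknown")) {
    stop("cohort evaluation requires labelled samples", call. = FALSE)
  }
  is_case <- df$group_label == "cancer"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("at least 2 samples per class are required", call. = FALSE)
  }
  cm_case <- df$cm[is_case]
  cm_ctrl <- df$cm[!is_case]

  mw <- mann_whitney_test(cm_case, cm_ctrl)
  roc <- roc_auc(df$cm, is_case)
  derived <- identical(threshold, "derive")
  thr <- if (derived) {
    roc$best_threshold
  } else if (is.null(threshold)) {
    config$constants$cm_threshold
  } else {
    as.numeric(threshold)
  }
  conf <- confusion_metrics(df$cm, is_case, thr)

  desc <- do.call(rbind, lapply(list(control = cm_ctrl, cancer = cm_case),
                                function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    ci <- if (length(v) > 1 && stats::sd(v) > 0) {
      as.numeric(stats::t.test(v)$conf.int)
    } else {
      c(mean(v), mean(v))
    }
    data.frame(n = length(v), min = min(v), q25 = q[1], median = q[2],
               q75 = q[3], max = max(v), mean = mean(v),
               mean_ci_lower = ci[1], mean_ci_upper = ci[2])
  }))
  desc <- cbind(class = rownames(desc), desc)
  rownames(desc) <- NULL

  structure(list(descriptives = desc, mann_whitney = mw, roc = roc,
                 threshold = thr, threshold_derived = derived,
                 confusion = conf),
            class = "cm_evaluation")
}

#' Per-gene contribution table
#'
#' Long table of per-sample, per-gene methylation M backing stacked-bar
#' views of how each gene contributes to a sample's CM, ordered by
#' descending sample CM within class.
#'
#' @param scores A `cm_scores` object.
#' @return Data frame `sample_id`, `group_label`, `gene`, `m`, `cm`.
#' @export
gene_contributions <- function(scores) {
  stopifnot(inherits(scores, "cm_scores"))
  g <- merge(scores$genes[, c("sample_id", "gene", "m")],
             scores$samples[, c("sample_id", "group_label", "cm")],
             by = "sample_id", sort = FALSE)
  g <- g[!is.na(g$cm), , drop = FALSE]
  g <- g[order(g$group_label, -g$cm, g$sample_id, g$gene), ,
         drop = FALSE]
  rownames(g) <- NULL
  g[, c("sample_id", "group_label", "gene", "m", "cm")]
}

#' @export
print.cm_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_case, x$n_control))
  cat(sprintf("Best (Youden) threshold: %g\n", x$best_threshold))
  invisible(x)
}

#' @export
print.cm_confusion <- function(x, ...) {
  cat(sprintf("Threshold > %g: TP %d, FN %d, TN %d, FP %d\n",
              x$threshold, x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("Sensitivity %.1f%% (%.1f-%.1f), Specificity %.1f%% (%.1f-%.1f)\n",
              100 * x$sensitivity[1], 100 * x$sensitivity[2],
              100 * x$sensitivity[3], 100 * x$specificity[1],
              100 * x$specificity[2], 100 * x$specificity[3]))
  cat(sprintf("Accuracy %.1f%% (%.1f-%.1f), LR+ %s\n",
              100 * x$accuracy[1], 100 * x$accuracy[2],
              100 * x$accuracy[3],
              if (x$lr_defined) sprintf("%.1f", x$lr_positive) else "undefined"))
  invisible(x)
}

#' @export
print.cm_evaluation <- function(x, ...) {
  cat("Cohort evaluation\n-----------------\n")
  print(x$descriptives, row.names = FALSE)
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%s)\n",
              x$mann_whitney$statistic, x$mann_whitney$p_value,
              x$mann_whitney$method))
  print(x$roc)
  cat(if (x$threshold_derived) "Derived (Youden) threshold used\n" else
        "Locked threshold used\n")
  print(x$confusion)
  invisible(x)
}
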