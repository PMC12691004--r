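# Classification metrics, fold confidence intervals, effect sizes, decision
# curves, and the two summary-statistics tests used for cohort tables
# (Pearson chi-square on counts, pooled-variance t from mean/SD/n).

#' Confusion-matrix classification metrics
#'
#' Accuracy, recall (= sensitivity), specificity, PPV (= precision), NPV and
#' F1 from binary predictions. Degenerate denominators follow fixed
#' conventions: PPV = 0 when TP+FP = 0, NPV = 0 when TN+FN = 0, F1 = 0 when
#' PPV+recall = 0.
#'
#' @param y_true,y_pred equal-length binary (0/1 or logical) vectors.
#' @return Named list with TP, FP, TN, FN and the six metrics.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("no samples")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y <- as.logical(y_true); p <- as.logical(y_pred)
  tp <- sum(y & p); fp <- sum(!y & p); tn <- sum(!y & !p); fn <- sum(y & !p)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  f1 <- if (ppv + rec > 0) 2 * ppv * rec / (ppv + rec) else 0
  list(TP = tp, FP = fp, TN = tn, FN = fn, accuracy = acc, recall = rec,
       specificity = spec, ppv = ppv, npv = npv, f1 = f1)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random positive scores above a random negative, ties
#' counting one half.
#'
#' @param y_true binary labels, both classes present.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, scores) {
  y <- as.logical(y_true)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("undefined AUC: one class absent")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' @param y_true binary labels.
#' @param probs predicted probabilities.
#' @return Mean squared probability error.
#' @export
brier_score <- function(y_true, probs) mean((probs - as.numeric(y_true))^2)

#' t-based confidence interval over cross-validation folds
#'
#' mean +/- t_{1-(1-level)/2, k-1} * sd / sqrt(k) over the k fold values.
#'
#' @param values numeric vector of per-fold metric values (k >= 2).
#' @param level confidence level (default 0.95).
#' @return Named vector (mean, low, high).
#' @export
fold_ci <- function(values, level = 0.95) {
  k <- length(values)
  if (k < 2) stop("insufficient folds: need k >= 2")
  m <- mean(values)
  hw <- stats::qt(1 - (1 - level) / 2, df = k - 1) * stats::sd(values) / sqrt(k)
  c(mean = m, low = m - hw, high = m + hw)
}

#' Cohen's d effect size between two sets of fold metrics
#'
#' (mean_a - mean_b) / pooled SD. A zero pooled SD with unequal means returns
#' signed infinity with a warning.
#'
#' @param a,b numeric vectors.
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (is.na(sp2)) sp2 <- 0
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    warning("zero pooled SD with unequal means: returning signed infinity")
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

#' Decision curve analysis with Youden operating point
#'
#' Net benefit NB(t) = TP/n - (FP/n) t/(1-t) for the model, treat-all and
#' treat-none policies, plus the Youden-index threshold (argmax of
#' sensitivity + specificity - 1 over observed score cut-points) and the
#' clinical utility metrics (PPV, NPV, FPR, FNR) at both the default 0.5 and
#' Youden thresholds.
#'
#' @param y_true binary labels.
#' @param probs predicted probabilities in `[0, 1]`.
#' @param thresholds probability thresholds in (0, 1).
#' @return List with `curve` (data.frame threshold, nb_model, nb_all,
#'   nb_none), `youden` (threshold, J) and `utility` (metrics at 0.5 and at
#'   the Youden threshold).
#' @export
decision_curve <- function(y_true, probs,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0,1]")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("invalid threshold")
  y <- as.logical(y_true)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(t) {
    pred <- probs >= t
    sum(y & pred) / n - (sum(!y & pred) / n) * t / (1 - t)
  }, 0)
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  cuts <- sort(unique(probs))
  js <- vapply(cuts, function(t) {
    pred <- probs >= t
    sens <- if (sum(y)) sum(y & pred) / sum(y) else 0
    spec <- if (sum(!y)) sum(!y & !pred) / sum(!y) else 0
    sens + spec - 1
  }, 0)
  t_youden <- cuts[which.max(js)]
  util <- function(t) {
    cm <- confusion_metrics(y, probs >= t)
    c(threshold = t, ppv = cm$ppv, npv = cm$npv,
      fpr = if (cm$FP + cm$TN > 0) cm$FP / (cm$FP + cm$TN) else 0,
      fnr = if (cm$FN + cm$TP > 0) cm$FN / (cm$FN + cm$TP) else 0)
  }
  list(
    curve = data.frame(threshold = thresholds, nb_model = nb, nb_all = nb_all,
                       nb_none = 0),
    youden = c(threshold = t_youden, J = max(js)),
    utility = rbind(default = util(0.5), youden = util(t_youden))
  )
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' No continuity correction; df = k - 1.
#'
#' @param table 2 x k matrix of non-negative counts with positive marginals.
#' @return Named list (chi2, df, p).
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero marginal")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student t with pooled variance from (mean, SD, n) pairs; two-sided p with
#' df = n_a + n_b - 2.
#'
#' @param a,b lists or named vectors with `mean`, `sd`, `n` (n >= 2).
#' @return Named list (t, df, p).
#' @export
pooled_t_from_summary <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (a$n < 2 || b$n < 2) stop("need n >= 2 per group")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    t <- if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  } else {
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Published cohort table: clinical characteristic counts
#'
#' The 2 x k contingency tables of the published 148-patient cohort
#' (columns: without RD, with RD), transcribed from the publication for
#' recomputing its group-comparison statistics.
#'
#' @return Named list of 2 x k count matrices.
#' @export
rd_table1_counts <- function() {
  list(
    laterality = matrix(c(44, 55, 26, 23), 2, 2,
                        dimnames = list(c("left", "right"), c("noRD", "RD"))),
    surgery = matrix(c(19, 80, 10, 39), 2, 2,
                     dimnames = list(c("TM/MRM", "BCS"), c("noRD", "RD"))),
    ajcc = matrix(c(24, 31, 32, 11, 1, 10, 15, 16, 6, 2), 5, 2,
                  dimnames = list(0:4, c("noRD", "RD"))),
    scf = matrix(c(78, 21, 32, 17), 2, 2,
                 dimnames = list(c("no", "yes"), c("noRD", "RD"))),
    imn = matrix(c(82, 17, 33, 16), 2, 2,
                 dimnames = list(c("no", "yes"), c("noRD", "RD"))),
    chemotherapy = matrix(c(51, 48, 23, 26), 2, 2,
                          dimnames = list(c("no", "yes"), c("noRD", "RD")))
  )
}

#' Published cohort table: DVH summaries (mean, SD, n) per group
#'
#' @return data.frame with one row per DVH feature and columns for the
#'   without-RD (n = 99) and with-RD (n = 49) group summaries.
#' @export
rd_table2_summaries <- function() {
  data.frame(
    feature = c(paste0("V", seq(5, 50, 5), "Gy"), "PTV100", "PTV105"),
    mean_no = c(312.7, 248.6, 218.0, 198.2, 181.26, 166.5, 152.3, 137.5,
                114.6, 46.3, 648.0, 57.2),
    sd_no = c(123.6, 90.9, 76.3, 63.8, 55.1, 47.8, 41.8, 37.3, 31.1, 24.8,
              374.3, 80.0),
    n_no = 99,
    mean_rd = c(349.9, 277.2, 241.8, 218.3, 199.8, 182.5, 166.1, 149.3,
                125.4, 50.2, 814.5, 93.5),
    sd_rd = c(112.3, 83.7, 67.0, 57.1, 49.4, 43.4, 38.2, 37.1, 30.1, 24.2,
              394.1, 202.1),
    n_rd = 49
  )
}

# assemble a per-fold metric report with CIs
metric_report <- function(fold_metrics) {
  mnames <- c("accuracy", "recall", "specificity", "ppv", "npv", "f1",
              "auc", "brier")
  per_fold <- do.call(rbind, lapply(fold_metrics, function(m) {
    unlist(m[mnames])
  }))
  summary <- t(apply(per_fold, 2, fold_ci))
  list(per_fold = as.data.frame(per_fold), summary = as.data.frame(summary))
}
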