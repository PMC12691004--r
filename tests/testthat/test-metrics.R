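# Classification metrics, fold CIs, effect sizes, decision curves and the
# summary-statistics tests.

test_that("confusion metrics reproduce their formulas and conventions", {
  # TP=3 FP=1 TN=5 FN=1
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(y, p)
  expect_equal(m[c("TP", "FP", "TN", "FN")], list(TP = 3L, FP = 1L, TN = 5L, FN = 1L))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$f1, 0.75)

  perf <- confusion_metrics(y, y)
  expect_true(all(unlist(perf[c("accuracy", "recall", "specificity",
                                "ppv", "npv", "f1")]) == 1))

  # all-positive predictor at prevalence 1/3
  y3 <- c(rep(1, 5), rep(0, 10))
  ap <- confusion_metrics(y3, rep(1, 15))
  expect_equal(ap$recall, 1)
  expect_equal(ap$specificity, 0)
  expect_equal(ap$accuracy, 1 / 3)
  expect_equal(ap$f1, 0.5)
  expect_equal(ap$npv, 0)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "no samples")
})

test_that("metrics agree with brute-force counting on fuzzed inputs", {
  set.seed(10)
  for (rep in 1:10) {
    y <- runif(40) < 0.4
    p <- runif(40) < 0.5
    m <- confusion_metrics(y, p)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in 1:40) {
      if (y[i] && p[i]) tp <- tp + 1
      if (!y[i] && p[i]) fp <- fp + 1
      if (!y[i] && !p[i]) tn <- tn + 1
      if (y[i] && !p[i]) fn <- fn + 1
    }
    expect_equal(m$accuracy, (tp + tn) / 40)
    expect_equal(m$recall, if (tp + fn) tp / (tp + fn) else 0)
    expect_equal(m$ppv, if (tp + fp) tp / (tp + fp) else 0)
  }
})

test_that("AUC follows the Mann-Whitney pair count with half ties", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(12)
  y <- runif(20) < 0.5
  y[1] <- TRUE; y[2] <- FALSE
  s <- sample(seq(0, 1, 0.05), 20, replace = TRUE)   # ties likely
  pairs <- 0; wins <- 0
  for (i in which(y)) for (j in which(!y)) {
    pairs <- pairs + 1
    wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(auc_score(y, s), wins / pairs)
  # monotone transform invariance
  expect_equal(auc_score(y, plogis(5 * s - 2)), auc_score(y, s))
  expect_error(auc_score(rep(1, 4), runif(4)), "undefined AUC")
})

test_that("fold CI matches the closed-form t interval", {
  expect_equal(unname(fold_ci(rep(0.7, 5))), c(0.7, 0.7, 0.7))
  v <- c(0.7, 0.72, 0.74, 0.76, 0.78)
  ci <- fold_ci(v)
  hw <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(unname(ci), c(0.74, 0.74 - hw, 0.74 + hw))
  expect_true(ci["low"] <= ci["mean"] && ci["mean"] <= ci["high"])
  expect_error(fold_ci(0.7), "insufficient folds")
})

test_that("Cohen's d uses the pooled SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0.5, 1.5); b <- c(-0.5, 0.5)   # means 1 apart, pooled sd 1/sqrt(2)...
  set.seed(2)
  x <- rnorm(20); y <- rnorm(15, 0.4)
  sp <- sqrt(((19) * var(x) + 14 * var(y)) / 33)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  # unit case: construct samples with pooled sd exactly 1
  a2 <- c(2, 4); b2 <- c(1, 3)  # sds sqrt(2), pooled sqrt(2)
  expect_equal(cohens_d(a2, b2), 1 / sqrt(2))
  expect_warning(d <- cohens_d(c(1, 1), c(0, 0)), "signed infinity")
  expect_identical(d, Inf)
})

test_that("decision curve reproduces net-benefit arithmetic and Youden", {
  # 10-sample hand-worked set at t = 0.2: NB = TP/n - (FP/n) * 0.25
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.6, 0.3, 0.4, 0.1, 0.1, 0.2, 0.05, 0.15, 0.25)
  dc <- decision_curve(y, p, thresholds = c(0.2, 0.5))
  # at 0.2: predicted positive = p >= 0.2 -> TP = 3 (0.9, 0.6, 0.3) and
  # FP = 3 (0.4, 0.25, 0.2)
  expect_equal(dc$curve$nb_model[1], 3 / 10 - (3 / 10) * 0.25)
  expect_equal(dc$curve$nb_all[1], 0.3 - 0.7 * 0.25)
  expect_true(all(dc$curve$nb_none == 0))
  expect_true(all(dc$curve$nb_model <= mean(y) + 1e-12))

  # perfect classifier: NB = prevalence below the smallest positive score,
  # and Youden J = 1
  yp <- c(0, 0, 0, 1, 1)
  pp <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  dcp <- decision_curve(yp, pp, thresholds = c(0.4, 0.6))
  expect_equal(dcp$curve$nb_model, c(0.4, 0.4))
  expect_equal(unname(dcp$youden["J"]), 1)
  expect_equal(unname(dcp$utility["default", "ppv"]), 1)
  expect_error(decision_curve(yp, pp, thresholds = c(0, 0.5)),
               "invalid threshold")
  expect_error(decision_curve(yp, pp * 2), "\\[0,1\\]")
})

test_that("chi-square reproduces printed cohort statistics and the cellwise formula", {
  tabs <- rd_table1_counts()
  expect_lt(abs(chi_square_2xk(tabs$imn)$p - 0.033), 5e-4)
  expect_lt(abs(chi_square_2xk(tabs$laterality)$p - 0.323), 5e-4)
  expect_lt(abs(chi_square_2xk(tabs$chemotherapy)$p - 0.600), 5e-4)

  prop <- matrix(c(20, 40, 10, 20), 2, 2)  # exactly proportional
  r <- chi_square_2xk(prop)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  set.seed(4)
  for (rep in 1:5) {
    tb <- matrix(rpois(4, 30) + 1, 2, 2)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(chi_square_2xk(tb)$chi2, sum((tb - E)^2 / E))
    # 2x2 chi-square equals the squared two-proportion z statistic
    p1 <- tb[1, 1] / sum(tb[, 1]); p2 <- tb[1, 2] / sum(tb[, 2])
    pp <- sum(tb[1, ]) / sum(tb)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(tb[, 1]) + 1 / sum(tb[, 2])))
    expect_equal(chi_square_2xk(tb)$chi2, z^2, tolerance = 1e-10)
  }
  expect_error(chi_square_2xk(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("pooled t from summaries reproduces printed DVH comparisons", {
  t2 <- rd_table2_summaries()
  pt_of <- function(feat) {
    r <- t2[t2$feature == feat, ]
    pooled_t_from_summary(list(mean = r$mean_no, sd = r$sd_no, n = r$n_no),
                          list(mean = r$mean_rd, sd = r$sd_rd, n = r$n_rd))
  }
  expect_lt(abs(pt_of("PTV100")$p - 0.013), 5e-4)
  expect_lt(abs(pt_of("V25Gy")$p - 0.048), 5e-4)
  expect_lt(abs(pt_of("V45Gy")$p - 0.046), 5e-4)
  expect_lt(abs(pt_of("V50Gy")$p - 0.366), 5e-4)

  eq <- pooled_t_from_summary(list(mean = 5, sd = 1, n = 10),
                              list(mean = 5, sd = 2, n = 12))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  # p equals numerical integration of the t density
  r <- pooled_t_from_summary(list(mean = 10, sd = 3, n = 14),
                             list(mean = 12, sd = 4, n = 9))
  dens <- function(x) dt(x, r$df)
  p_num <- 2 * integrate(dens, abs(r$t), Inf)$value
  expect_equal(r$p, p_num, tolerance = 1e-6)
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(c(1, 0, 1), c(0.5, 0.5, 0.5)), 0.25)
})
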