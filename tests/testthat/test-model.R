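# Fold plans, SMOTE-ENN, the stacked ensemble and the nested-CV loop.

test_that("fold plan partitions patients with stratified positives", {
  set.seed(1)
  y <- c(rep(TRUE, 49), rep(FALSE, 99))[sample(148)]
  plan <- make_fold_plan(y, 5, 5, seed = 3)
  tests <- lapply(plan$outer, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:148)           # partition
  expect_equal(sum(vapply(tests, length, 0L)), 148)
  pos <- vapply(tests, function(te) sum(y[te]), 0L)
  expect_true(all(pos %in% c(9L, 10L)))              # 49 positives over 5 folds
  # inner folds never contain outer-test patients
  for (f in 1:5) {
    inner_ids <- unlist(lapply(plan$inner[[f]], function(p) c(p$train, p$val)))
    expect_length(intersect(inner_ids, plan$outer[[f]]$test), 0)
    val_union <- sort(unique(unlist(lapply(plan$inner[[f]], `[[`, "val"))))
    expect_equal(val_union, sort(plan$outer[[f]]$train))
  }
  expect_identical(make_fold_plan(y, 5, 5, seed = 3), plan)  # determinism
  expect_error(make_fold_plan(c(TRUE, rep(FALSE, 20)), 5, 5), "insufficient class")
})

test_that("SMOTE balances classes and ENN agrees with brute-force 3-NN editing", {
  set.seed(2)
  # two well-separated blobs: SMOTE balances, ENN removes nothing
  X <- rbind(matrix(rnorm(60 * 2, 0), 60), matrix(rnorm(20 * 2, 8), 20))
  colnames(X) <- c("u", "v")
  y <- rep(c(FALSE, TRUE), c(60, 20))
  out <- smote_enn(X, y, seed = 5)
  expect_equal(out$n_removed, 0)
  expect_equal(sum(out$y), sum(!out$y))              # balanced after SMOTE
  expect_equal(out$n_synthetic, 40)

  # a lone minority point inside the majority blob is removed by ENN
  X2 <- rbind(matrix(rnorm(40 * 2, 0, 0.5), 40),
              matrix(c(0, 0), 1),                    # minority intruder
              matrix(rnorm(12 * 2, 10, 0.5), 12))
  colnames(X2) <- c("u", "v")
  y2 <- rep(c(FALSE, TRUE, TRUE), c(40, 1, 12))
  out2 <- smote_enn(X2, y2, seed = 6)
  # brute-force ENN on the SMOTE-balanced set
  bal <- dosederm:::run_with_seed(6, {
    minority <- TRUE
    Xmin <- X2[y2, , drop = FALSE]
    D <- as.matrix(dist(Xmin)); diag(D) <- Inf
    nn <- t(apply(D, 1, function(r) order(r)[1:5]))
    n_new <- 40 - 13
    bi <- sample.int(13, n_new, replace = TRUE)
    pk <- nn[cbind(bi, sample.int(5, n_new, replace = TRUE))]
    u <- runif(n_new)
    rbind(X2, Xmin[bi, ] + u * (Xmin[pk, ] - Xmin[bi, ]))
  })
  yb <- c(y2, rep(TRUE, 27))
  Db <- as.matrix(dist(bal)); diag(Db) <- Inf
  keep <- vapply(seq_len(nrow(bal)), function(i) {
    nb <- order(Db[i, ])[1:3]
    mean(yb[nb]) == 0.5 || (mean(yb[nb]) > 0.5) == yb[i]
  }, TRUE)
  expect_equal(nrow(out2$X), sum(keep))
  expect_false(keep[41])                              # the intruder goes
  expect_error(smote_enn(X, rep(TRUE, 80)), "degenerate training fold")
})

test_that("stacked fit separates separable data and composes base + meta", {
  sep <- make_separable(n = 120, seed = 4)
  inner <- make_inner(120, 4)
  m <- fit_stacked(sep$X, sep$y, search_space(4), inner, seed = 7)
  p <- predict(m, sep$X)
  expect_equal(auc_score(sep$y, p), 1)
  expect_true(all(p >= 0 & p <= 1))

  # pipeline consistency: prediction equals the meta model applied to the
  # three base probability outputs
  set.seed(9)
  Xn <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, colnames(sep$X)))
  bp <- sapply(c("lr", "rf", "gbdt"), function(l) {
    dosederm:::predict_base(m$base[[l]], Xn)
  })
  manual <- as.numeric(predict(m$meta, bp, type = "response"))
  expect_equal(predict(m, Xn), manual, tolerance = 1e-12)

  # seeded determinism of the chosen hyperparameters
  m2 <- fit_stacked(sep$X, sep$y, search_space(4), inner, seed = 7)
  expect_identical(m$best_params, m2$best_params)
  expect_equal(predict(m2, Xn), predict(m, Xn), tolerance = 1e-12)
})

test_that("nested CV keeps test folds untouched (leak freedom)", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 12))
  y <- co$clinical$rd_grade_ge2
  blocks <- list(clinical = encode_clinical(co$clinical), dvh = co$dvh)
  cfg <- nested_cv_config(k_outer = 4, k_inner = 3, n_draws = 2,
                          boruta_iter = 10, seed = 5)
  plan <- make_fold_plan(y, 4, 3, seed = 5)
  te <- plan$outer[[1]]$test
  fit_a <- dosederm:::fit_outer_fold(blocks, y,
    dosederm:::resolve_combination(1), plan$outer[[1]]$train, cfg, "o1", 1005)
  # replace every test-fold row with noise: the fitted fold model and its
  # training-row predictions must be bit-identical
  blocks_b <- blocks
  for (b in names(blocks_b)) {
    blocks_b[[b]][te, ] <- matrix(rnorm(length(te) * ncol(blocks_b[[b]]), 1e3),
                                  length(te))
  }
  fit_b <- dosederm:::fit_outer_fold(blocks_b, y,
    dosederm:::resolve_combination(1), plan$outer[[1]]$train, cfg, "o1", 1005)
  expect_identical(fit_a$reports, fit_b$reports)
  expect_identical(fit_a$model$best_params, fit_b$model$best_params)
  tr <- plan$outer[[1]]$train
  expect_identical(predict(fit_a$model, fit_a$fused[tr, , drop = FALSE]),
                   predict(fit_b$model, fit_b$fused[tr, , drop = FALSE]))
})

test_that("nested CV predicts original test rows and is reproducible end to end", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 12))
  y <- co$clinical$rd_grade_ge2
  blocks <- list(clinical = encode_clinical(co$clinical), dvh = co$dvh)
  cfg <- nested_cv_config(k_outer = 4, k_inner = 3, n_draws = 2,
                          boruta_iter = 10, seed = 5)
  r1 <- run_nested_cv(blocks, y, 1, cfg)
  expect_equal(sort(r1$predictions$id), 1:80)   # every patient predicted once
  expect_equal(nrow(r1$predictions), 80)        # SMOTE never inflates tests
  expect_equal(nrow(r1$report$per_fold), 4)
  r2 <- run_nested_cv(blocks, y, 1, cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$report, r2$report)
})

test_that("ablation reports all four models; degenerate constant models follow the formulas", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 8))
  y <- co$clinical$rd_grade_ge2
  blocks <- list(clinical = encode_clinical(co$clinical), dvh = co$dvh)
  cfg <- nested_cv_config(k_outer = 3, k_inner = 3, n_draws = 2,
                          boruta_iter = 8, seed = 2)
  ab <- run_ablation(blocks, y, 1, cfg)
  expect_identical(names(ab), c("lr", "rf", "gbdt", "stacked"))
  for (m in ab) expect_equal(nrow(m$report$per_fold), 3)

  # an always-positive degenerate predictor: recall 1, specificity 0,
  # accuracy = prevalence (the pattern printed for saturated models)
  yy <- c(rep(TRUE, 10), rep(FALSE, 20))
  cm <- confusion_metrics(yy, rep(TRUE, 30))
  expect_equal(cm$recall, 1)
  expect_equal(cm$specificity, 0)
  expect_equal(cm$accuracy, 1 / 3)
})

test_that("sensitivity table equals brute-force aggregation of the search log", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 8))
  y <- co$clinical$rd_grade_ge2
  blocks <- list(clinical = encode_clinical(co$clinical), dvh = co$dvh)
  r <- run_nested_cv(blocks, y, 1,
                     nested_cv_config(k_outer = 3, k_inner = 3, n_draws = 3,
                                      boruta_iter = 8, seed = 2))
  tab <- hyperparam_sensitivity(r$search_log)
  expect_true(all(c("n_estimators", "max_depth", "learning_rate") %in%
                    tab$parameter))
  # grouped means match direct recomputation
  gb <- r$search_log[r$search_log$learner == "gbdt" &
                       !is.na(r$search_log$max_depth), ]
  for (v in unique(gb$max_depth)) {
    expect_equal(tab$mean_f1[tab$learner == "gbdt" & tab$parameter == "max_depth" &
                               tab$value == v],
                 mean(gb$f1[gb$max_depth == v]))
  }
  # every sampled value appears
  expect_setequal(tab$value[tab$learner == "gbdt" & tab$parameter == "max_depth"],
                  unique(gb$max_depth))
  expect_error(hyperparam_sensitivity(NULL), "no search data")
})
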