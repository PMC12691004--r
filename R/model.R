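# Stacking-ensemble modelling under nested stratified cross-validation.
# Outer folds estimate generalisation; inner folds drive randomized
# hyperparameter search (scored by AUC). SMOTE-ENN rebalancing, feature
# selection and z-scoring are all fitted strictly inside the training fold.

#' Stratified nested cross-validation fold plan
#'
#' Outer test folds partition the patients; stratification keeps each fold's
#' positive fraction within one patient of the global fraction. Inner folds
#' subdivide each outer training set and never contain outer-test patients.
#'
#' @param labels binary labels.
#' @param k_outer,k_inner fold counts (default 5/5).
#' @param seed integer seed.
#' @return List of class `fold_plan` with `outer` (train/test id pairs) and
#'   `inner` (per outer fold, k_inner train/val pairs over the training ids).
#' @export
make_fold_plan <- function(labels, k_outer = 5, k_inner = 5, seed = 1) {
  y <- as.logical(labels)
  if (sum(y) < k_outer || sum(!y) < k_outer)
    stop("insufficient class size for ", k_outer, " folds")
  run_with_seed(seed, {
    assign_folds <- function(ids, k) {
      # deal shuffled ids round-robin so fold sizes differ by at most one
      ids <- sample(ids)
      split(ids, rep_len(seq_len(k), length(ids)))
    }
    strat <- function(ids, yy, k) {
      f_pos <- assign_folds(ids[yy[ids]], k)
      f_neg <- assign_folds(ids[!yy[ids]], k)
      lapply(seq_len(k), function(i) sort(c(f_pos[[i]], f_neg[[i]])))
    }
    outer_test <- strat(seq_along(y), y, k_outer)
    outer <- lapply(outer_test, function(te) {
      list(train = setdiff(seq_along(y), te), test = te)
    })
    inner <- lapply(outer, function(fo) {
      val <- strat(fo$train, y, k_inner)
      lapply(val, function(v) list(train = setdiff(fo$train, v), val = v))
    })
    structure(list(outer = outer, inner = inner, k_outer = k_outer,
                   k_inner = k_inner, seed = seed), class = "fold_plan")
  })
}

#' SMOTE oversampling followed by edited-nearest-neighbour cleaning
#'
#' SMOTE: synthetic minority samples x_new = x_i + u (x_nn - x_i) with
#' u ~ U(0,1) and x_nn one of the k_smote nearest minority neighbours, drawn
#' until the classes balance. ENN then removes every sample whose k_enn
#' nearest neighbours' majority vote disagrees with its label. Runs on a
#' training fold only.
#'
#' @param X numeric matrix.
#' @param y binary labels (both classes present).
#' @param k_smote SMOTE neighbourhood size (default 5).
#' @param k_enn ENN neighbourhood size (default 3).
#' @param seed integer seed.
#' @return List (X, y, n_synthetic, n_removed).
#' @export
smote_enn <- function(X, y, k_smote = 5, k_enn = 3, seed = 1) {
  y <- as.logical(y)
  if (all(y) || !any(y)) stop("degenerate training fold: single class")
  X <- as.matrix(X)
  run_with_seed(seed, {
    minority <- if (sum(y) <= sum(!y)) TRUE else FALSE
    Xmin <- X[y == minority, , drop = FALSE]
    n_min <- nrow(Xmin); n_maj <- sum(y != minority)
    n_new <- n_maj - n_min
    k_use <- min(k_smote, n_min - 1)
    Xs <- X; ys <- y
    if (n_new > 0 && k_use >= 1) {
      D <- as.matrix(stats::dist(Xmin))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_use)]))
      base_i <- sample.int(n_min, n_new, replace = TRUE)
      pick <- nn[cbind(base_i, sample.int(k_use, n_new, replace = TRUE))]
      u <- stats::runif(n_new)
      Xnew <- Xmin[base_i, , drop = FALSE] +
        u * (Xmin[pick, , drop = FALSE] - Xmin[base_i, , drop = FALSE])
      Xs <- rbind(X, Xnew)
      ys <- c(y, rep(minority, n_new))
    }
    n_syn <- length(ys) - length(y)
    # ENN cleaning on the balanced set
    Dall <- as.matrix(stats::dist(Xs))
    diag(Dall) <- Inf
    keep <- vapply(seq_len(nrow(Xs)), function(i) {
      nb <- order(Dall[i, ])[seq_len(min(k_enn, nrow(Xs) - 1))]
      mean(ys[nb]) == 0.5 || (mean(ys[nb]) > 0.5) == ys[i]
    }, TRUE)
    # heavy class overlap can let ENN gut a class; editing is then skipped so
    # the fold stays trainable
    if (min(sum(ys[keep]), sum(!ys[keep])) < 6) keep <- rep(TRUE, length(ys))
    list(X = Xs[keep, , drop = FALSE], y = ys[keep], n_synthetic = n_syn,
         n_removed = sum(!keep))
  })
}

#' Randomized-search space for the base learners
#'
#' @param n_draws sampled configurations per learner (default 30).
#' @return List of class `search_space`.
#' @export
search_space <- function(n_draws = 30) {
  structure(list(
    rf = list(n_estimators = 100:500, max_depth = c(0, 3:15)),
    gbdt = list(n_estimators = 50:300, learning_rate = c(0.01, 0.3),
                max_depth = 2:5),
    lr = list(lambda_log10 = c(-2, 0.5)),
    n_draws = n_draws
  ), class = "search_space")
}

draw_configs <- function(space) {
  n <- space$n_draws
  list(
    lr = data.frame(
      lambda = 10^stats::runif(n, space$lr$lambda_log10[1],
                               space$lr$lambda_log10[2])),
    rf = data.frame(
      n_estimators = sample(space$rf$n_estimators, n, replace = TRUE),
      max_depth = sample(space$rf$max_depth, n, replace = TRUE)),
    gbdt = data.frame(
      n_estimators = sample(space$gbdt$n_estimators, n, replace = TRUE),
      learning_rate = stats::runif(n, space$gbdt$learning_rate[1],
                                   space$gbdt$learning_rate[2]),
      max_depth = sample(space$gbdt$max_depth, n, replace = TRUE))
  )
}

fit_base <- function(learner, params, X, y, seed) {
  y <- as.numeric(as.logical(y))
  if (learner == "lr") {
    Xg <- if (ncol(X) < 2) cbind(X, `..pad` = 0) else X
    list(type = "lr",
         fit = glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                              lambda = params$lambda, standardize = FALSE),
         pad = ncol(X) < 2)
  } else if (learner == "rf") {
    list(type = "rf",
         fit = ranger::ranger(x = as.data.frame(X), y = factor(y, c(0, 1)),
                              probability = TRUE,
                              num.trees = params$n_estimators,
                              max.depth = params$max_depth,
                              seed = seed, num.threads = 1))
  } else if (learner == "gbdt") {
    list(type = "gbdt",
         fit = xgboost::xgb.train(
           params = list(objective = "binary:logistic",
                         eta = params$learning_rate,
                         max_depth = params$max_depth,
                         nthread = 1, seed = seed),
           data = xgboost::xgb.DMatrix(X, label = y),
           nrounds = params$n_estimators, verbose = 0))
  } else stop("unknown learner")
}

predict_base <- function(model, X) {
  if (model$type == "lr") {
    Xg <- if (isTRUE(model$pad)) cbind(X, `..pad` = 0) else X
    as.numeric(stats::predict(model$fit, Xg, type = "response"))
  } else if (model$type == "rf") {
    stats::predict(model$fit, data = as.data.frame(X),
                   num.threads = 1)$predictions[, "1"]
  } else if (model$type == "gbdt") {
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  } else if (model$type == "constant") {
    rep(model$p, nrow(X))
  } else stop("unknown model type")
}

#' Fit the stacking ensemble with randomized hyperparameter search
#'
#' Per base learner (logistic regression, random forest, gradient-boosted
#' trees), `n_draws` sampled configurations are scored by mean inner-fold
#' AUC; the winners are refit on the full training data. The logistic
#' meta-learner is trained on 5-fold out-of-sample base probabilities so the
#' meta level never sees in-sample base predictions.
#'
#' @param X numeric training matrix (typically rebalanced by [smote_enn()]).
#' @param y binary training labels.
#' @param space a [search_space()].
#' @param inner_folds list of `list(train, val)` index pairs into `X`.
#' @param seed integer seed.
#' @return List of class `stacked_model` with the fitted base learners,
#'   meta-learner, chosen hyperparameters and the search log.
#' @export
fit_stacked <- function(X, y, space = search_space(), inner_folds, seed = 1) {
  X <- as.matrix(X)
  y <- as.logical(y)
  run_with_seed(seed, {
    cfgs <- draw_configs(space)
    log_rows <- list()
    best <- list()
    for (learner in c("lr", "rf", "gbdt")) {
      cf <- cfgs[[learner]]
      scores <- matrix(NA_real_, nrow(cf), length(inner_folds))
      for (d in seq_len(nrow(cf))) {
        for (f in seq_along(inner_folds)) {
          tr <- inner_folds[[f]]$train; va <- inner_folds[[f]]$val
          if (length(unique(y[va])) < 2 || min(sum(y[tr]), sum(!y[tr])) < 2) next
          m <- fit_base(learner, cf[d, , drop = FALSE],
                        X[tr, , drop = FALSE], y[tr], seed = seed + d)
          pv <- predict_base(m, X[va, , drop = FALSE])
          a <- auc_score(y[va], pv)
          f1 <- confusion_metrics(y[va], pv >= 0.5)$f1
          scores[d, f] <- a
          log_rows[[length(log_rows) + 1]] <- data.frame(
            learner = learner, draw = d, fold = f,
            n_estimators = if (is.null(cf$n_estimators)) NA else cf$n_estimators[d],
            max_depth = if (is.null(cf$max_depth)) NA else cf$max_depth[d],
            learning_rate = if (is.null(cf$learning_rate)) NA else cf$learning_rate[d],
            lambda = if (is.null(cf$lambda)) NA else cf$lambda[d],
            auc = a, f1 = f1)
        }
      }
      mean_auc <- rowMeans(scores, na.rm = TRUE)
      mean_auc[is.nan(mean_auc)] <- -Inf
      best[[learner]] <- cf[which.max(mean_auc), , drop = FALSE]
    }
    base <- lapply(c(lr = "lr", rf = "rf", gbdt = "gbdt"), function(l) {
      fit_base(l, best[[l]], X, y, seed = seed)
    })
    # out-of-sample base probabilities for the meta level
    k_meta <- 5
    meta_p <- matrix(NA_real_, nrow(X), 3,
                     dimnames = list(NULL, c("lr", "rf", "gbdt")))
    folds <- rep_len(seq_len(k_meta), nrow(X))[sample.int(nrow(X))]
    for (f in seq_len(k_meta)) {
      tr <- which(folds != f); ho <- which(folds == f)
      if (min(sum(y[tr]), sum(!y[tr])) < 2) next
      for (l in c("lr", "rf", "gbdt")) {
        m <- fit_base(l, best[[l]], X[tr, , drop = FALSE], y[tr],
                      seed = seed + f)
        meta_p[ho, l] <- predict_base(m, X[ho, , drop = FALSE])
      }
    }
    if (anyNA(meta_p)) {
      for (l in c("lr", "rf", "gbdt")) {
        miss <- is.na(meta_p[, l])
        meta_p[miss, l] <- predict_base(base[[l]], X[miss, , drop = FALSE])
      }
    }
    # lightly ridge-penalised logistic meta-learner: base probabilities are
    # strongly correlated and an unpenalised fit is unstable at fold sizes
    meta <- glmnet::glmnet(meta_p, as.numeric(y), family = "binomial",
                           alpha = 0, lambda = 0.02, standardize = FALSE)
    structure(list(base = base, meta = meta, best_params = best,
                   search_log = do.call(rbind, log_rows), seed = seed),
              class = "stacked_model")
  })
}

#' Predicted Grade >= 2 probabilities from a stacked model
#'
#' @param object a `stacked_model`.
#' @param newdata numeric matrix on the model's feature scale.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.stacked_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  bp <- vapply(c("lr", "rf", "gbdt"), function(l) {
    predict_base(object$base[[l]], newdata)
  }, numeric(nrow(newdata)))
  if (is.null(dim(bp))) bp <- matrix(bp, 1, dimnames = list(NULL, c("lr", "rf", "gbdt")))
  as.numeric(stats::predict(object$meta, bp, type = "response"))
}

#' Nested cross-validation configuration
#'
#' @param k_outer,k_inner fold counts.
#' @param n_draws randomized-search draws per learner.
#' @param alpha ANOVA retention threshold.
#' @param boruta_iter,boruta_trees Boruta stage parameters.
#' @param select_blocks blocks subjected to two-stage selection; blocks not
#'   listed pass through unselected ("all" = every block).
#' @param smote apply SMOTE-ENN to training folds.
#' @param k_smote,k_enn rebalancing neighbourhood sizes.
#' @param seed integer seed for folds, selection, rebalancing and search.
#' @return List of class `ncv_config`.
#' @export
nested_cv_config <- function(k_outer = 5, k_inner = 5, n_draws = 30,
                             alpha = 0.05, boruta_iter = 200,
                             boruta_trees = 200, select_blocks = "all",
                             smote = TRUE, k_smote = 5, k_enn = 3, seed = 1) {
  structure(as.list(environment()), class = "ncv_config")
}

constant_model <- function(p) {
  structure(list(base = NULL, meta = NULL, constant = p), class = "constant_model")
}

#' @export
predict.constant_model <- function(object, newdata, ...) {
  rep(object$constant, nrow(as.matrix(newdata)))
}

fit_outer_fold <- function(blocks, y, comb, train, cfg, fold_id, fold_seed) {
  sel_names <- if (identical(cfg$select_blocks, "all")) comb$blocks
               else intersect(cfg$select_blocks, comb$blocks)
  reports <- list()
  for (b in sel_names) {
    reports[[b]] <- select_block(blocks[[b]][train, , drop = FALSE], y[train],
                                 alpha = cfg$alpha, n_iter = cfg$boruta_iter,
                                 num_trees = cfg$boruta_trees,
                                 seed = fold_seed, fold_id = fold_id)
  }
  fused <- tryCatch(
    fuse(blocks, reports, comb, train_ids = train, fold_id = fold_id),
    error = function(e) {
      if (grepl("no features survived", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(fused)) {
    return(list(model = constant_model(mean(y[train])), fused = NULL,
                reports = reports, search_log = NULL, degenerate = TRUE))
  }
  Xtr <- fused[train, , drop = FALSE]
  ytr <- y[train]
  if (cfg$smote) {
    reb <- smote_enn(Xtr, ytr, cfg$k_smote, cfg$k_enn, seed = fold_seed)
    Xtr <- reb$X; ytr <- reb$y
  }
  inner <- run_with_seed(fold_seed + 1, {
    make_inner_folds(ytr, cfg$k_inner)
  })
  model <- fit_stacked(Xtr, ytr, search_space(cfg$n_draws), inner,
                       seed = fold_seed + 2)
  list(model = model, fused = fused, reports = reports,
       search_log = model$search_log, degenerate = FALSE,
       Xtr = Xtr, ytr = ytr)
}

make_inner_folds <- function(y, k) {
  y <- as.logical(y)
  idx_pos <- sample(which(y)); idx_neg <- sample(which(!y))
  fold_of <- integer(length(y))
  fold_of[idx_pos] <- rep_len(seq_len(k), length(idx_pos))
  fold_of[idx_neg] <- rep_len(seq_len(k), length(idx_neg))
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), val = which(fold_of == f))
  })
}

#' Run the full nested cross-validation for one feature combination
#'
#' Per outer fold: two-stage selection on the training rows, fusion with
#' train-fitted z-scoring, SMOTE-ENN rebalancing of the training rows,
#' randomized search + stacked fit, prediction of the untouched test fold.
#' No test-fold row enters selection, scaling, rebalancing or fitting.
#'
#' @param blocks named list of full-cohort feature matrices.
#' @param labels binary outcome vector.
#' @param combination combination id (1-11) or registry entry.
#' @param config an [nested_cv_config()].
#' @param model one of "stacked" (default), "lr", "rf", "gbdt" — single-model
#'   runs reuse the same folds and search for ablation.
#' @param return_models keep the fitted per-fold models (for audits).
#' @return List with `report` (per-fold metrics + fold CIs), `predictions`
#'   (pooled outer-fold probabilities), `search_log`, `plan`, and optionally
#'   `models`.
#' @export
run_nested_cv <- function(blocks, labels, combination,
                          config = nested_cv_config(), model = "stacked",
                          return_models = FALSE) {
  comb <- resolve_combination(combination)
  y <- as.logical(labels)
  plan <- make_fold_plan(y, config$k_outer, config$k_inner, seed = config$seed)
  fold_metrics <- list(); preds <- list(); logs <- list(); models <- list()
  for (f in seq_len(config$k_outer)) {
    fo <- plan$outer[[f]]
    fit <- fit_outer_fold(blocks, y, comb, fo$train, config,
                          fold_id = paste0("outer", f),
                          fold_seed = config$seed + 1000 * f)
    mdl <- if (model == "stacked" || fit$degenerate) fit$model else {
      fit_base(model, fit$model$best_params[[model]], fit$Xtr, fit$ytr,
               seed = config$seed + 1000 * f)
    }
    Xte <- if (is.null(fit$fused)) {
      matrix(0, length(fo$test), 1)
    } else fit$fused[fo$test, , drop = FALSE]
    p <- if (inherits(mdl, "stacked_model") || inherits(mdl, "constant_model")) {
      predict(mdl, Xte)
    } else predict_base(mdl, Xte)
    cm <- confusion_metrics(y[fo$test], p >= 0.5)
    cm$auc <- auc_score(y[fo$test], p)
    cm$brier <- brier_score(y[fo$test], p)
    fold_metrics[[f]] <- cm
    preds[[f]] <- data.frame(id = fo$test, fold = f, prob = p,
                             label = y[fo$test])
    if (!is.null(fit$search_log)) logs[[f]] <- cbind(outer_fold = f, fit$search_log)
    if (return_models) models[[f]] <- mdl
  }
  out <- list(report = metric_report(fold_metrics), fold_metrics = fold_metrics,
              predictions = do.call(rbind, preds),
              search_log = if (length(logs)) do.call(rbind, logs),
              plan = plan, combination = comb, model = model)
  if (return_models) out$models <- models
  out
}

#' Ablation: each base learner alone versus the stacked ensemble
#'
#' @inheritParams run_nested_cv
#' @return Named list of four `run_nested_cv()` results (lr, rf, gbdt,
#'   stacked), sharing fold seeds.
#' @export
run_ablation <- function(blocks, labels, combination,
                         config = nested_cv_config()) {
  sapply(c("lr", "rf", "gbdt", "stacked"), function(m) {
    run_nested_cv(blocks, labels, combination, config, model = m)
  }, simplify = FALSE)
}

#' Hyperparameter sensitivity table from search logs
#'
#' Mean F1 (and draw counts) grouped by each sampled value of n_estimators,
#' max_depth and learning_rate.
#'
#' @param search_logs data.frame from `run_nested_cv()$search_log`.
#' @return data.frame (learner, parameter, value, mean_f1, n).
#' @export
hyperparam_sensitivity <- function(search_logs) {
  if (is.null(search_logs) || nrow(search_logs) == 0) stop("no search data")
  out <- list()
  for (par in c("n_estimators", "max_depth", "learning_rate")) {
    d <- search_logs[!is.na(search_logs[[par]]), ]
    if (!nrow(d)) next
    for (l in unique(d$learner)) {
      dl <- d[d$learner == l, ]
      agg <- stats::aggregate(dl$f1, by = list(value = dl[[par]]),
                              FUN = function(v) c(mean(v), length(v)))
      out[[length(out) + 1]] <- data.frame(
        learner = l, parameter = par, value = agg$value,
        mean_f1 = agg$x[, 1], n = agg$x[, 2])
    }
  }
  do.call(rbind, out)
}
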