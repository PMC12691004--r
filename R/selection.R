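# Two-stage feature selection applied independently per modality block:
# stage 1 = one-way ANOVA (binary outcome -> two-group F test, the square of
# the pooled t); stage 2 = Boruta-style shadow-feature wrapper on a
# depth-unlimited random forest scored by exact TreeSHAP importances, with a
# two-sided binomial decision on hit counts. Fusion concatenates the selected
# blocks with train-fitted z-scoring and asserts the fold context so that
# selection fitted on one training fold can never touch another fold's rows.

#' Stage-1 ANOVA feature filter
#'
#' One-way ANOVA of each feature across the two label groups; features with
#' p < alpha are retained. A zero-variance feature gets p = 1 and is
#' rejected.
#'
#' @param X numeric matrix (patients x features) with column names.
#' @param y binary labels, both classes present.
#' @param alpha retention threshold (default 0.05).
#' @param fold_id optional fold identifier recorded for leakage checks.
#' @return List of class `anova_report`: `stats` (feature, F, p), `retained`.
#' @export
anova_filter <- function(X, y, alpha = 0.05, fold_id = NA) {
  y <- as.logical(y)
  if (!any(y) || all(y)) stop("both classes must be present")
  X <- as.matrix(X)
  n <- nrow(X); k <- 2
  mu <- colMeans(X)
  m1 <- colMeans(X[y, , drop = FALSE]); n1 <- sum(y)
  m0 <- colMeans(X[!y, , drop = FALSE]); n0 <- sum(!y)
  ssb <- n1 * (m1 - mu)^2 + n0 * (m0 - mu)^2
  sst <- colSums(sweep(X, 2, mu)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- ifelse(ssw > 0, (ssb / (k - 1)) / (ssw / (n - k)),
              ifelse(ssb > 0, Inf, 0))
  p <- ifelse(sst > 0, stats::pf(f, k - 1, n - k, lower.tail = FALSE), 1)
  stats_df <- data.frame(feature = colnames(X), F = f, p = p,
                         row.names = NULL)
  structure(list(stats = stats_df,
                 retained = colnames(X)[p < alpha & sst > 0],
                 alpha = alpha, fold_id = fold_id),
            class = "anova_report")
}

boruta_forest_params <- function(n_feat, num_trees) {
  list(objective = "binary:logistic", eta = 1, max_depth = 0,
       tree_method = "hist", grow_policy = "lossguide", max_leaves = 0,
       subsample = 0.632, colsample_bynode = max(1, floor(sqrt(n_feat))) / n_feat,
       num_parallel_tree = num_trees, nthread = 1)
}

#' Stage-2 Boruta-style selection scored by TreeSHAP
#'
#' Each iteration permutes every column independently to create shadow
#' features, fits a depth-unlimited random forest on [real | shadow], and
#' computes per-feature importance as the mean absolute TreeSHAP value. A
#' real feature scores a hit when its importance exceeds the best shadow
#' importance. After `n_iter` rounds the decision is a two-sided binomial
#' test of the hit count against Binomial(n_iter, 1/2): significantly above
#' -> accepted, significantly below -> rejected, otherwise tentative
#' (treated as rejected at the modelling boundary).
#'
#' @param X numeric matrix of ANOVA-retained features (>= 1 column).
#' @param y binary labels.
#' @param n_iter iterations (default 200).
#' @param seed integer seed (shadow permutations and forest subsampling).
#' @param num_trees forest size per iteration (default 200).
#' @param alpha decision significance level (default 0.05).
#' @param fold_id optional fold identifier recorded for leakage checks.
#' @return List of class `boruta_report`: `hits`, `decision`, `accepted`.
#' @export
boruta_shap <- function(X, y, n_iter = 200, seed = 1, num_trees = 200,
                        alpha = 0.05, fold_id = NA) {
  if (n_iter < 1) stop("invalid iterations")
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("need at least one retained feature")
  y <- as.numeric(as.logical(y))
  p <- ncol(X)
  hits <- stats::setNames(integer(p), colnames(X))
  run_with_seed(seed, {
    for (it in seq_len(n_iter)) {
      shadow <- apply(X, 2, sample)
      colnames(shadow) <- paste0("shadow_", colnames(X))
      XX <- cbind(X, shadow)
      dtr <- xgboost::xgb.DMatrix(XX, label = y)
      fit <- xgboost::xgb.train(
        params = boruta_forest_params(ncol(XX), num_trees),
        data = dtr, nrounds = 1, verbose = 0)
      contrib <- predict(fit, dtr, predcontrib = TRUE)
      imp <- colMeans(abs(contrib[, seq_len(ncol(XX)), drop = FALSE]))
      best_shadow <- max(imp[p + seq_len(p)])
      hits <- hits + (imp[seq_len(p)] > best_shadow)
    }
  })
  pbin <- vapply(hits, function(h) {
    stats::binom.test(h, n_iter, 0.5)$p.value
  }, 0)
  decision <- ifelse(pbin < alpha & hits > n_iter / 2, "accepted",
                     ifelse(pbin < alpha & hits < n_iter / 2, "rejected",
                            "tentative"))
  structure(list(hits = hits, decision = decision,
                 accepted = names(hits)[decision == "accepted"],
                 n_iter = n_iter, seed = seed, alpha = alpha,
                 fold_id = fold_id),
            class = "boruta_report")
}

#' Two-stage selection for one modality block
#'
#' @param X numeric feature matrix for one block.
#' @param y binary labels.
#' @param alpha ANOVA threshold.
#' @param n_iter,num_trees,seed Boruta parameters.
#' @param fold_id fold identifier carried into the reports.
#' @return List of class `selection_report` with `anova`, `boruta` (NULL if
#'   nothing survived stage 1) and the final `accepted` name set.
#' @export
select_block <- function(X, y, alpha = 0.05, n_iter = 200, seed = 1,
                         num_trees = 200, fold_id = NA) {
  an <- anova_filter(X, y, alpha, fold_id = fold_id)
  if (!length(an$retained)) {
    return(structure(list(anova = an, boruta = NULL, accepted = character(),
                          fold_id = fold_id), class = "selection_report"))
  }
  bo <- boruta_shap(X[, an$retained, drop = FALSE], y, n_iter = n_iter,
                    seed = seed, num_trees = num_trees, fold_id = fold_id)
  structure(list(anova = an, boruta = bo, accepted = bo$accepted,
                 fold_id = fold_id), class = "selection_report")
}

#' Registry of the 11 studied feature combinations
#'
#' @return Named list of 11 entries; each has `id` and `blocks` (subset of
#'   clinical, dvh, hcr, dlr_original, dlr_skin5mm, dlr_ptv100, dlr_v5gy).
#' @export
feature_combinations <- function() {
  defs <- list(
    list(id = 1L, blocks = c("clinical", "dvh")),
    list(id = 2L, blocks = "hcr"),
    list(id = 3L, blocks = "dlr_original"),
    list(id = 4L, blocks = "dlr_skin5mm"),
    list(id = 5L, blocks = "dlr_ptv100"),
    list(id = 6L, blocks = "dlr_v5gy"),
    list(id = 7L, blocks = c("clinical", "dvh", "hcr")),
    list(id = 8L, blocks = c("clinical", "dvh", "dlr_original")),
    list(id = 9L, blocks = c("clinical", "dvh", "dlr_skin5mm")),
    list(id = 10L, blocks = c("clinical", "dvh", "dlr_ptv100")),
    list(id = 11L, blocks = c("clinical", "dvh", "dlr_v5gy"))
  )
  stats::setNames(defs, paste0("combination_", vapply(defs, `[[`, 1L, "id")))
}

resolve_combination <- function(combination) {
  if (is.numeric(combination)) {
    reg <- feature_combinations()
    if (!combination %in% 1:11) stop("unknown combination id")
    reg[[combination]]
  } else combination
}

#' Fuse selected modality blocks into one modelling matrix
#'
#' Concatenates the combination's blocks, restricting each block with a
#' selection report to its accepted features, and z-scores every column with
#' centre/scale fitted on the training rows only. All reports must carry the
#' same fold id; a mismatch aborts (leakage guard).
#'
#' @param blocks named list of full-cohort matrices (rows = patients).
#' @param reports named list of `selection_report`s (entries optional; a
#'   block without a report passes through unselected).
#' @param combination combination id (1-11) or registry entry.
#' @param train_ids row indices that define the z-scoring parameters
#'   (default: all rows).
#' @param fold_id fold context; checked against every report.
#' @return Numeric matrix with unique, block-prefixed column names and
#'   attributes `center`, `scale`, `block_map`, `fold_id`.
#' @export
fuse <- function(blocks, reports = list(), combination, train_ids = NULL,
                 fold_id = NA) {
  comb <- resolve_combination(combination)
  parts <- list()
  for (b in comb$blocks) {
    M <- blocks[[b]]
    if (is.null(M)) stop("missing block: ", b)
    M <- as.matrix(M)
    rep_b <- reports[[b]]
    if (!is.null(rep_b)) {
      if (!identical(rep_b$fold_id, fold_id))
        stop("selection/fold mismatch for block ", b)
      keep <- intersect(colnames(M), rep_b$accepted)
      M <- M[, keep, drop = FALSE]
    }
    parts[[b]] <- M
  }
  X <- do.call(cbind, parts)
  if (is.null(X) || ncol(X) == 0) stop("no features survived")
  if (anyDuplicated(colnames(X))) stop("fused column names must be unique")
  if (is.null(train_ids)) train_ids <- seq_len(nrow(X))
  ctr <- colMeans(X[train_ids, , drop = FALSE])
  scl <- apply(X[train_ids, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  attr(Xs, "block_map") <- rep(comb$blocks, vapply(parts, ncol, 0L))
  attr(Xs, "fold_id") <- fold_id
  Xs
}
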