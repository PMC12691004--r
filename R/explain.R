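# Explainability: permutation-sampling Shapley attributions for the stacked
# predictor (model-agnostic; TreeSHAP covers only the tree components) and
# Grad-CAM saliency for the frozen convolutional extractor via a logistic
# probe head on the GAP features.

#' Permutation-sampling SHAP attributions
#'
#' For each explained row, marginal contributions are accumulated along
#' `n_perm` random feature permutations against random background rows. The
#' telescoping sum along each permutation equals f(x) - f(background row)
#' exactly, so local additivity (base value + sum of attributions = model
#' output) holds to floating-point precision.
#'
#' @param predict_fun function(matrix) -> numeric predictions (e.g. wrap
#'   [predict.stacked_model()]).
#' @param X_background background matrix (training fold), non-empty.
#' @param X_explain rows to explain.
#' @param n_perm sampled permutations per row (default 64).
#' @param seed integer seed.
#' @return List of class `shap_report`: `phi` (rows x features), `base`
#'   (mean background prediction), `base_rows` (per-row mean prediction over
#'   the sampled background draws; `base_rows + rowSums(phi)` equals the
#'   model output exactly), `ranking` (features by mean |phi|).
#' @export
shap_attributions <- function(predict_fun, X_background, X_explain,
                              n_perm = 64, seed = 1) {
  X_background <- as.matrix(X_background)
  X_explain <- as.matrix(X_explain)
  if (nrow(X_background) == 0) stop("no background")
  p <- ncol(X_explain)
  phi <- matrix(0, nrow(X_explain), p,
                dimnames = list(rownames(X_explain), colnames(X_explain)))
  base_rows <- numeric(nrow(X_explain))
  run_with_seed(seed, {
    for (i in seq_len(nrow(X_explain))) {
      x <- X_explain[i, ]
      acc <- numeric(p)
      fb <- 0
      for (s in seq_len(n_perm)) {
        perm <- sample.int(p)
        bg <- X_background[sample.int(nrow(X_background), 1), ]
        # walk the permutation, switching coordinates from background to x;
        # evaluate all p+1 intermediate points in one batched call
        Z <- matrix(bg, p + 1, p, byrow = TRUE,
                    dimnames = list(NULL, colnames(X_explain)))
        for (j in seq_len(p)) Z[(j + 1):(p + 1), perm[j]] <- x[perm[j]]
        f <- predict_fun(Z)
        acc[perm] <- acc[perm] + diff(f)
        fb <- fb + f[1]
      }
      phi[i, ] <- acc / n_perm
      base_rows[i] <- fb / n_perm
    }
  })
  base <- mean(predict_fun(X_background))
  rk <- sort(colMeans(abs(phi)), decreasing = TRUE)
  structure(list(phi = phi, base = base, base_rows = base_rows, ranking = rk),
            class = "shap_report")
}

#' Logistic probe head on deep GAP features
#'
#' Fits an L2-regularised logistic regression on (selected) deep features to
#' provide the differentiable scalar head that Grad-CAM requires on top of
#' the frozen extractor.
#'
#' @param dlr_matrix patients x deep-feature matrix (named columns
#'   `dlr_<design>_conv<L>_<c>`).
#' @param labels binary outcome.
#' @param lambda ridge penalty (default 0.1).
#' @return List of class `dlr_probe` with per-feature weights and intercept.
#' @export
fit_dlr_probe <- function(dlr_matrix, labels, lambda = 0.1) {
  X <- as.matrix(dlr_matrix)
  fit <- glmnet::glmnet(X, as.numeric(as.logical(labels)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  w <- as.numeric(fit$beta)
  names(w) <- rownames(fit$beta)
  structure(list(weights = w, intercept = as.numeric(fit$a0)),
            class = "dlr_probe")
}

parse_probe_weights <- function(weights, layer_index, n_channels) {
  # channel weights of one conv layer from `..._conv<L>_<c>` names
  w <- numeric(n_channels)
  pat <- paste0("conv", layer_index, "_([0-9]+)$")
  hit <- grepl(pat, names(weights))
  ch <- as.integer(sub(paste0(".*", pat), "\\1", names(weights)[hit]))
  w[ch] <- weights[hit]
  w
}

#' Grad-CAM saliency map for one convolutional layer
#'
#' The scalar head is a logistic probe on the GAP features; the gradient of
#' its logit with respect to layer `layer_index`'s post-activation map is
#' taken through that layer's own GAP term, giving channel weights
#' w_c = probe_weight_c / (H W). The map is ReLU(sum_c w_c A_c), bilinearly
#' upsampled to the input resolution and normalised to [0, 1]; an all-zero
#' weighted map is returned as all zeros and flagged.
#'
#' @param extractor a [build_extractor()].
#' @param probe a [fit_dlr_probe()] (or any list with `weights` named like
#'   the deep features).
#' @param slice_input prepared input array from [prepare_slice()].
#' @param layer_index convolutional layer (1-13).
#' @return List of class `saliency_map`: `map` (input_size^2 matrix in
#'   [0, 1]), `layer`, `zero_gradient` flag.
#' @export
grad_cam <- function(extractor, probe, slice_input, layer_index) {
  if (!layer_index %in% 1:13) stop("no such layer")
  cfg <- extractor$config
  x <- slice_input
  A <- NULL
  for (l in 1:13) {
    x <- conv3x3(x, extractor$taps[[l]], extractor$layers[[l]]$b)
    if (l == layer_index) { A <- x; break }
    if (l %in% cfg$pool_after) x <- maxpool2(x)
  }
  d <- dim(A)
  w <- parse_probe_weights(probe$weights, layer_index, d[3]) / (d[1] * d[2])
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) if (w[c] != 0) cam <- cam + w[c] * A[, , c]
  cam[cam < 0] <- 0
  zero <- all(cam == 0)
  up <- bilinear_upsample(cam, cfg$input_size)
  if (!zero) up <- up / max(up)
  structure(list(map = up, layer = layer_index, zero_gradient = zero),
            class = "saliency_map")
}

bilinear_upsample <- function(m, size) {
  d <- dim(m)
  if (all(d == size)) return(m)
  # sample source coordinates at target pixel centres (align corners = FALSE)
  src <- function(n_src, n_dst) {
    s <- (seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5
    pmin(pmax(s, 1), n_src)
  }
  sx <- src(d[1], size); sy <- src(d[2], size)
  x0 <- pmin(floor(sx), d[1] - 1); y0 <- pmin(floor(sy), d[2] - 1)
  fx <- sx - x0; fy <- sy - y0
  m[x0, y0] * outer(1 - fx, 1 - fy) + m[x0 + 1, y0] * outer(fx, 1 - fy) +
    m[x0, y0 + 1] * outer(1 - fx, fy) + m[x0 + 1, y0 + 1] * outer(fx, fy)
}

#' Dice overlap between a saliency map's hottest pixels and a reference mask
#'
#' Thresholds the map at its `quantile` level (keeping the top (1-quantile)
#' fraction of pixels) and computes the Dice coefficient against the
#' reference mask slice.
#'
#' @param map a `saliency_map` or numeric matrix in [0, 1].
#' @param reference logical matrix (e.g. one slice of a [structure_mask()]),
#'   non-empty.
#' @param quantile threshold quantile (default 0.8).
#' @return Dice fraction in [0, 1].
#' @export
overlap_score <- function(map, reference, quantile = 0.8) {
  m <- if (inherits(map, "saliency_map")) map$map else map
  if (!any(reference)) stop("empty reference")
  if (!identical(dim(m), dim(reference))) stop("map and mask must be congruent")
  thr <- stats::quantile(m, quantile, names = FALSE)
  hot <- m > thr
  if (!any(hot)) hot <- m >= thr  # flat maps: fall back to >= so set non-empty
  inter <- sum(hot & reference)
  denom <- sum(hot) + sum(reference)
  2 * inter / denom
}
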