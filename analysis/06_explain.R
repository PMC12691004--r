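#!/usr/bin/env Rscript
# Explainability: permutation-SHAP attribution for the stacked model and
# Grad-CAM saliency for the dose-guided deep feature extractor.

suppressMessages(library(dosederm))
dir.create("results", showWarnings = FALSE)

co <- generate_cohort(cohort_config(
  n_patients = 148, seed = 1,
  betas = c(b0 = NA, age = 0.35, imn = 0.8, v25 = 1.0, texture = 0.3)))
y <- co$clinical$rd_grade_ge2
X <- fuse(list(clinical = encode_clinical(co$clinical), dvh = co$dvh),
          combination = 1)
inner <- lapply(1:5, function(f) {
  v <- seq(f, nrow(X), by = 5)
  list(train = setdiff(seq_len(nrow(X)), v), val = v)
})
model <- fit_stacked(X, y, search_space(10), inner, seed = 3)

sh <- shap_attributions(function(Z) predict(model, Z), X, X[1:40, ],
                        n_perm = 48, seed = 5)
rank_df <- data.frame(feature = names(sh$ranking),
                      mean_abs_phi = unname(sh$ranking))
cat("Top 10 features by mean |SHAP|:\n")
print(head(rank_df, 10), row.names = FALSE, digits = 3)
write.csv(rank_df, "results/shap_ranking.csv", row.names = FALSE)
write.csv(sh$phi, "results/shap_values.csv")

# Grad-CAM on one phantom, dose-guided input design
img <- generate_cohort(cohort_config(n_patients = 10, seed = 2), images = TRUE)
p <- img$patients[[1]]
rois <- build_roi_set(p$ct, p$dose_on_ct, p$ptv, 50)
cfg <- extractor_config(input_size = 96)
ex <- build_extractor(cfg, seed = 7)
dlr <- t(vapply(img$patients, function(q) {
  r <- build_roi_set(q$ct, q$dose_on_ct, q$ptv, 50)
  extract_dlr(q$ct, ex, input_design("v5gy", roi = r$v5gy))
}, numeric(4224)))
probe <- fit_dlr_probe(dlr, img$clinical$rd_grade_ge2, lambda = 0.5)

iz <- which.max(apply(rois$v5gy$mask, 3, sum))
x <- prepare_slice(p$ct$values[, , iz],
                   input_design("v5gy", roi = rois$v5gy), cfg,
                   roi_slice = rois$v5gy$mask[, , iz])
for (layer in c(2, 5, 9)) {
  cam <- grad_cam(ex, probe, x, layer_index = layer)
  dice <- overlap_score(cam$map, rois$v5gy$mask[, , iz], quantile = 0.8)
  cat(sprintf("layer %2d: Dice(top-20%% heat, V5Gy skin ROI) = %.3f%s\n",
              layer, dice, if (cam$zero_gradient) " [zero gradient]" else ""))
  write.csv(cam$map, sprintf("results/gradcam_layer%02d.csv", layer))
  png(sprintf("results/gradcam_layer%02d.png", layer), 480, 480)
  image(cam$map, col = hcl.colors(64, "inferno"), axes = FALSE,
        main = sprintf("Grad-CAM, conv layer %d (dose-guided input)", layer))
  contour(matrix(as.numeric(rois$v5gy$mask[, , iz]), 96), levels = 0.5,
          add = TRUE, col = "white", drawlabels = FALSE)
  dev.off()
}
cat("Wrote SHAP tables and Grad-CAM maps under results/\n")
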