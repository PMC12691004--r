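#!/usr/bin/env Rscript
# Feature extraction on the image phantoms: read the DICOM cohort back,
# build the ROI set (body, skin5mm, >= 5 Gy isodose, dose-guided skin ROI),
# and extract DVH, handcrafted and deep feature blocks.

suppressMessages(library(dosederm))
dir.create("results", showWarnings = FALSE)

root <- "results/dicom_cohort"
if (!dir.exists(root)) stop("run analysis/01_simulate_cohort.R first")
manifest <- jsonlite::read_json(file.path(root, "manifest.json"))
patients <- unlist(manifest$patients)

cfg_dlr <- extractor_config(input_size = 96)
extractor <- build_extractor(cfg_dlr, seed = 7)

dvh_rows <- list(); hcr_rows <- list(); dlr_rows <- list()
for (pid in patients) {
  ct <- read_ct_series(file.path(root, pid, "CT"))
  dose <- read_rtdose(file.path(root, pid, "dose.dcm"))
  strs <- read_rtstruct(file.path(root, pid, "struct.dcm"), ct)
  dose_ct <- resample_dose_to_ct(dose, ct)
  rois <- build_roi_set(ct, dose_ct, strs$ptv, prescription = 50)
  dvh_rows[[pid]] <- compute_dvh_features(dose_ct, rois, 50)
  hcr_rows[[pid]] <- extract_hcr(ct, rois$skin5mm, hcr_params())
  dlr_rows[[pid]] <- extract_dlr(ct, extractor,
                                 input_design("v5gy", roi = rois$v5gy))
  cat(sprintf("%s: skin5mm %.1f cc, V5Gy ROI %d voxels, %d eligible slices\n",
              pid, voxel_volume_cc(ct) * sum(rois$skin5mm$mask),
              sum(rois$v5gy$mask), attr(dlr_rows[[pid]], "n_slices")))
}

write.csv(do.call(rbind, dvh_rows), "results/features_dvh.csv")
write.csv(do.call(rbind, hcr_rows), "results/features_hcr_skin5mm.csv")
write.csv(do.call(rbind, dlr_rows), "results/features_dlr_v5gy.csv")
jsonlite::write_json(
  list(weights_mode = cfg_dlr$weights_mode, seed = 7,
       input_size = cfg_dlr$input_size,
       n_slices = lapply(dlr_rows, attr, "n_slices")),
  "results/dlr_extraction_manifest.json", auto_unbox = TRUE, pretty = TRUE)
cat("Wrote DVH (12), HCR (105) and deep (4224) feature tables under results/\n")
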