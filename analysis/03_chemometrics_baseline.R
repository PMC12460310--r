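#!/usr/bin/env Rscript
# Stage 3 - chemometric baselines.
#
# PLS-DA (2 latent variables, the visualization setting) on the raw spectra
# with VIP scores, and PCA of the mineral-element panel. Writes score and
# VIP tables under results/chemometrics/.

library(fcbtrace)

set <- read_spectra_csv("results/data/spectra.csv")
out <- "results/chemometrics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fit <- plsda_fit(set$reflectance, set$labels, n_lv = 2)
pred <- plsda_predict(fit, set$reflectance)
acc <- mean(as.character(pred$class) == as.character(set$labels))
message(sprintf("PLS-DA (2 LVs) training accuracy: %.1f%%", 100 * acc))

utils::write.csv(
  data.frame(sample_id = set$sample_id, class = as.character(set$labels),
             LV1 = fit$scores[, 1], LV2 = fit$scores[, 2],
             predicted = as.character(pred$class)),
  file.path(out, "plsda_scores.csv"), row.names = FALSE)

vip <- vip_scores(fit)
utils::write.csv(
  data.frame(wavelength_nm = set$wavelengths_nm, vip = vip,
             selected = vip > 1),
  file.path(out, "vip.csv"), row.names = FALSE)
message(sprintf("%d of %d wavelengths have VIP > 1", sum(vip > 1),
                length(vip)))

elements <- utils::read.csv("results/data/elements.csv")
E <- do.call(cbind, split(elements$value, elements$analyte))
pca <- pca_scores(E, k = 2, scale = TRUE)
cls <- elements$class[!duplicated(elements$sample_id)]
utils::write.csv(
  data.frame(class = cls, PC1 = pca$scores[, 1], PC2 = pca$scores[, 2]),
  file.path(out, "element_pca_scores.csv"), row.names = FALSE)
message(sprintf("element PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pca$explained[1], 100 * pca$explained[2]))
message("stage 3 complete: results/chemometrics/")
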