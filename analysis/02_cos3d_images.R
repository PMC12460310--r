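#!/usr/bin/env Rscript
# Stage 2 - synchronous correlation images.
#
# Reads the simulated spectra, computes the full-set synchronous 3DCOS map
# (the covariance-like phi(v1, v2) over all 90 bulbs) and one rank-1
# per-sample map per bulb against the global mean spectrum, and exports a
# few rendered PNGs for inspection. The pipeline proper recomputes
# per-sample images against the *training-set* mean inside stage 4; this
# stage documents what the maps look like.

library(fcbtrace)

set <- read_spectra_csv("results/data/spectra.csv")
out <- "results/cos3d"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dyn <- dynamic_spectra(set)
full <- synchronous_map(dyn)
print(full)
utils::write.csv(
  data.frame(wavelength_nm = full$wavelengths_nm,
             diag_intensity = diag(full$phi)),
  file.path(out, "sync_diagonal.csv"), row.names = FALSE)

spec <- render_spec(656, 656, normalization = "per-image")
export_map_png(render_map(full, spec), file.path(out, "sync_full_set.png"),
               colormap = "viridis")

# one per-sample image per class, shared global intensity scale
ref <- colMeans(set$reflectance)
imgs <- cos_images(set, ref, size = 224L)
first_of <- match(levels(set$labels), as.character(set$labels))
for (i in first_of) {
  export_map_png(imgs$images[, , i],
                 file.path(out, sprintf("sample_%s.png",
                                        gsub("[^A-Za-z0-9]", "_",
                                             as.character(set$labels)[i]))),
                 colormap = "viridis")
}
message(sprintf("rendered full-set map and %d per-class sample images (intensity limits %.4g..%.4g)",
                length(first_of), imgs$limits[1], imgs$limits[2]))
message("stage 2 complete: results/cos3d/")
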