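#!/usr/bin/env Rscript
# Stage 2 — pixel-level PCA variance accounting.
#
# Pools the pixel spectra of each species and fits a 6-component PCA,
# mirroring the per-image variance accounting of hyperspectral plant scans:
# PC1 captures overall brightness/structure contrast, PC2 morphological
# variability. Writes the per-species explained/cumulative variance table
# and the pooled (t1, t2) score scatter with point densities.

library(weedspec)

seed <- 1
dir.create("results", showWarnings = FALSE)
cohort <- generate_cohort(roi_counts = weed_roi_counts(), seed = seed)

rows <- lapply(weed_species(), function(sp) {
  px <- cohort_pixels(cohort, species = sp, max_pixels = 2000, seed = seed)
  m <- fit_pixel_pca(px, k = 6)
  ev <- explained_variance(m)
  data.frame(species = sp, component = 1:6, eigenvalue = m$eigenvalues,
             explained_pct = ev,
             cumulative_pct = cumsum(ev))
})
var_tab <- do.call(rbind, rows)
write.table(var_tab, "results/pca_variance_by_species.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pooled <- fit_pixel_pca(cohort_pixels(cohort, max_pixels = 5000,
                                      seed = seed), k = 6)
scatter <- variance_scatter(pooled)
write.table(scatter, "results/pca_scatter.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pc1 <- var_tab$explained_pct[var_tab$component == 1]
cat(sprintf("per-species PC1 explained variance: %.1f-%.1f%% (mean %.1f%%)\n",
            min(pc1), max(pc1), mean(pc1)))
cat(sprintf("pooled cumulative variance at PC2: %.2f%%\n",
            cumulative_variance(pooled, 2)))
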