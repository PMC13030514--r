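#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the nine-species cohort the rest of the workflow analyses:
# 25 plants per species, per-species ROI totals as reported for the imaging
# campaign (601 ROIs overall, >= 50 pure pixels each), 61-band 400-1000 nm
# grid, and the default pixel/plant noise model. Writes the ROI mean-spectrum
# table and a design summary under results/.

library(weedspec)

seed <- 1
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(roi_counts = weed_roi_counts(), seed = seed)
tab <- roi_table(cohort)

write_roi_table(tab, "results/cohort_rois.tsv")
design <- aggregate(pixel_count ~ species + part, tab, length)
names(design)[3] <- "n_rois"
write.table(design[order(design$species, design$part), ],
            "results/cohort_design.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("cohort:", nrow(tab), "ROIs from", length(unique(tab$plant_id)),
    "plants across", length(unique(tab$species)), "species\n")
cat("per-species ROI counts match the study design:",
    all(table(tab$species)[names(weed_roi_counts())] == weed_roi_counts()),
    "\n")
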