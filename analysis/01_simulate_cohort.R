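#!/usr/bin/env Rscript
# Simulate the reference synthetic cohort: 38 subjects aged 7-17, both
# hemispheres, rhinal + collateral sulcal masks on a shared 1 mm grid,
# with conformation types drawn at the cohort's Type-1 rate and
# inter-hemispheric concordance. Writes the cohort and morphometry tables
# and a per-structure mask inventory under results/.

library(mtlatlas)

seed <- 1L
out <- file.path("results", "01_simulate")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_subjects = 38, seed = seed)
sim <- generate_cohort(cfg)

write_cohort_table(sim$cohort, file.path(out, "cohort.tsv"))
write_morphometry_table(sim$morphometry, file.path(out, "morphometry.tsv"))

inventory <- do.call(rbind, lapply(sim$masks, function(m)
  data.frame(subject_id = m$subject_id, hemisphere = m$hemisphere,
             structure = m$structure,
             conformation_type = m$conformation_type,
             n_voxels = sum(m$volume$data))))
write.table(inventory, file.path(out, "mask_inventory.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

types <- summarize_types(sim$cohort)
cat(sprintf("Simulated %d subjects (%d hemisphere rows).\n",
            cfg$n_subjects, nrow(sim$cohort)))
print(types)
cat(sprintf("Median mask size: %d voxels; all subjects classified: %s\n",
            round(median(inventory$n_voxels)),
            all(inventory$conformation_type %in% c(1, 2))))
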