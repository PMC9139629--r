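#!/usr/bin/env Rscript
# Step 1: simulate the paired synthetic cohort.
#
# Generates 17 patients, each with 3DCRT, IMRT and PBS plans for five
# thoracic organs at risk, prescriptions drawn from the tabulated
# 45-66 Gy / 25-33 fx support, and writes the DVH files plus manifest
# under results/cohort/. Everything downstream reads that manifest.

library(smrisk)

seed <- 1L
spec <- cohort_spec(n_patients = 17L, seed = seed)
cohort <- generate_cohort(spec)
manifest <- write_cohort(cohort, "results/cohort")

cat("Simulated cohort (seed", seed, "):\n")
print(cohort)
cat("Manifest:", manifest, "\n")

# quick structural sanity: shared prescription within patient, paired plans
rx <- sapply(cohort$patients, function(p) cohort$meta[[p]][["3DCRT"]]$prescription_dose)
cat("Prescriptions [Gy]:", paste(rx, collapse = " "),
    "\n  median:", median(rx), "Gy\n")
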