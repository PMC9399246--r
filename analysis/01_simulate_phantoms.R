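#!/usr/bin/env Rscript
# Simulate the study inputs: a labelled set of frontal torso surface renders
# (normal and anomalous phantoms) and a longitudinal anomaly-score cohort.
suppressPackageStartupMessages(library(anoscore))

dir.create("results", showWarnings = FALSE)

ds <- generate_image_dataset(n_normal = 48, n_anomalous_per_kind = 4,
                             spec_template = phantom_spec(image_size = 48,
                                                          severity = 1),
                             seed = 2026)
write_image_dataset(ds, "results/images")
cat(sprintf("wrote %d images (%d normal, %d anomalous) to results/images\n",
            length(ds$images), sum(ds$labels == "normal"),
            sum(ds$labels != "normal")))

cohort <- generate_cohort(cohort_gen_spec(n_patients = 61, seed = 2026))
write_cohort_csv(cohort, "results/cohort.csv")
cat(sprintf("wrote cohort of %d patients (%d rows) to results/cohort.csv\n",
            length(unique(cohort$patient_id)), nrow(cohort)))
cat(sprintf("expander fraction: %.2f, hypofractionated: %.2f\n",
            mean(cohort$recon_type[cohort$visit == "pre_rt"] == "expander"),
            mean(cohort$fractionation[cohort$visit == "pre_rt"] == "hypo")))
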