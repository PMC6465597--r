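#!/usr/bin/env Rscript
# Simulate the synthetic cohort: an early image-identity signal shared by
# both memorability conditions, plus a dispersion difference (high-memorable
# exemplar prototypes more spread out) confined to 149-228 ms. Writes one
# epochs container per subject and the ground-truth geometry.

source("analysis/_common.R")

message("Simulating ", cohort_cfg$n_subjects, " subjects (",
        cohort_cfg$n_high + cohort_cfg$n_low, " images, ",
        cohort_cfg$n_trials_per_image, " trials/image, ",
        cohort_cfg$n_channels, " channels @ ", cohort_cfg$sampling_rate, " Hz)")

cohort <- simulate_cohort(cohort_cfg)

for (ep in cohort$subjects)
  write_epochs(ep, epochs_file(ep$subject_id), overwrite = TRUE)

jsonlite::write_json(
  list(effect_window_ms = cohort$truth$effect_window,
       sigma_high = cohort$truth$sigma_high,
       sigma_low = cohort$truth$sigma_low,
       sigma_id = cohort$truth$sigma_id,
       condition_of = cohort$truth$condition_of,
       seed = cohort$truth$seed,
       subject_seeds = cohort$subject_seeds),
  file.path(paths$data, "ground_truth.json"),
  auto_unbox = TRUE, digits = NA)

hi <- cohort$truth$condition_of == "high"
d2 <- function(m) mean(as.matrix(dist(m))[lower.tri(diag(nrow(m)))]^2)
message(sprintf(
  "Mean squared within-condition prototype distance: high %.1f, low %.1f (ratio %.1f)",
  d2(cohort$truth$v[hi, ]), d2(cohort$truth$v[!hi, ]),
  d2(cohort$truth$v[hi, ]) / d2(cohort$truth$v[!hi, ])))
message("Epochs written to ", paths$data)
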