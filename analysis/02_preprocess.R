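#!/usr/bin/env Rscript
# Epoch-domain preprocessing: baseline mean removal, zero-phase 20 Hz
# low-pass, 6000-unit amplitude rejection, PCA blink projection. Writes
# cleaned containers and a per-subject loss report.

source("analysis/_common.R")

params <- preproc_params()
report <- list()

for (id in subject_ids) {
  ep <- read_epochs(epochs_file(id))
  out <- preprocess_epochs(ep, params)
  write_epochs(out$epochs, epochs_file(id, paths$preproc), overwrite = TRUE)
  report[[id]] <- list(
    n_trials_in = out$report$n_trials_in,
    n_rejected = out$report$n_rejected,
    fraction_lost = out$report$fraction_lost,
    blink_events = out$report$blink$n_events
  )
  message(sprintf("%s: %d/%d trials rejected (%.1f%%), %s blink events",
                  id, out$report$n_rejected, out$report$n_trials_in,
                  100 * out$report$fraction_lost,
                  out$report$blink$n_events))
}

jsonlite::write_json(report, file.path(paths$preproc, "preproc_report.json"),
                     auto_unbox = TRUE, digits = NA)
lost <- vapply(report, function(x) x$fraction_lost, numeric(1))
message(sprintf("Trial loss across subjects: max %.2f%% (target: < 5%%)",
                100 * max(lost)))
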