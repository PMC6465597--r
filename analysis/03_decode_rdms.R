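#!/usr/bin/env Rscript
# Time-resolved pairwise decoding: sub-average trials into pseudo-trials
# (groups of 5), leave-one-out linear-SVM accuracy for every image pair at
# every time point, averaged over repetitions, giving one K x K decoding
# matrix (RDM) per time point per subject.

source("analysis/_common.R")

seeds <- local({ set.seed(global_seed); sample.int(2^31 - 2, length(subject_ids)) })

for (i in seq_along(subject_ids)) {
  id <- subject_ids[i]
  ep <- read_epochs(epochs_file(id, paths$preproc))
  p <- decode_cfg
  p$seed <- seeds[i]
  t0 <- Sys.time()
  rdm <- build_rdm_series(ep, p)
  write_rdm_series(rdm, file.path(paths$rdm, paste0(id, ".csv")))
  grand <- mean(attr(rdm, "rep_grand_mean"))
  message(sprintf("%s: grand-mean pairwise accuracy %.1f%% (%.0f s)",
                  id, grand, as.numeric(Sys.time() - t0, units = "secs")))
}
message("RDM series written to ", paths$rdm)
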