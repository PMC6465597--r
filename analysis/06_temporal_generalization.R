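#!/usr/bin/env Rscript
# Temporal generalization: classifiers trained at time t are tested at every
# time t', per within-condition image pair, averaged within condition and
# across subjects; 2-D cluster-size permutation tests mark where decoding
# generalizes above chance and where the conditions differ.

source("analysis/_common.R")

seeds <- local({ set.seed(global_seed + 1L); sample.int(2^31 - 2, length(subject_ids)) })
p <- decode_cfg
p$repetitions <- 1L   # one sub-averaging draw per subject keeps this stage tractable

tg <- lapply(seq_along(subject_ids), function(i) {
  ep <- read_epochs(epochs_file(subject_ids[i], paths$preproc))
  p$seed <- seeds[i]
  out <- subject_tempgen(ep, p)
  message(subject_ids[i], " done")
  out
})
times <- tg[[1]]$times
n_t <- length(times)

summarize <- function(arr, chance, label) {
  cr <- cluster_test_2d(arr, chance, stats_cfg, times)
  sig <- which(cr$significant)
  if (length(sig)) {
    for (j in sig) {
      rc <- arrayInd(cr$clusters[[j]], c(n_t, n_t))
      message(sprintf(
        "%s: cluster of %d points, train %g..%g ms / test %g..%g ms (p = %.3g)",
        label, cr$sizes[j], times[min(rc[, 1])], times[max(rc[, 1])],
        times[min(rc[, 2])], times[max(rc[, 2])], cr$p_values[j]))
    }
  } else message(label, ": no significant cluster")
  cr
}

for (tag in c("high", "low")) {
  arr <- array(0, c(length(tg), n_t, n_t))
  for (i in seq_along(tg)) arr[i, , ] <- tg[[i]][[tag]]
  grand <- apply(arr, c(2, 3), mean)
  write.csv(grand, file.path(paths$tables, sprintf("tempgen_%s.csv", tag)),
            row.names = FALSE)
  cr <- summarize(arr, 50, paste(tag, "vs chance"))
  write.csv(which(cr$sig_mask, arr.ind = TRUE),
            file.path(paths$tables, sprintf("tempgen_%s_sig.csv", tag)),
            row.names = FALSE)
}

darr <- array(0, c(length(tg), n_t, n_t))
for (i in seq_along(tg)) darr[i, , ] <- tg[[i]]$high - tg[[i]]$low
invisible(summarize(darr, 0, "high - low"))
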