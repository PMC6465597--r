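#!/usr/bin/env Rscript
# Within-condition decoding time courses: average the RDM entries over
# within-high and within-low image pairs separately, test each against the
# 50% chance level and their difference against 0 with cluster-size
# permutation tests, and bootstrap the peak latencies.

source("analysis/_common.R")

rdms <- lapply(subject_ids, function(id)
  read_rdm_series(file.path(paths$rdm, paste0(id, ".csv"))))
tc <- lapply(rdms, condition_mean_timecourses)
times <- rdms[[1]]$times

mats <- lapply(c(high = "high", low = "low", difference = "difference"),
               function(tag) do.call(rbind, lapply(tc, function(x) x[[tag]]$accuracy)))

rows <- list()
for (tag in names(mats)) {
  chance <- if (tag == "difference") 0 else 50
  cr <- cluster_test_1d(mats[[tag]], chance, stats_cfg, times)
  pk <- bootstrap_peak_latency(mats[[tag]], times, stats_cfg)
  sig <- which(cr$significant)
  for (i in seq_along(cr$sizes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      curve = tag, chance = chance,
      onset_ms = times[min(cr$clusters[[i]])],
      offset_ms = times[max(cr$clusters[[i]])],
      size = cr$sizes[i], p = cr$p_values[i],
      significant = cr$significant[i],
      peak_ms = pk$peak_ms, peak_ci_low = pk$ci_ms[1], peak_ci_high = pk$ci_ms[2]
    )
  }
  msg <- if (length(sig))
    sprintf("%s; peak %g ms [%g, %g]",
            paste(sprintf("%g..%g ms (p = %.3g)",
                          vapply(sig, function(j) times[min(cr$clusters[[j]])], 1),
                          vapply(sig, function(j) times[max(cr$clusters[[j]])], 1),
                          cr$p_values[sig]), collapse = ", "),
            pk$peak_ms, pk$ci_ms[1], pk$ci_ms[2])
  else "no significant cluster"
  message(sprintf("%s (vs %g): %s", tag, chance, msg))
}

write.csv(do.call(rbind, rows),
          file.path(paths$tables, "condition_clusters.csv"), row.names = FALSE)

group <- data.frame(time_ms = times,
                    high = colMeans(mats$high), low = colMeans(mats$low),
                    difference = colMeans(mats$difference))
write.csv(group, file.path(paths$tables, "group_timecourses.csv"),
          row.names = FALSE)
message("Tables written to ", paths$tables)
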