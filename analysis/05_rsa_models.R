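#!/usr/bin/env Rscript
# Representational similarity analysis: compare the measured RDM series
# against two hypothesis geometries — a categorical model (conditions
# linearly separable) and a dispersion model (high-memorable exemplars more
# spread out around a shared centroid) — via per-subject Spearman rho, with
# group cluster inference on each rho time course. Also embeds the
# window-averaged group RDM in 2-D (classical MDS) for visualization.

source("analysis/_common.R")

rdms <- lapply(subject_ids, function(id)
  read_rdm_series(file.path(paths$rdm, paste0(id, ".csv"))))
times <- rdms[[1]]$times
cond <- rdms[[1]]$condition_of

models <- list(categorical = categorical_model(cond),
               dispersion = dispersion_model(cond))

rho_tabs <- list()
for (name in names(models)) {
  rho <- do.call(rbind, lapply(rdms, function(r)
    rsa_correlate(r, models[[name]])$accuracy))
  cr <- cluster_test_1d(rho, 0, stats_cfg, times)
  sig <- which(cr$significant)
  message(sprintf("%s model: %s", name,
                  if (length(sig))
                    paste(sprintf("significant cluster %g..%g ms (p = %.3g)",
                                  vapply(sig, function(j) times[min(cr$clusters[[j]])], 1),
                                  vapply(sig, function(j) times[max(cr$clusters[[j]])], 1),
                                  cr$p_values[sig]), collapse = ", ")
                  else "no significant cluster"))
  rho_tabs[[name]] <- data.frame(time_ms = times, model = name,
                                 mean_rho = colMeans(rho),
                                 sig = seq_along(times) %in%
                                   unlist(cr$clusters[cr$significant]))
}
write.csv(do.call(rbind, rho_tabs), file.path(paths$tables, "rsa_rho.csv"),
          row.names = FALSE)

# window-averaged group RDM -> 2-D geometry
win <- cohort_cfg$effect_window
sel <- times >= win[1] & times <= win[2]
grand <- Reduce(`+`, lapply(rdms, function(r)
  apply(r$values[sel, , , drop = FALSE], c(2, 3), mean))) / length(rdms)
xy <- mds_embed(grand)
write.csv(data.frame(image_id = rdms[[1]]$image_ids, condition = cond,
                     dim1 = xy[, 1], dim2 = xy[, 2]),
          file.path(paths$tables, "mds_window.csv"), row.names = FALSE)
hi <- cond == "high"
spread <- function(m) mean(sqrt(rowSums(sweep(m, 2, colMeans(m))^2)))
message(sprintf("MDS spread in %g..%g ms window: high %.2f vs low %.2f",
                win[1], win[2], spread(xy[hi, ]), spread(xy[!hi, ])))
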