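# Reduced-scale study cohorts shared by the recovery checks. The cohort
# keeps the generator's default signal geometry, scales and effect window and
# shrinks only problem sizes (subjects, images, trials, sampling rate,
# repetitions) so a full simulate -> preprocess -> decode -> RSA -> stats
# cycle stays at desk scale.

reduced_cohort_config <- function(seed) {
  synth_config(n_subjects = 15, n_high = 5, n_low = 5,
               n_trials_per_image = 20, n_channels = 64,
               sampling_rate = 100, seed = seed)
}

run_reduced_cohort <- function(seed) {
  cfg <- reduced_cohort_config(seed)
  cohort <- simulate_cohort(cfg)
  dparams <- decode_params(group_size = 5, repetitions = 2, seed = seed)
  rdms <- lapply(cohort$subjects, function(ep) {
    pp <- preprocess_epochs(ep)
    build_rdm_series(pp$epochs, dparams)
  })
  tc <- lapply(rdms, condition_mean_timecourses)
  times <- rdms[[1]]$times
  disp <- dispersion_model(rdms[[1]]$condition_of)
  cat_m <- categorical_model(rdms[[1]]$condition_of)
  list(
    times = times,
    effect_window = cfg$effect_window,
    high = do.call(rbind, lapply(tc, function(x) x$high$accuracy)),
    low = do.call(rbind, lapply(tc, function(x) x$low$accuracy)),
    difference = do.call(rbind, lapply(tc, function(x) x$difference$accuracy)),
    rho_dispersion = do.call(rbind, lapply(rdms, function(r)
      rsa_correlate(r, disp)$accuracy)),
    rho_categorical = do.call(rbind, lapply(rdms, function(r)
      rsa_correlate(r, cat_m)$accuracy))
  )
}

# Cache: both recovery checks consume the same 20 cohorts.
.cohort_cache <- new.env(parent = emptyenv())

recovery_cohorts <- function(n_cohorts = 20) {
  key <- as.character(n_cohorts)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- lapply(seq_len(n_cohorts) * 101L, run_reduced_cohort)
  .cohort_cache[[key]]
}

# TRUE if any significant cluster of `cr` overlaps [win[1], win[2]] ms.
any_cluster_overlaps <- function(cr, times, win) {
  hit <- FALSE
  for (i in seq_along(cr$clusters)) {
    if (!cr$significant[i]) next
    t_ext <- times[range(cr$clusters[[i]])]
    if (t_ext[1] <= win[2] && t_ext[2] >= win[1]) hit <- TRUE
  }
  hit
}
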