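# Shared configuration of the analysis workflow. All drivers source this
# file; everything downstream of it is a pure function of `global_seed`.

library(memdecode)

global_seed <- 20260921L

paths <- list(
  data = "results/data",
  preproc = "results/preproc",
  rdm = "results/rdm",
  tables = "results/tables"
)
invisible(lapply(paths, dir.create, recursive = TRUE, showWarnings = FALSE))

# Desk-scale cohort: the study design (15 subjects, high/low image split,
# effect window 149-228 ms) with problem sizes reduced for a laptop run.
cohort_cfg <- synth_config(
  n_subjects = 15, n_high = 5, n_low = 5, n_trials_per_image = 20,
  n_channels = 64, sampling_rate = 100, seed = global_seed
)

decode_cfg <- decode_params(group_size = 5, repetitions = 5, seed = global_seed)
stats_cfg <- stat_params(n_perm = 1000, cdt = 0.05, alpha = 0.05,
                         seed = global_seed)

subject_ids <- sprintf("sub-%02d", seq_len(cohort_cfg$n_subjects))
epochs_file <- function(id, dir = paths$data) file.path(dir, paste0(id, ".h5"))
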