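#' Assemble an end-to-end pipeline configuration
#'
#' Bundles the stage configurations with the analysis list, output directory
#' and the single global seed from which every stage seed is derived
#' (global -> subject -> repetition -> permutation), so any stage can be
#' re-run in isolation reproducibly.
#'
#' @param synth A [synth_config()] (its `seed` is overridden by `seed`).
#' @param preproc A [preproc_params()].
#' @param decode A [decode_params()].
#' @param stats A [stat_params()].
#' @param analyses Character vector drawn from `"rdm"`, `"condition_means"`,
#'   `"rsa_categorical"`, `"rsa_dispersion"`, `"tempgen"`, `"mds"`, and
#'   `"roi:<group>"` entries.
#' @param out_dir Output directory for the report bundle.
#' @param seed Global integer seed.
#' @param figures Also render PNG figures (requires ggplot2)? Default `FALSE`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), preproc = preproc_params(),
                            decode = decode_params(), stats = stat_params(),
                            analyses = c("rdm", "condition_means",
                                         "rsa_categorical", "rsa_dispersion"),
                            out_dir = "pipeline_out", seed = 1L,
                            figures = FALSE) {
  known <- c("rdm", "condition_means", "rsa_categorical", "rsa_dispersion",
             "tempgen", "mds")
  bad <- analyses[!(analyses %in% known | startsWith(analyses, "roi:"))]
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, preproc = preproc, decode = decode,
                 stats = stats, analyses = analyses, out_dir = out_dir,
                 seed = as.integer(seed), figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `seed`, `out_dir`, `analyses`, `figures` plus nested
#' sections `synth`, `preproc`, `decode`, `stats` whose entries are passed to
#' the respective constructors.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(f, args) do.call(f, if (is.null(args)) list() else args)
  pipeline_config(
    synth = build(synth_config, y$synth),
    preproc = build(preproc_params, y$preproc),
    decode = build(decode_params, y$decode),
    stats = build(stat_params, y$stats),
    analyses = if (is.null(y$analyses)) c("rdm", "condition_means") else unlist(y$analyses),
    out_dir = if (is.null(y$out_dir)) "pipeline_out" else y$out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed,
    figures = isTRUE(y$figures)
  )
}

cluster_summary <- function(cr, times) {
  lapply(seq_along(cr$sizes), function(i) {
    idx <- cr$clusters[[i]]
    out <- list(size = unname(cr$sizes[i]), p = unname(cr$p_values[i]),
                significant = unname(cr$significant[i]))
    if (is.null(cr$dims)) {
      out$onset_ms <- times[min(idx)]
      out$offset_ms <- times[max(idx)]
    } else {
      rc <- arrayInd(idx, cr$dims)
      out$train_ms <- c(times[min(rc[, 1L])], times[max(rc[, 1L])])
      out$test_ms <- c(times[min(rc[, 2L])], times[max(rc[, 2L])])
    }
    out
  })
}

peak_summary <- function(samples, times, params) {
  pk <- bootstrap_peak_latency(samples, times, params)
  list(peak_ms = pk$peak_ms, ci_low_ms = pk$ci_ms[1L], ci_high_ms = pk$ci_ms[2L],
       flat_peak = pk$flat_peak)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, preprocesses every subject, decodes the requested
#' channel sets into RDM series, and runs the requested representational and
#' inferential analyses, writing every artifact (tables, cluster summaries,
#' MDS coordinates, a machine-readable `summary.json` and a `report.md`) into
#' `config$out_dir`. Each output names the seed and parameters that produced
#' it; two runs with the same configuration produce byte-identical summaries.
#'
#' @param config A [pipeline_config()] object.
#' @return The report bundle (the summary list), invisibly; side effect is
#'   the populated output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("simulate", simulate_cohort(config$synth))
  n_subj <- length(cohort$subjects)
  truth_meta <- list(effect_window_ms = cohort$truth$effect_window,
                     sigma_high = cohort$truth$sigma_high,
                     sigma_low = cohort$truth$sigma_low,
                     condition_of = cohort$truth$condition_of,
                     seed = cohort$truth$seed)
  jsonlite::write_json(truth_meta, file.path(config$out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  clean <- stage("preprocess", lapply(cohort$subjects, function(ep)
    preprocess_epochs(ep, config$preproc)))
  epochs <- lapply(clean, `[[`, "epochs")
  times <- epochs[[1L]]$times

  decode_seeds <- with_seed_(config$seed,
                             sample.int(.Machine$integer.max - 1L, n_subj))
  decode_for <- function(channels) {
    lapply(seq_len(n_subj), function(i) {
      p <- config$decode
      p$channels <- channels
      p$seed <- decode_seeds[i]
      build_rdm_series(epochs[[i]], p)
    })
  }

  summary <- list(seed = config$seed, analyses = list(),
                  parameters = list(
                    synth = unclass(config$synth),
                    preproc = unclass(config$preproc),
                    decode = unclass(config$decode),
                    stats = unclass(config$stats)),
                  preprocessing = list(
                    fraction_lost = vapply(clean, function(x) x$report$fraction_lost,
                                           numeric(1))))

  wants <- function(a) a %in% config$analyses
  need_rdm <- any(c("rdm", "condition_means", "rsa_categorical",
                    "rsa_dispersion", "mds") %in% config$analyses)
  rdms <- NULL
  if (need_rdm) {
    rdms <- stage("decode", decode_for(config$decode$channels))
    if (wants("rdm")) {
      for (i in seq_len(n_subj))
        write_rdm_series(rdms[[i]], file.path(config$out_dir,
                                              sprintf("rdm_%s.csv", rdms[[i]]$subject_id)))
      summary$analyses$rdm <- list(n_subjects = n_subj, K = length(rdms[[1L]]$image_ids))
    }
  }

  condition_block <- function(rdm_list, label) {
    tc <- lapply(rdm_list, condition_mean_timecourses)
    mats <- lapply(c("high", "low", "difference"), function(tag)
      do.call(rbind, lapply(tc, function(x) x[[tag]]$accuracy)))
    names(mats) <- c("high", "low", "difference")
    tab <- do.call(rbind, lapply(seq_along(tc), function(i)
      do.call(rbind, lapply(tc[[i]], function(x)
        data.frame(subject = x$subject_id, tag = x$tag,
                   time_ms = x$times, value = x$accuracy)))))
    utils::write.csv(tab, file.path(config$out_dir,
                                    sprintf("timecourses_%s.csv", label)),
                     row.names = FALSE)
    sp <- config$stats
    res <- list()
    for (tag in c("high", "low", "difference")) {
      chance <- if (tag == "difference") 0 else 50
      cr <- stage(paste0("stats:", label, ":", tag),
                  cluster_test_1d(mats[[tag]], chance, sp, times))
      res[[tag]] <- list(chance = chance,
                         clusters = cluster_summary(cr, times),
                         peak = peak_summary(mats[[tag]], times, sp),
                         group_mean = unname(colMeans(mats[[tag]])))
    }
    res$times_ms <- times
    res
  }

  if (wants("condition_means") && !is.null(rdms))
    summary$analyses$condition_means <- stage("condition_means",
                                              condition_block(rdms, "sensor"))

  for (model_name in c("categorical", "dispersion")) {
    key <- paste0("rsa_", model_name)
    if (!wants(key) || is.null(rdms)) next
    summary$analyses[[key]] <- stage(key, {
      model <- if (model_name == "categorical")
        categorical_model(rdms[[1L]]$condition_of)
      else dispersion_model(rdms[[1L]]$condition_of)
      rho <- do.call(rbind, lapply(rdms, function(r) rsa_correlate(r, model)$accuracy))
      utils::write.csv(
        data.frame(time_ms = times, t(rho)),
        file.path(config$out_dir, sprintf("rho_%s.csv", model_name)),
        row.names = FALSE)
      cr <- cluster_test_1d(rho, 0, config$stats, times)
      list(model = model_name,
           clusters = cluster_summary(cr, times),
           group_mean_rho = unname(colMeans(rho)),
           times_ms = times)
    })
  }

  if (wants("mds") && !is.null(rdms)) {
    summary$analyses$mds <- stage("mds", {
      win <- config$synth$effect_window
      sel <- times >= win[1L] & times <= win[2L]
      grand <- Reduce(`+`, lapply(rdms, function(r)
        apply(r$values[sel, , , drop = FALSE], c(2L, 3L), mean))) / n_subj
      xy <- mds_embed(grand)
      tab <- data.frame(image_id = rdms[[1L]]$image_ids,
                        condition = rdms[[1L]]$condition_of,
                        dim1 = xy[, 1L], dim2 = xy[, 2L])
      utils::write.csv(tab, file.path(config$out_dir, "mds_coordinates.csv"),
                       row.names = FALSE)
      list(window_ms = win, n_images = nrow(tab))
    })
  }

  roi_groups <- sub("^roi:", "", config$analyses[startsWith(config$analyses, "roi:")])
  for (grp in roi_groups) {
    if (!grp %in% epochs[[1L]]$channel_group)
      stop(sprintf("pipeline stage 'roi:%s' failed: channel group not present", grp))
    roi_rdms <- stage(paste0("roi:", grp), decode_for(grp))
    summary$analyses[[paste0("roi:", grp)]] <-
      stage(paste0("roi:", grp), condition_block(roi_rdms, paste0("roi_", grp)))
  }

  if (wants("tempgen")) {
    summary$analyses$tempgen <- stage("tempgen", {
      tg <- lapply(seq_len(n_subj), function(i) {
        p <- config$decode
        p$seed <- decode_seeds[i]
        subject_tempgen(epochs[[i]], p)
      })
      res <- list(times_ms = times)
      for (tag in c("high", "low")) {
        arr <- array(0, c(n_subj, length(times), length(times)))
        for (i in seq_len(n_subj)) arr[i, , ] <- tg[[i]][[tag]]
        grand <- apply(arr, c(2L, 3L), mean)
        utils::write.csv(grand, file.path(config$out_dir,
                                          sprintf("tempgen_%s.csv", tag)),
                         row.names = FALSE)
        cr <- cluster_test_2d(arr, 50, config$stats, times)
        res[[tag]] <- list(clusters = cluster_summary(cr, times))
      }
      darr <- array(0, c(n_subj, length(times), length(times)))
      for (i in seq_len(n_subj)) darr[i, , ] <- tg[[i]]$high - tg[[i]]$low
      res$difference <- list(clusters = cluster_summary(
        cluster_test_2d(darr, 0, config$stats, times), times))
      res
    })
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  make_report(summary, config)
  invisible(summary)
}

#' Render a human-readable report from a pipeline bundle
#'
#' Writes `report.md` into the output directory, one section per requested
#' analysis (analyses absent from the bundle are listed as skipped), and —
#' when `config$figures` is set and ggplot2 is installed — companion PNG
#' figures of the condition-mean time courses and model-correlation curves.
#'
#' @param summary The bundle returned by [run_pipeline()].
#' @param config The [pipeline_config()] that produced it.
#' @return Path of the report file, invisibly.
#' @export
make_report <- function(summary, config) {
  path <- file.path(config$out_dir, "report.md")
  ln <- c(sprintf("# Memorability decoding pipeline report (seed %d)", summary$seed), "")
  fmt_clusters <- function(cl) {
    if (!length(cl)) return("no supra-threshold clusters")
    paste(vapply(cl, function(x) {
      ext <- if (!is.null(x$onset_ms))
        sprintf("%g..%g ms", x$onset_ms, x$offset_ms)
      else sprintf("train %g..%g / test %g..%g ms",
                   x$train_ms[1L], x$train_ms[2L], x$test_ms[1L], x$test_ms[2L])
      sprintf("size %d (%s), p = %.4g%s", x$size, ext, x$p,
              if (isTRUE(x$significant)) " *" else "")
    }, character(1)), collapse = "; ")
  }
  for (a in config$analyses) {
    ln <- c(ln, sprintf("## %s", a), "")
    blk <- summary$analyses[[a]]
    if (is.null(blk)) { ln <- c(ln, "skipped", ""); next }
    if (a == "rdm") {
      ln <- c(ln, sprintf("%d subjects, K = %d images; per-subject RDM tables written.",
                          blk$n_subjects, blk$K), "")
    } else if (a %in% c("condition_means") || startsWith(a, "roi:")) {
      for (tag in c("high", "low", "difference"))
        ln <- c(ln, sprintf("- %s (chance %g): %s; peak %g ms [%g, %g]",
                            tag, blk[[tag]]$chance, fmt_clusters(blk[[tag]]$clusters),
                            blk[[tag]]$peak$peak_ms, blk[[tag]]$peak$ci_low_ms,
                            blk[[tag]]$peak$ci_high_ms))
      ln <- c(ln, "")
    } else if (startsWith(a, "rsa_")) {
      ln <- c(ln, sprintf("- %s model: %s", blk$model, fmt_clusters(blk$clusters)), "")
    } else if (a == "mds") {
      ln <- c(ln, sprintf("MDS of the group-mean RDM averaged over %g..%g ms (%d images).",
                          blk$window_ms[1L], blk$window_ms[2L], blk$n_images), "")
    } else if (a == "tempgen") {
      for (tag in c("high", "low", "difference"))
        ln <- c(ln, sprintf("- %s: %s", tag, fmt_clusters(blk[[tag]]$clusters)))
      ln <- c(ln, "")
    }
  }
  writeLines(ln, path)
  if (config$figures && requireNamespace("ggplot2", quietly = TRUE))
    report_figures(summary, config)
  invisible(path)
}

report_figures <- function(summary, config) {
  blk <- summary$analyses$condition_means
  if (!is.null(blk)) {
    df <- do.call(rbind, lapply(c("high", "low"), function(tag)
      data.frame(time_ms = blk$times_ms, accuracy = blk[[tag]]$group_mean, tag = tag)))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$accuracy,
                                          colour = .data$tag)) +
      ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey50") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ms)", y = "pairwise decoding (%)",
                    colour = "condition") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(config$out_dir, "condition_means.png"), p,
                    width = 6, height = 4, dpi = 120)
  }
  for (m in c("categorical", "dispersion")) {
    blk <- summary$analyses[[paste0("rsa_", m)]]
    if (is.null(blk)) next
    df <- data.frame(time_ms = blk$times_ms, rho = blk$group_mean_rho)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$rho)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ms)", y = "Spearman rho",
                    title = sprintf("%s model", m)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(config$out_dir, sprintf("rsa_%s.png", m)), p,
                    width = 6, height = 4, dpi = 120)
  }
  invisible(NULL)
}
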