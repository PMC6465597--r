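#' Parameters of the nonparametric group inference
#'
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param cdt Cluster-defining threshold: pointwise one-sample t-test p-value
#'   below which a time point enters a cluster (default 0.05).
#' @param alpha Corrected (cluster-level) significance level (default 0.05).
#' @param tail `"greater"` (accuracy vs chance, rho vs 0), `"less"`, or
#'   `"two.sided"` (differences, when no direction is claimed).
#' @param n_boot Number of bootstrap resamples for peak-latency intervals
#'   (default 1000).
#' @param ci_level Confidence level of the peak-latency interval (default 0.95).
#' @param seed Seed for the permutation / bootstrap draws.
#' @return An object of class `stat_params`.
#' @export
stat_params <- function(n_perm = 1000L, cdt = 0.05, alpha = 0.05,
                        tail = c("greater", "less", "two.sided"),
                        n_boot = 1000L, ci_level = 0.95, seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(cdt > 0, cdt < 1, alpha > 0, alpha < 1, n_perm >= 100L, n_boot >= 100L)
  structure(list(n_perm = as.integer(n_perm), cdt = cdt, alpha = alpha,
                 tail = tail, n_boot = as.integer(n_boot),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "stat_params")
}

# One-sample t statistics of sign-flipped deviations, vectorized over flip
# patterns: `signs` is n_flips x n_subjects in {-1,+1}, `D` n_subjects x p.
flip_tstats <- function(signs, D) {
  n <- nrow(D)
  M <- (signs %*% D) / n
  ss <- matrix(colSums(D^2), nrow(signs), ncol(D), byrow = TRUE)
  v <- (ss - n * M^2) / (n - 1)
  tt <- M / sqrt(v / n)
  tt[!is.finite(tt) & M == 0] <- 0    # 0/0 under a constant-zero pattern
  tt
}

sign_flip_matrix <- function(n_subj, params) {
  exhaustive <- 2^n_subj <= params$n_perm
  if (exhaustive) {
    warning(sprintf(
      "n_perm = %d exceeds the 2^%d distinct sign patterns; using exhaustive flips",
      params$n_perm, n_subj))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_subj)))
    dimnames(signs) <- NULL
  } else {
    signs <- with_seed_(params$seed, matrix(
      sample(c(-1, 1), params$n_perm * n_subj, replace = TRUE),
      params$n_perm, n_subj))
  }
  list(signs = signs, exhaustive = exhaustive)
}

cluster_pvalues <- function(sizes, null_max, exhaustive) {
  if (!length(sizes)) return(numeric(0))
  vapply(sizes, function(s) {
    if (exhaustive) mean(null_max >= s)
    else (1 + sum(null_max >= s)) / (length(null_max) + 1)
  }, numeric(1))
}

new_cluster_result <- function(clusters, sizes, p_values, sig_mask, params,
                               t_obs, t_crit, exhaustive, times = NULL,
                               dims = NULL) {
  structure(list(
    clusters = clusters, sizes = sizes, p_values = p_values,
    significant = p_values <= params$alpha, sig_mask = sig_mask,
    t_obs = t_obs, t_crit = t_crit, times = times, dims = dims,
    params = list(n_perm = params$n_perm, cdt = params$cdt,
                  alpha = params$alpha, tail = params$tail,
                  seed = params$seed, exhaustive = exhaustive,
                  statistic = "one-sample t, sign-flip max cluster size")
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(x$sizes)
  cat(sprintf("<cluster_result> %d cluster(s); n_perm = %d, cdt = %g, alpha = %g, tail = %s\n",
              k, x$params$n_perm, x$params$cdt, x$params$alpha, x$params$tail))
  if (k) {
    for (i in seq_len(k)) {
      ext <- if (!is.null(x$times) && is.null(x$dims)) {
        idx <- x$clusters[[i]]
        sprintf("%g..%g ms", x$times[min(idx)], x$times[max(idx)])
      } else sprintf("%d elements", x$sizes[i])
      cat(sprintf("  cluster %d: size %d (%s), p = %.4g%s\n", i, x$sizes[i], ext,
                  x$p_values[i], if (x$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

# Contiguous supra-threshold runs of a logical vector, as index vectors.
runs_above <- function(above) {
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) starts[i]:ends[i])
}

#' Cluster-size permutation test on decoding / correlation time courses
#'
#' Each time point is tested with a one-sample t statistic of the subject
#' deviations from `chance`, thresholded at the cluster-defining p-value;
#' maximal contiguous supra-threshold runs form clusters scored by their size
#' (count of supra-threshold points). The null distribution of the maximum
#' cluster size is built by flipping the sign of each subject's whole
#' deviation series (random flips, or exhaustive when `2^n` does not exceed
#' `n_perm`), and each observed cluster gets
#' `p = (1 + #\{perm max >= size\}) / (n_perm + 1)`.
#'
#' @param samples Numeric matrix `n_subjects x n_times`.
#' @param chance Chance level subtracted from every sample (50 for accuracy,
#'   0 for differences and correlations).
#' @param params A [stat_params()] object.
#' @param times Optional time axis in ms for reporting.
#' @return A `cluster_result` object: `clusters` (index vectors), `sizes`,
#'   `p_values`, `significant`, `sig_mask` (over time points), the pointwise
#'   `t_obs` and threshold, and the parameters used.
#' @export
cluster_test_1d <- function(samples, chance = 50, params = stat_params(),
                            times = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 6L) stop("cluster inference needs at least 6 subjects")
  if (!all(is.finite(samples))) stop("samples must be finite")
  D <- samples - chance
  if (params$tail == "less") D <- -D
  two <- params$tail == "two.sided"
  t_crit <- stats::qt(1 - (if (two) params$cdt / 2 else params$cdt), df = n - 1)
  sf <- sign_flip_matrix(n, params)
  tt <- flip_tstats(sf$signs, D)
  null_max <- as.integer(cpp_max_run(tt, t_crit))
  if (two) null_max <- pmax(null_max, as.integer(cpp_max_run(-tt, t_crit)))
  t_obs <- flip_tstats(matrix(1, 1L, n), D)[1L, ]
  clusters <- runs_above(t_obs > t_crit)
  if (two) clusters <- c(clusters, runs_above(t_obs < -t_crit))
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  sizes <- lengths(clusters)
  p <- cluster_pvalues(sizes, null_max, sf$exhaustive)
  sig_mask <- rep(FALSE, ncol(samples))
  for (i in seq_along(clusters)) if (p[i] <= params$alpha) sig_mask[clusters[[i]]] <- TRUE
  new_cluster_result(clusters, sizes, p, sig_mask, params, t_obs, t_crit,
                     sf$exhaustive, times = times)
}

#' Cluster-size permutation test on temporal generalization matrices
#'
#' As [cluster_test_1d()], but clusters are 4-connected components of the
#' supra-threshold `train x test` t-map and the null is the maximum 2-D
#' component size under whole-matrix sign flips per subject.
#'
#' @param samples Numeric array `n_subjects x n_train_times x n_test_times`.
#' @inheritParams cluster_test_1d
#' @return A `cluster_result`; `sig_mask` and `t_obs` are
#'   `n_train x n_test` matrices and `clusters` hold linear indices
#'   (column-major) into them.
#' @export
cluster_test_2d <- function(samples, chance = 50, params = stat_params(),
                            times = NULL) {
  d <- dim(samples)
  if (length(d) != 3L) stop("samples must be [n_subjects x n_train x n_test]")
  n <- d[1L]
  if (n < 6L) stop("cluster inference needs at least 6 subjects")
  if (!all(is.finite(samples))) stop("samples must be finite")
  D <- matrix(samples, n, d[2L] * d[3L]) - chance
  if (params$tail == "less") D <- -D
  two <- params$tail == "two.sided"
  t_crit <- stats::qt(1 - (if (two) params$cdt / 2 else params$cdt), df = n - 1)
  sf <- sign_flip_matrix(n, params)
  tt <- flip_tstats(sf$signs, D)
  null_max <- as.integer(cpp_perm_max_component(tt, d[2L], d[3L], t_crit))
  if (two) null_max <- pmax(null_max,
                            as.integer(cpp_perm_max_component(-tt, d[2L], d[3L], t_crit)))
  t_obs <- matrix(flip_tstats(matrix(1, 1L, n), D)[1L, ], d[2L], d[3L])
  comp <- function(mask) {
    lab <- cpp_label_components(mask)
    k <- max(lab)
    if (k == 0L) return(list())
    lapply(seq_len(k), function(i) which(lab == i))
  }
  clusters <- comp(t_obs > t_crit)
  if (two) clusters <- c(clusters, comp(t_obs < -t_crit))
  sizes <- lengths(clusters)
  ord <- order(-sizes)
  clusters <- clusters[ord]; sizes <- sizes[ord]
  p <- cluster_pvalues(sizes, null_max, sf$exhaustive)
  sig_mask <- matrix(FALSE, d[2L], d[3L])
  for (i in seq_along(clusters)) if (p[i] <= params$alpha) sig_mask[clusters[[i]]] <- TRUE
  new_cluster_result(clusters, sizes, p, sig_mask, params, t_obs, t_crit,
                     sf$exhaustive, times = times, dims = d[2:3])
}

#' Bootstrap confidence interval for the peak latency of a group time course
#'
#' Subjects are resampled with replacement `n_boot` times; each resampled
#' group-average series contributes its argmax latency, and the interval is
#' formed from the empirical percentiles of that distribution. The point
#' estimate is the peak of the full-sample mean; flat maxima resolve to the
#' earliest maximum and are flagged.
#'
#' @param samples Numeric matrix `n_subjects x n_times`.
#' @param times Time axis in ms.
#' @param params A [stat_params()] object (`n_boot`, `ci_level`, `seed`).
#' @return List with `peak_ms`, `ci_ms` (length 2), `boot_ms` (the bootstrap
#'   distribution) and `flat_peak` flag.
#' @export
bootstrap_peak_latency <- function(samples, times, params = stat_params()) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2L) stop("peak-latency bootstrap needs at least 2 subjects")
  stopifnot(ncol(samples) == length(times))
  peak_of <- function(mu) which(mu == max(mu))[1L]
  mu <- colMeans(samples)
  flat <- sum(mu == max(mu)) > 1L
  peak <- times[peak_of(mu)]
  boot <- with_seed_(params$seed, vapply(seq_len(params$n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    times[peak_of(colMeans(samples[idx, , drop = FALSE]))]
  }, numeric(1)))
  a <- (1 - params$ci_level) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a)))
  list(peak_ms = peak, ci_ms = ci, boot_ms = boot, flat_peak = flat)
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with rates clipped to
#' `[1/(2n), 1 - 1/(2n)]` per response class before the inverse-normal
#' transform, so perfect and empty cells stay finite while negative
#' sensitivities remain representable.
#'
#' @param hits,misses Signal-trial counts.
#' @param false_alarms,correct_rejections Noise-trial counts.
#' @return Scalar d-prime.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  stopifnot(all(c(hits, misses, false_alarms, correct_rejections) >= 0))
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig == 0 || n_noise == 0)
    stop("both signal and noise trials are required")
  clip <- function(rate, n) pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hits / n_sig, n_sig)) -
    stats::qnorm(clip(false_alarms / n_noise, n_noise))
}

#' Two-sided Wilcoxon signed-rank test with an exact tied-rank null
#'
#' Zero differences are dropped; the remaining absolute differences are
#' ranked with average ranks for ties and the statistic is the sum of the
#' positive-difference ranks. For `n <= 25` the null distribution is computed
#' exactly over all `2^n` sign assignments of the observed (possibly tied)
#' ranks via a generating-function recursion on doubled ranks; beyond that a
#' normal approximation with tie correction is used. The two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param values Per-subject scalars.
#' @param null_value Hypothesized location (default 0).
#' @return List with `statistic` (V), `p.value`, `n_used`, `exact`, and
#'   `all_zero` flag (in which case `p.value = 1`).
#' @export
signed_rank_test <- function(values, null_value = 0) {
  d <- values - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p.value = 1, n_used = 0L, exact = TRUE,
                all_zero = TRUE))
  if (n < 5L) stop("signed-rank test needs at least 5 non-zero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    R2 <- as.integer(round(2 * r))         # doubled ranks are integers
    S <- sum(R2)
    cnt <- numeric(S + 1L)
    cnt[1L] <- 1
    for (Ri in R2)
      cnt[(Ri + 1L):(S + 1L)] <- cnt[(Ri + 1L):(S + 1L)] + cnt[1L:(S + 1L - Ri)]
    tot <- 2^n
    w2 <- as.integer(round(2 * V))
    ple <- sum(cnt[1L:(w2 + 1L)]) / tot
    pge <- sum(cnt[(w2 + 1L):(S + 1L)]) / tot
    p <- min(1, 2 * min(ple, pge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = V, p.value = p, n_used = n, exact = exact, all_zero = FALSE)
}
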