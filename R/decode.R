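#' Decoding parameters
#'
#' @param group_size Pseudo-trial group size `g` (default 5): trials of each
#'   image are sub-averaged in random groups of `g`, so 30 trials yield
#'   `floor(30/5) = 6` pseudo-trials.
#' @param repetitions Number of times the random sub-averaging plus
#'   cross-validation cycle is repeated and averaged (default 100).
#' @param cost SVM regularization parameter C of the linear kernel (default 1).
#' @param channels `NULL` to decode on all channels, or a channel-group label
#'   to restrict the pattern vectors (ROI decoding).
#' @param seed Seed governing the random group assignments; repetition seeds
#'   are derived from it deterministically.
#' @return An object of class `decode_params`.
#' @export
decode_params <- function(group_size = 5L, repetitions = 100L, cost = 1,
                          channels = NULL, seed = 1L) {
  stopifnot(group_size >= 1L, repetitions >= 1L, cost > 0)
  structure(list(group_size = as.integer(group_size),
                 repetitions = as.integer(repetitions),
                 cost = cost, channels = channels, seed = as.integer(seed)),
            class = "decode_params")
}

#' Sub-average the trials of one image into pseudo-trials
#'
#' Randomly partitions the image's trials into `floor(n/g)` groups of exactly
#' `g` (remainder trials are discarded at random) and averages each group.
#' Uses the caller's RNG state; [build_rdm_series()] seeds it per repetition.
#'
#' @param epochs A [meg_epochs()] object.
#' @param image Image id whose trials to sub-average.
#' @param g Group size.
#' @return An object of class `pseudo_trials`: list with `data`
#'   (`n_pseudo x n_channels x n_times`), `times`, `image_id`, `g`, and
#'   `members` (list of the trial indices averaged into each pseudo-trial).
#' @export
subaverage <- function(epochs, image, g) {
  validate_epochs(epochs)
  idx <- which(epochs$image_id == image)
  n <- length(idx)
  if (n < g) stop(sprintf("image %s has %d trials, fewer than group size %d", image, n, g))
  n_pseudo <- n %/% g
  perm <- sample(idx)
  used <- perm[seq_len(n_pseudo * g)]
  members <- split(used, rep(seq_len(n_pseudo), each = g))
  d <- dim(epochs$data)
  out <- array(0, c(n_pseudo, d[2L], d[3L]))
  for (p in seq_len(n_pseudo)) {
    sl <- epochs$data[members[[p]], , , drop = FALSE]
    out[p, , ] <- colMeans(sl, dims = 1L)
  }
  structure(list(data = out, times = epochs$times, image_id = image,
                 g = as.integer(g), members = members),
            class = "pseudo_trials")
}

check_pseudo_pair <- function(pa, pb) {
  if (!inherits(pa, "pseudo_trials") || !inherits(pb, "pseudo_trials"))
    stop("inputs must be `pseudo_trials` objects")
  if (dim(pa$data)[1L] != dim(pb$data)[1L])
    stop("pseudo-trial counts differ between the two images")
  if (!isTRUE(all.equal(pa$times, pb$times)))
    stop("time axes differ between the two images")
  invisible(NULL)
}

#' Leave-one-out pairwise decoding time course
#'
#' For each time point, fold `k` holds out pseudo-trial `k` of each image,
#' trains a linear SVM (cost `C`) on the remaining `2(N-1)` channel-pattern
#' vectors, and classifies the two held-out vectors; accuracy is the percent
#' of correct classifications over all `2N` tests.
#'
#' @param pa,pb [subaverage()] results for the two images (equal pseudo-trial
#'   counts and identical time axes).
#' @param params A [decode_params()] object (only `cost` is used here).
#' @return Numeric vector of accuracies in percent, one per time point, with
#'   the time axis attached as attribute `"times"`.
#' @export
pair_decode_timecourse <- function(pa, pb, params = decode_params()) {
  check_pseudo_pair(pa, pb)
  acc <- as.numeric(cpp_pair_decode(pa$data, pb$data, params$cost))
  attr(acc, "times") <- pa$times
  acc
}

#' Temporal generalization matrix for one image pair
#'
#' The classifiers trained per fold at time `t` (the identical fold schedule
#' and solutions as [pair_decode_timecourse()]) are tested on the held-out
#' pseudo-trials at every time `t'`. Rows index training time, columns
#' testing time; the diagonal equals the 1-D decoding time course exactly.
#'
#' @inheritParams pair_decode_timecourse
#' @return Numeric `n_times x n_times` matrix of accuracies in percent, with
#'   attribute `"times"`.
#' @export
temporal_generalization <- function(pa, pb, params = decode_params()) {
  check_pseudo_pair(pa, pb)
  acc <- cpp_pair_tempgen(pa$data, pb$data, params$cost)
  attr(acc, "times") <- pa$times
  acc
}

rep_seeds <- function(params) {
  with_seed_(params$seed, sample.int(.Machine$integer.max - 1L, params$repetitions))
}

#' Build the time-resolved RDM series for one subject
#'
#' For each of `repetitions` cycles, the random sub-averaging is re-drawn for
#' all images and the leave-one-out SVM accuracy of every image pair is
#' computed at every time point; accuracies are averaged over repetitions
#' into one symmetric, zero-diagonal `K x K` decoding matrix per time point.
#'
#' @param epochs A (preprocessed) [meg_epochs()] object.
#' @param params A [decode_params()] object. With `params$channels` set, the
#'   pattern vectors are restricted to that channel group (ROI decoding).
#' @return An [rdm_series()] object. The per-repetition grand-mean accuracy
#'   (over pairs and time) is attached as attribute `"rep_grand_mean"` for
#'   calibration diagnostics.
#' @export
build_rdm_series <- function(epochs, params = decode_params()) {
  validate_epochs(epochs)
  if (!is.null(params$channels)) epochs <- select_channel_group(epochs, params$channels)
  tab <- unique(data.frame(image_id = epochs$image_id, condition = epochs$condition))
  tab <- tab[order(tab$image_id), ]
  K <- nrow(tab)
  if (K < 2L) stop("need at least 2 images to decode")
  n_t <- length(epochs$times)
  seeds <- rep_seeds(params)
  acc_sum <- array(0, c(n_t, K, K))
  rep_means <- numeric(params$repetitions)
  pairs <- utils::combn(K, 2L)
  for (r in seq_len(params$repetitions)) {
    pseudo <- with_seed_(seeds[r], lapply(tab$image_id, function(img)
      subaverage(epochs, img, params$group_size)))
    rep_acc <- 0
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      acc <- as.numeric(cpp_pair_decode(pseudo[[i]]$data, pseudo[[j]]$data, params$cost))
      acc_sum[, i, j] <- acc_sum[, i, j] + acc
      acc_sum[, j, i] <- acc_sum[, j, i] + acc
      rep_acc <- rep_acc + mean(acc)
    }
    rep_means[r] <- rep_acc / ncol(pairs)
  }
  out <- rdm_series(
    values = acc_sum / params$repetitions,
    times = epochs$times,
    image_ids = tab$image_id,
    condition_of = tab$condition,
    subject_id = epochs$subject_id,
    params = list(group_size = params$group_size, repetitions = params$repetitions,
                  cost = params$cost, channels = params$channels, seed = params$seed,
                  tempgen_fold_reuse = TRUE)
  )
  attr(out, "rep_grand_mean") <- rep_means
  out
}

#' Within-condition average of temporal generalization matrices
#'
#' Element-wise mean of the supplied matrices within each condition label;
#' between-condition pairs (label `"between"`) are excluded from both
#' averages. Averaging over pairs and then subjects reduces to this flat mean
#' when every subject contributes the same pairs.
#'
#' @param matrices List of `n_times x n_times` accuracy matrices.
#' @param conditions Character vector (`"high"`, `"low"`, `"between"`) of the
#'   same length labelling each matrix by its image pair.
#' @return A list with elements `high` and `low`.
#' @export
condition_mean_tempgen <- function(matrices, conditions) {
  stopifnot(length(matrices) == length(conditions))
  avg <- function(cond) {
    sel <- which(conditions == cond)
    if (!length(sel)) stop(sprintf("no matrices with condition '%s'", cond))
    Reduce(`+`, matrices[sel]) / length(sel)
  }
  list(high = avg("high"), low = avg("low"))
}

#' Subject-level condition-mean temporal generalization
#'
#' Convenience driver: repeats sub-averaging `params$repetitions` times,
#' computes the temporal generalization matrix of every within-condition image
#' pair, and averages within the high and low conditions.
#'
#' @inheritParams build_rdm_series
#' @return A list with `high` and `low` `n_times x n_times` matrices and the
#'   time axis in `times`.
#' @export
subject_tempgen <- function(epochs, params = decode_params()) {
  validate_epochs(epochs)
  if (!is.null(params$channels)) epochs <- select_channel_group(epochs, params$channels)
  tab <- unique(data.frame(image_id = epochs$image_id, condition = epochs$condition))
  tab <- tab[order(tab$image_id), ]
  K <- nrow(tab)
  n_t <- length(epochs$times)
  seeds <- rep_seeds(params)
  sum_high <- matrix(0, n_t, n_t); n_high <- 0L
  sum_low <- matrix(0, n_t, n_t); n_low <- 0L
  pairs <- utils::combn(K, 2L)
  for (r in seq_len(params$repetitions)) {
    pseudo <- with_seed_(seeds[r], lapply(tab$image_id, function(img)
      subaverage(epochs, img, params$group_size)))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      ci <- tab$condition[i]; cj <- tab$condition[j]
      if (ci != cj) next                      # between-condition pairs unused
      m <- cpp_pair_tempgen(pseudo[[i]]$data, pseudo[[j]]$data, params$cost)
      if (ci == "high") { sum_high <- sum_high + m; n_high <- n_high + 1L }
      else { sum_low <- sum_low + m; n_low <- n_low + 1L }
    }
  }
  if (n_high == 0L || n_low == 0L) stop("each condition needs at least one within-condition pair")
  list(high = sum_high / n_high, low = sum_low / n_low, times = epochs$times)
}
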