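# Small programmatic fixtures shared across test files.

# Minimal valid epochs object: deterministic data unless `fill` is given.
toy_epochs <- function(n_trials = 4, n_channels = 3, n_times = 5,
                       sampling_rate = 1000, t0 = -2, fill = NULL,
                       image_id = NULL, condition = NULL,
                       channel_group = NULL) {
  if (is.null(fill))
    fill <- array(seq_len(n_trials * n_channels * n_times) / 10,
                  c(n_trials, n_channels, n_times))
  if (is.null(image_id)) image_id <- rep_len(1:2, n_trials)
  if (is.null(condition)) condition <- ifelse(image_id %% 2 == 1, "high", "low")
  meg_epochs(
    data = fill,
    times = t0 + (seq_len(n_times) - 1) * 1000 / sampling_rate,
    image_id = image_id,
    condition = condition,
    channel_group = channel_group,
    sampling_rate = sampling_rate,
    subject_id = "toy"
  )
}

# Signal-free epochs: pure white noise, balanced images.
noise_epochs <- function(K = 4, n_trials_per_image = 10, n_channels = 6,
                         n_times = 8, seed = 1, sampling_rate = 250) {
  set.seed(seed)
  n <- K * n_trials_per_image
  image_id <- rep(seq_len(K), each = n_trials_per_image)
  meg_epochs(
    data = array(rnorm(n * n_channels * n_times), c(n, n_channels, n_times)),
    times = (seq_len(n_times) - 1) * 1000 / sampling_rate,
    image_id = image_id,
    condition = ifelse(image_id <= K / 2, "high", "low"),
    sampling_rate = sampling_rate,
    subject_id = sprintf("noise%d", seed)
  )
}

# Pseudo-trial object wrapped around an explicit N x S x T array.
as_pseudo <- function(data, times = NULL, image_id = 1L) {
  if (is.null(times)) times <- seq_len(dim(data)[3]) - 1
  structure(list(data = data, times = times, image_id = image_id,
                 g = 1L, members = NULL),
            class = "pseudo_trials")
}

# Independent LOO pairwise decoder built on e1071 (libsvm), mirroring the
# documented fold schedule; used as the dual-route oracle for the compiled
# SMO decoder.
e1071_pair_decode <- function(A, B, cost = 1) {
  N <- dim(A)[1]; Tn <- dim(A)[3]
  vapply(seq_len(Tn), function(t) {
    correct <- 0
    for (k in seq_len(N)) {
      Xtr <- rbind(A[-k, , t, drop = FALSE][, , 1, drop = TRUE],
                   B[-k, , t, drop = FALSE][, , 1, drop = TRUE])
      if (dim(A)[2] == 1) Xtr <- cbind(as.numeric(Xtr))
      y <- factor(rep(c("A", "B"), each = N - 1))
      fit <- e1071::svm(Xtr, y, kernel = "linear", cost = cost, scale = FALSE)
      pred <- predict(fit, rbind(A[k, , t], B[k, , t]))
      correct <- correct + sum(pred == c("A", "B"))
    }
    100 * correct / (2 * N)
  }, numeric(1))
}

# Brute-force Spearman oracle: average ranks by hand, then the Pearson
# formula on the ranks; independent of stats::cor.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

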