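test_that("sub-averaging partitions trials into floor(n/g) groups of exactly g", {
  ep <- noise_epochs(K = 2, n_trials_per_image = 30, n_channels = 3, n_times = 4)
  set.seed(1)
  ps <- subaverage(ep, 1, 5)
  expect_equal(dim(ps$data)[1], 6L)                 # 30 trials / 5 -> 6
  expect_true(all(lengths(ps$members) == 5L))
  expect_length(unique(unlist(ps$members)), 30L)

  # 32 trials, g = 5: 6 pseudo-trials, 2 trials unused, no trial reused
  ep32 <- noise_epochs(K = 1, n_trials_per_image = 32, n_channels = 2, n_times = 3)
  set.seed(2)
  ps32 <- subaverage(ep32, 1, 5)
  expect_equal(dim(ps32$data)[1], 6L)
  used <- unlist(ps32$members)
  expect_length(used, 30L)
  expect_length(unique(used), 30L)
  expect_true(all(used %in% which(ep32$image_id == 1)))
  # each pseudo-trial is the arithmetic mean of its group
  expect_equal(ps32$data[3, , ], colMeans(ep32$data[ps32$members[[3]], , ], dims = 1))

  # g = 1: pseudo-trials are a permutation of the originals
  set.seed(3)
  ps1 <- subaverage(ep, 2, 1)
  expect_equal(dim(ps1$data)[1], 30L)
  expect_setequal(unlist(ps1$members), which(ep$image_id == 2))

  expect_error(subaverage(ep, 1, 31), "fewer than group size")
})

test_that("separable patterns decode at 100% and chance data near 50%", {
  # 1-channel patterns, A = +1, B = -1, no noise -> 100% everywhere
  A <- array(1, c(3, 1, 4)); B <- array(-1, c(3, 1, 4))
  acc <- pair_decode_timecourse(as_pseudo(A), as_pseudo(B))
  expect_equal(as.numeric(acc), rep(100, 4))

  # clean 2-channel toy with N = 3 listed vectors: every training fold is
  # linearly separable with margin and the held-out points sit inside their
  # class clouds, so any max-margin separator scores 100%
  A2 <- array(0, c(3, 2, 2)); B2 <- array(0, c(3, 2, 2))
  A2[, 1, ] <- c(1, 1.2, 0.9); A2[, 2, ] <- c(0, 0.1, -0.1)
  B2[, 1, ] <- c(-1, -1.1, -0.8); B2[, 2, ] <- c(0, 0.2, 0)
  expect_equal(as.numeric(pair_decode_timecourse(as_pseudo(A2), as_pseudo(B2))),
               rep(100, 2))

  # identically distributed pseudo-trials: grand mean near chance
  set.seed(4)
  A3 <- array(rnorm(6 * 8 * 150), c(6, 8, 150))
  B3 <- array(rnorm(6 * 8 * 150), c(6, 8, 150))
  acc <- pair_decode_timecourse(as_pseudo(A3), as_pseudo(B3))
  expect_gt(mean(acc), 47); expect_lt(mean(acc), 53)

  expect_error(pair_decode_timecourse(as_pseudo(A3), as_pseudo(B3[1:4, , ])),
               "counts differ")
})

test_that("fold schedule is unbiased at several pseudo-trial counts", {
  set.seed(9)
  for (N in c(3, 6, 10)) {
    A <- array(rnorm(N * 6 * 120), c(N, 6, 120))
    B <- array(rnorm(N * 6 * 120), c(N, 6, 120))
    acc <- pair_decode_timecourse(as_pseudo(A), as_pseudo(B))
    expect_gt(mean(acc), 47)
    expect_lt(mean(acc), 53)
  }
})

test_that("compiled SMO decoder agrees with the libsvm oracle", {
  skip_if_not_installed("e1071")
  set.seed(11)
  # weight-vector agreement on single fits
  for (i in 1:20) {
    n <- sample(4:10, 1); d <- sample(2:6, 1)
    X <- matrix(rnorm(2 * n * d), 2 * n, d)
    X[seq_len(n), 1] <- X[seq_len(n), 1] + 1.5
    y <- rep(c(1, -1), each = n)
    fit <- memdecode:::cpp_svm_train(X, y, 1)
    ref <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    w_ref <- as.numeric(t(ref$coefs) %*% ref$SV)
    expect_equal(as.numeric(fit$w), w_ref, tolerance = 1e-3)
    expect_equal(fit$b, -ref$rho, tolerance = 5e-3)
  }
  # full LOO accuracy curves on random decodable toys
  for (i in 1:5) {
    N <- sample(3:6, 1); S <- sample(2:5, 1); Tn <- 6
    A <- array(rnorm(N * S * Tn, mean = 0.8), c(N, S, Tn))
    B <- array(rnorm(N * S * Tn, mean = -0.8), c(N, S, Tn))
    mine <- as.numeric(pair_decode_timecourse(as_pseudo(A), as_pseudo(B)))
    orac <- e1071_pair_decode(A, B)
    expect_equal(mine, orac)
  }
})

test_that("pair decoding is symmetric in its arguments and deterministic", {
  set.seed(13)
  A <- array(rnorm(4 * 5 * 10, 0.3), c(4, 5, 10))
  B <- array(rnorm(4 * 5 * 10, -0.3), c(4, 5, 10))
  ab <- pair_decode_timecourse(as_pseudo(A), as_pseudo(B))
  ba <- pair_decode_timecourse(as_pseudo(B), as_pseudo(A))
  expect_equal(as.numeric(ab), as.numeric(ba))
  expect_identical(pair_decode_timecourse(as_pseudo(A), as_pseudo(B)), ab)
})

test_that("accuracy is monotone in class separation", {
  set.seed(17)
  S <- 4; N <- 6; Tn <- 40
  acc_at <- function(delta) {
    mean(vapply(1:8, function(r) {
      A <- array(rnorm(N * S * Tn, delta / 2), c(N, S, Tn))
      B <- array(rnorm(N * S * Tn, -delta / 2), c(N, S, Tn))
      mean(pair_decode_timecourse(as_pseudo(A), as_pseudo(B)))
    }, numeric(1)))
  }
  a0 <- acc_at(0); a1 <- acc_at(0.6); a2 <- acc_at(1.5)
  expect_gt(a1, a0 - 1.5)
  expect_gt(a2, a1 - 1.5)
  expect_gt(a2, a0 + 5)     # clear growth across the grid
})

test_that("RDM assembly averages repetitions and respects symmetry", {
  ep <- noise_epochs(K = 3, n_trials_per_image = 10, n_channels = 4,
                     n_times = 6, seed = 21)
  params <- decode_params(group_size = 5, repetitions = 2, seed = 8)
  rdm <- build_rdm_series(ep, params)
  expect_s3_class(rdm, "rdm_series")
  expect_equal(dim(rdm$values), c(6, 3, 3))
  # determinism: same data + params + seed -> identical series
  expect_identical(build_rdm_series(ep, params)$values, rdm$values)

  # averaging contract: the R = 2 series equals the mean of the two
  # single-repetition series reconstructed from the derived child seeds
  seeds <- memdecode:::rep_seeds(params)
  one_rep <- function(s) {
    pseudo <- memdecode:::with_seed_(s, lapply(1:3, function(img)
      subaverage(ep, img, 5)))
    v <- array(0, c(6, 3, 3))
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      acc <- as.numeric(memdecode:::cpp_pair_decode(
        pseudo[[p[1]]]$data, pseudo[[p[2]]]$data, 1))
      v[, p[1], p[2]] <- acc; v[, p[2], p[1]] <- acc
    }
    v
  }
  expect_equal(rdm$values, (one_rep(seeds[1]) + one_rep(seeds[2])) / 2)
})

test_that("condition means average the right pairs", {
  # printed 2+2-image toy: images 1,2 high; 3,4 low
  K <- 4
  vals <- array(0, c(1, K, K))
  m <- matrix(0, K, K)
  m[1, 2] <- 60                                  # within-high
  m[3, 4] <- 52                                  # within-low
  m[1, 3] <- 70; m[1, 4] <- 72; m[2, 3] <- 74; m[2, 4] <- 76  # between
  m <- m + t(m)
  vals[1, , ] <- m
  rdm <- rdm_series(vals, 0, 1:4, c("high", "high", "low", "low"))
  tc <- condition_mean_timecourses(rdm)
  expect_equal(tc$high$accuracy, 60)
  expect_equal(tc$low$accuracy, 52)
  expect_equal(tc$difference$accuracy, 8)

  # constant RDM: high = low, difference = 0
  vals[] <- 0; vals[1, , ] <- 55; for (i in 1:4) vals[1, i, i] <- 0
  rdmc <- rdm_series(vals, 0, 1:4, c("high", "high", "low", "low"))
  tcc <- condition_mean_timecourses(rdmc)
  expect_equal(tcc$high$accuracy, 55)
  expect_equal(tcc$difference$accuracy, 0)

  bad <- rdm_series(vals, 0, 1:4, c("high", "high", "high", "low"))
  expect_error(condition_mean_timecourses(bad), "fewer than 2")
})

test_that("temporal generalization reuses the diagonal classifiers", {
  set.seed(23)
  A <- array(rnorm(4 * 3 * 8, 0.5), c(4, 3, 8))
  B <- array(rnorm(4 * 3 * 8, -0.5), c(4, 3, 8))
  tg <- temporal_generalization(as_pseudo(A), as_pseudo(B))
  acc <- pair_decode_timecourse(as_pseudo(A), as_pseudo(B))
  expect_identical(diag(unclass(tg)), as.numeric(acc))   # bit-exact diagonal

  # time-constant patterns: each training row is constant across test times
  Ac <- array(rep(rnorm(4 * 3, 0.5), 8), c(4, 3, 8))
  Bc <- array(rep(rnorm(4 * 3, -0.5), 8), c(4, 3, 8))
  tgc <- unclass(temporal_generalization(as_pseudo(Ac), as_pseudo(Bc)))
  expect_true(all(apply(tgc, 1, function(r) length(unique(r)) == 1L)))

  # sign flip at mid-time: off-diagonal blocks fall to 100 - diagonal
  Tn <- 6
  Af <- array(0, c(4, 2, Tn)); Bf <- array(0, c(4, 2, Tn))
  base <- matrix(rnorm(4 * 2, 1.2), 4, 2)
  for (t in 1:Tn) {
    s <- if (t <= 3) 1 else -1
    Af[, , t] <- s * base
    Bf[, , t] <- -s * base
  }
  tgf <- unclass(temporal_generalization(as_pseudo(Af), as_pseudo(Bf)))
  expect_equal(tgf[1:3, 4:6], 100 - tgf[1:3, 1:3])
})

test_that("condition-mean temporal generalization averages within conditions", {
  m1 <- matrix(60, 2, 2); m2 <- matrix(70, 2, 2); m3 <- matrix(80, 2, 2)
  out <- condition_mean_tempgen(list(m1, m2, m3), c("high", "high", "low"))
  expect_equal(out$high, matrix(65, 2, 2))
  expect_equal(out$low, matrix(80, 2, 2))
  # between-condition matrices are never counted
  out2 <- condition_mean_tempgen(list(m1, m2, m3, matrix(99, 2, 2)),
                                 c("high", "high", "low", "between"))
  expect_equal(out2$high, matrix(65, 2, 2))
  expect_equal(out2$low, matrix(80, 2, 2))
  expect_error(condition_mean_tempgen(list(m1), c("high")), "no matrices")
})

test_that("ROI decoding is ordinary decoding on the channel subset", {
  ep <- noise_epochs(K = 2, n_trials_per_image = 6, n_channels = 6,
                     n_times = 4, seed = 25)
  ep$channel_group <- rep(c("occ", "par"), each = 3)
  p_all <- decode_params(group_size = 3, repetitions = 2, seed = 4)
  p_roi <- decode_params(group_size = 3, repetitions = 2, seed = 4,
                         channels = "par")
  roi_direct <- build_rdm_series(select_channel_group(ep, "par"), p_all)
  roi_via <- build_rdm_series(ep, p_roi)
  expect_equal(roi_via$values, roi_direct$values)
})
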