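test_that("1-D cluster test recovers a localized effect with a small p-value", {
  set.seed(41)
  n <- 15; Tn <- 80
  win <- 31:50
  X <- matrix(rnorm(n * Tn, 0, 1), n, Tn)
  X[, win] <- X[, win] + 2.5            # strong localized effect
  cr <- cluster_test_1d(X, 0, stat_params(n_perm = 1000, seed = 5))
  expect_s3_class(cr, "cluster_result")
  big <- which.max(cr$sizes)
  expect_lt(cr$p_values[big], 0.05)
  # recovered boundaries within +-5 samples of the true window
  idx <- cr$clusters[[big]]
  expect_lt(abs(min(idx) - min(win)), 6)
  expect_lt(abs(max(idx) - max(win)), 6)
  expect_true(all(cr$sig_mask[win[3:18]]))
  # p-values nonincreasing in cluster size
  ord <- order(cr$sizes)
  expect_true(all(diff(cr$p_values[ord]) <= 1e-12))
})

test_that("1-D cluster test is reproducible and warns into exhaustive flips", {
  set.seed(43)
  X <- matrix(rnorm(7 * 30), 7, 30)
  p <- stat_params(n_perm = 500, seed = 9)
  expect_warning(r1 <- cluster_test_1d(X, 0, p), "exhaustive")   # 2^7 = 128 < 500
  expect_warning(r2 <- cluster_test_1d(X, 0, p), "exhaustive")
  expect_identical(r1$p_values, r2$p_values)

  X15 <- matrix(rnorm(15 * 30), 15, 30)
  r3 <- cluster_test_1d(X15, 0, p)
  r4 <- cluster_test_1d(X15, 0, p)
  expect_identical(r3$p_values, r4$p_values)
  expect_error(cluster_test_1d(X[1:5, ], 0, p), "at least 6")
})

test_that("two-sided 1-D clustering finds negative effects too", {
  set.seed(45)
  X <- matrix(rnorm(12 * 60), 12, 60)
  X[, 10:25] <- X[, 10:25] - 2.5
  p2 <- stat_params(n_perm = 500, seed = 7, tail = "two.sided")
  cr <- cluster_test_1d(X, 0, p2)
  big <- which.max(cr$sizes)
  expect_lt(cr$p_values[big], 0.05)
  expect_true(min(cr$clusters[[big]]) >= 5 && max(cr$clusters[[big]]) <= 30)
  # one-sided greater must not flag the negative window
  cr1 <- cluster_test_1d(X, 0, stat_params(n_perm = 500, seed = 7))
  expect_true(all(!cr1$sig_mask[10:25]))
})

test_that("2-D cluster test recovers a block effect and controls isolated pixels", {
  set.seed(47)
  n <- 12; Tn <- 30
  arr <- array(rnorm(n * Tn * Tn), c(n, Tn, Tn))
  arr[, 8:18, 10:20] <- arr[, 8:18, 10:20] + 2.2
  cr <- cluster_test_2d(arr, 0, stat_params(n_perm = 500, seed = 11))
  big <- which.max(cr$sizes)
  expect_lt(cr$p_values[big], 0.05)
  rc <- arrayInd(cr$clusters[[big]], c(Tn, Tn))
  expect_lt(abs(min(rc[, 1]) - 8), 6);  expect_lt(abs(max(rc[, 1]) - 18), 6)
  expect_lt(abs(min(rc[, 2]) - 10), 6); expect_lt(abs(max(rc[, 2]) - 20), 6)

  # a single supra-threshold pixel never beats the 2-D null maxima
  null <- array(rnorm(n * Tn * Tn, 0, 0.2), c(n, Tn, Tn))
  null[, 15, 15] <- null[, 15, 15] + 2
  cr0 <- cluster_test_2d(null, 0, stat_params(n_perm = 500, seed = 13))
  one_px <- which(cr0$sizes == 1)
  expect_true(all(cr0$p_values[one_px] > 0.05))
})

test_that("4-connected labelling separates diagonal touches", {
  M <- matrix(0L, 4, 4)
  M[1, 1] <- 1L; M[2, 2] <- 1L; M[2, 3] <- 1L   # diagonal contact splits
  lab <- memdecode:::cpp_label_components(matrix(as.logical(M), 4, 4) * 1L)
  expect_equal(max(lab), 2L)
  expect_false(lab[1, 1] == lab[2, 2])
  expect_equal(lab[2, 2], lab[2, 3])
})

test_that("bootstrap peak latency honors its contracts", {
  times <- seq(0, 200, by = 10)
  bump <- function(center, amp = 5) amp * exp(-0.5 * ((times - center) / 20)^2)
  # noiseless shared peak: degenerate CI at the peak
  X <- do.call(rbind, replicate(6, bump(120), simplify = FALSE))
  out <- bootstrap_peak_latency(X, times, stat_params(seed = 3))
  expect_equal(out$peak_ms, 120)
  expect_equal(out$ci_ms, c(120, 120))
  expect_false(out$flat_peak)

  # two equal groups peaking at t1, t2: bootstrap support stays inside [t1, t2]
  X2 <- rbind(do.call(rbind, replicate(2, bump(60), simplify = FALSE)),
              do.call(rbind, replicate(2, bump(160), simplify = FALSE)))
  out2 <- bootstrap_peak_latency(X2, times, stat_params(seed = 5, n_boot = 400))
  expect_true(all(out2$boot_ms >= 60 & out2$boot_ms <= 160))
  expect_gte(out2$ci_ms[1], 60); expect_lte(out2$ci_ms[2], 160)

  # shift invariance
  out3 <- bootstrap_peak_latency(X2 + 17, times, stat_params(seed = 5, n_boot = 400))
  expect_identical(out3$peak_ms, out2$peak_ms)
  expect_identical(out3$ci_ms, out2$ci_ms)

  # flat series flagged, earliest maximum taken
  flat <- matrix(1, 3, length(times))
  out4 <- bootstrap_peak_latency(flat, times, stat_params(seed = 7))
  expect_true(out4$flat_peak)
  expect_equal(out4$peak_ms, 0)
})

test_that("d-prime matches the inverse-normal oracle", {
  expect_equal(dprime(25, 25, 25, 25), 0)
  expect_equal(dprime(45, 5, 5, 45), 2 * qnorm(0.9), tolerance = 1e-6)
  # perfect false-alarm row is clipped at 1/(2n): H = 1 -> 0.99 with n = 50
  expect_equal(dprime(50, 0, 0, 50), 2 * qnorm(0.99), tolerance = 1e-6)
  # negative sensitivity is representable
  expect_lt(dprime(10, 40, 40, 10), 0)
  expect_error(dprime(0, 0, 5, 45), "signal and noise")
})

test_that("signed-rank exact p matches exhaustive enumeration (with ties)", {
  # n = 6, all positive: two-sided p = 2/64
  out <- signed_rank_test(c(1, 2, 3, 4, 5, 6))
  expect_true(out$exact)
  expect_equal(out$p.value, 2 / 64)

  enum_p <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    W <- apply(signs, 1, function(s) sum(r[s]))
    min(1, 2 * min(mean(W <= V), mean(W >= V)))
  }
  set.seed(51)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n) * 2) / 2
    d[d == 0] <- 0.5                       # keep >= 5 non-zero diffs, allow ties
    expect_equal(signed_rank_test(d)$p.value, enum_p(d))
  }

  # agreement with the base-R exact test in the tie-free case
  set.seed(53)
  d <- rnorm(12)
  expect_equal(signed_rank_test(d)$p.value,
               wilcox.test(d, exact = TRUE)$p.value)

  # invariances and edge behavior
  expect_equal(signed_rank_test(d)$p.value, signed_rank_test(3.7 * d)$p.value)
  z <- signed_rank_test(rep(0, 8))
  expect_true(z$all_zero)
  expect_equal(z$p.value, 1)
  expect_error(signed_rank_test(c(0, 0, 0, 0, 1, 2)), "at least 5")
  # symmetric values around the null: p stays large
  expect_gt(signed_rank_test(c(-3, -2, -1, 1, 2, 3, -0.5, 0.5))$p.value, 0.8)
})
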