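test_that("baseline correction zeroes the baseline mean and is idempotent", {
  ep <- toy_epochs(n_trials = 2, n_channels = 2, n_times = 10,
                   sampling_rate = 100, t0 = -50,
                   fill = array(7, c(2, 2, 10)))
  out <- baseline_correct(ep, c(-50, 0))
  expect_equal(max(abs(out$data)), 0)                      # constant -> zero
  expect_equal(baseline_correct(out, c(-50, 0))$data, out$data)  # idempotent

  # ramp toy, hand-computed: times -50..40, baseline samples -50..0 have
  # values 1..6, mean 3.5; corrected trace = (1..10) - 3.5
  ramp <- toy_epochs(n_trials = 1, n_channels = 1, n_times = 10,
                     sampling_rate = 100, t0 = -50,
                     fill = array(1:10, c(1, 1, 10)),
                     image_id = 1L, condition = "high")
  out <- baseline_correct(ramp, c(-50, 0))
  expect_equal(as.numeric(out$data[1, 1, ]), (1:10) - 3.5)
  expect_error(baseline_correct(ramp, c(-500, -400)), "no samples")
})

test_that("low-pass filter preserves DC and passband, kills the stopband", {
  fs <- 250
  tt <- seq(0, 1000 - 4, by = 1000 / fs)          # 1 s of data
  make_ep <- function(trace) {
    meg_epochs(array(rep(trace, each = 2), c(2, 1, length(tt))),
               times = tt, image_id = c(1L, 2L),
               condition = c("high", "low"), sampling_rate = fs)
  }
  amp_of <- function(trace, f_hz) {
    # least-squares sinusoid fit at the known frequency
    X <- cbind(sin(2 * pi * f_hz * tt / 1000), cos(2 * pi * f_hz * tt / 1000))
    sqrt(sum(qr.coef(qr(X), trace)^2))
  }
  dc <- make_ep(rep(3, length(tt)))
  expect_equal(lowpass_filter(dc, 20)$data, dc$data, tolerance = 1e-6)

  s5 <- sin(2 * pi * 5 * tt / 1000)
  out5 <- lowpass_filter(make_ep(s5), 20)$data[1, 1, ]
  expect_gte(amp_of(out5, 5) / amp_of(s5, 5), 0.95)

  s80 <- sin(2 * pi * 80 * tt / 1000)
  out80 <- lowpass_filter(make_ep(s80), 20)$data[1, 1, ]
  expect_lte(amp_of(out80, 80) / amp_of(s80, 80), 0.1)

  expect_error(lowpass_filter(dc, 125), "Nyquist")
})

test_that("amplitude rejection removes exactly the offending trials", {
  ep <- noise_epochs(K = 2, n_trials_per_image = 5, seed = 2)
  out <- reject_amplitude(ep, 6000)
  expect_length(out$rejected, 0)                    # all within threshold
  expect_identical(out$epochs$data, ep$data)

  spiked <- ep
  spiked$data[7, 3, 2] <- 7000
  out <- reject_amplitude(spiked, 6000)
  expect_identical(out$rejected, 7L)
  expect_identical(out$epochs$data, ep$data[-7, , ])
  expect_identical(out$epochs$image_id, ep$image_id[-7])
  expect_identical(out$epochs$condition, ep$condition[-7])

  expect_length(reject_amplitude(spiked, Inf)$rejected, 0)   # identity
  expect_error(reject_amplitude(ep, 1e-9), "threshold")      # all rejected

  # per-group thresholds: spike on a 'grad' channel passes the 'mag' limit
  grp <- noise_epochs(K = 2, n_trials_per_image = 3, n_channels = 4, seed = 3)
  grp$channel_group <- c("mag", "mag", "grad", "grad")
  grp$data[2, 3, 1] <- 5000
  out <- reject_amplitude(grp, c(mag = 6000, grad = 3000))
  expect_identical(out$rejected, 2L)
})

test_that("blink projection removes most of an injected artifact and is idempotent", {
  cfg <- synth_config(n_subjects = 1, n_high = 3, n_low = 3,
                      n_trials_per_image = 10, n_channels = 16,
                      sampling_rate = 100, sigma_noise = 1, seed = 5)
  ep <- simulate_subject(cfg, draw_prototypes(cfg), subject_seed = 9)

  # clean data: no events detected, returned unchanged
  clean <- remove_blinks(ep, preproc_params(blink_z = 6))
  expect_equal(clean$report$n_events, 0L)
  expect_identical(clean$epochs$data, ep$data)
  expect_match(clean$report$warning, "no blink events")

  inj <- inject_blinks(ep, fraction = 0.1, amplitude = 25, seed = 12)
  out <- remove_blinks(inj$epochs, preproc_params())
  expect_gt(out$report$n_events, 0L)
  # residual variance along the injected pattern <= 10% of the injected one
  proj_var <- function(data) {
    v <- apply(data, c(1, 3), function(x) sum(x * inj$pattern))
    sum(v^2)
  }
  injected <- proj_var(inj$epochs$data) - proj_var(ep$data)
  residual <- proj_var(out$epochs$data) - proj_var(ep$data)
  expect_lt(residual / injected, 0.10)

  # orthogonal projection onto the detected components is idempotent
  V <- out$report$components
  reproject <- out$epochs$data
  for (tr in seq_len(dim(reproject)[1])) {
    slab <- reproject[tr, , ]
    reproject[tr, , ] <- slab - V %*% crossprod(V, slab)
  }
  expect_equal(reproject, out$epochs$data, tolerance = 1e-10)
  noground <- ep
  noground$channel_group <- rep("sensor", 16)
  expect_error(remove_blinks(noground), "frontal")
})

test_that("the full chain preserves labels and reports losses", {
  cfg <- synth_config(n_subjects = 1, n_high = 3, n_low = 3,
                      n_trials_per_image = 8, n_channels = 12,
                      sampling_rate = 100, sigma_noise = 1, seed = 6)
  ep <- simulate_subject(cfg, draw_prototypes(cfg), subject_seed = 2)
  # sustained high-amplitude segment: survives the low-pass, trips rejection
  ep$data[5, 2, 30:61] <- 9000
  out <- preprocess_epochs(ep, preproc_params(amplitude_threshold = 6000))
  expect_equal(out$report$n_rejected, 1L)
  expect_identical(out$report$rejected_trials, 5L)
  expect_identical(out$epochs$image_id, ep$image_id[-5])
  expect_identical(out$epochs$condition, ep$condition[-5])
  expect_equal(out$report$fraction_lost, 1 / 48)
})

test_that("preprocessing signal-free data does not induce decodable structure", {
  cfg <- synth_config(n_subjects = 1, n_high = 2, n_low = 2,
                      n_trials_per_image = 30, n_channels = 8,
                      sampling_rate = 100, sigma_id = 0, sigma_high = 0,
                      sigma_low = 0, sigma_noise = 1, seed = 31)
  ep <- simulate_subject(cfg, draw_prototypes(cfg), subject_seed = 7)
  pp <- preprocess_epochs(ep)
  rdm <- build_rdm_series(pp$epochs, decode_params(group_size = 5,
                                                   repetitions = 4, seed = 3))
  lt <- lower.tri(matrix(0, 4, 4))
  grand <- mean(apply(rdm$values, 1, function(m) mean(m[lt])))
  expect_gt(grand, 47); expect_lt(grand, 53)
})
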