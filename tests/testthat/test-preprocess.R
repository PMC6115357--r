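test_that("bandpass filter passes the band and kills DC and high frequencies", {
  fs <- 420
  t <- (0:(10 * fs - 1)) / fs
  # DC is below the 0.3 Hz corner
  dc <- bandpass_filter(rep(1, length(t)), fs = fs)
  expect_lt(sqrt(mean(dc^2)), 0.01)
  # 10 Hz is mid-band: amplitude preserved within 2% (sinusoid regression)
  x10 <- cos(2 * pi * 10 * t)
  y10 <- bandpass_filter(x10, fs = fs)
  keep <- (2 * fs):(8 * fs)  # avoid edge transients
  co <- stats::coef(stats::lm(y10[keep] ~ cos(2 * pi * 10 * t[keep]) +
                                sin(2 * pi * 10 * t[keep]) - 1))
  expect_lt(abs(sqrt(sum(co^2)) - 1), 0.02)
  # 100 Hz is in the stopband: > 40 dB down
  x100 <- cos(2 * pi * 100 * t)
  y100 <- bandpass_filter(x100, fs = fs)
  expect_lt(sqrt(mean(y100[keep]^2)) / sqrt(mean(x100[keep]^2)), 10^(-40 / 20))
  expect_error(bandpass_filter(x10, fs = 90), "configuration error")
})

test_that("resampling to 420 Hz preserves duration and in-band amplitude", {
  fs_in <- 500
  t <- (0:(10 * fs_in - 1)) / fs_in
  x <- cos(2 * pi * 4 * t)
  y <- resample_to_420(x, fs_in)
  expect_length(y, 4200)
  # identity at 420
  expect_identical(resample_to_420(x, 420), x)
  # 4 Hz amplitude within 0.1% (interior window, integer cycles)
  seg <- y[421:3780]
  co <- dft_coefficients(seg, 420, 4)
  expect_lt(abs(Mod(co[1, 1]) - 1), 1e-3)
})

test_that("bad-sensor detection uses a strict fraction threshold", {
  n <- 1000
  x <- matrix(0, 3, n)
  x[2, 1:160] <- 35        # 16% of samples above 30 uV
  x[3, 1:150] <- 35        # exactly 15%: strict inequality, not flagged
  expect_identical(detect_bad_sensors(x, amp_thresh = 30, frac = 0.15), 2L)
  expect_length(detect_bad_sensors(matrix(0, 4, n), 30), 0)
})

test_that("interpolation averages the six nearest good channels", {
  mont <- make_montage(32)
  n <- 100
  x <- matrix(rnorm(32 * n), 32, n)
  # six nearest of channel 5 all equal a constant -> channel becomes it
  d <- as.matrix(dist(mont$positions)); diag(d) <- Inf
  nn5 <- order(d[5, ], 1:32)[1:6]
  x2 <- x
  for (ch in nn5) x2[ch, ] <- 7
  y <- interpolate_sensors(x2, 5, mont)
  expect_equal(y[5, ], rep(7, n))

  # brute-force 6-NN oracle on a random bad set
  bad <- c(3, 11)
  y2 <- interpolate_sensors(x, bad, mont)
  good <- setdiff(1:32, bad)
  for (ch in bad) {
    donors <- good[order(d[ch, good], good)][1:6]
    expect_equal(y2[ch, ], colMeans(x[donors, ]))
    expect_false(any(bad %in% donors))  # bad sensors never donate
  }

  # fewer than 6 good channels available -> named error
  mont8 <- make_montage(8)
  expect_error(interpolate_sensors(matrix(0, 8, 4), 1:3, mont8),
               "interpolation error")
})

test_that("common-average re-referencing zeroes the sensor mean and is idempotent", {
  x <- matrix(rnorm(50 * 200), 50, 200)
  y <- rereference_common_average(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  expect_equal(rereference_common_average(y), y)
  # adding a common offset changes nothing
  expect_equal(rereference_common_average(x + 5), y)
  # already zero-mean data pass through
  expect_equal(rereference_common_average(y), y)
})

test_that("segmentation yields bin-aligned epochs that reassemble the trial", {
  prot <- adult_protocol()
  mont <- tiny_montage(8)
  cond <- condition_spec("in_phase")
  truth <- ground_truth_response(cond, mont)
  rec <- synthesize_trial(cond, prot, truth, mont, seed = 3)
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$data), c(10, 8, 420))
  expect_equal(ep$epoch_map$bin, 1:10)
  # each epoch holds exactly 2 stimulus cycles at 2 Hz
  expect_equal(dim(ep$data)[3] / ep$fs * prot$f_stim, 2)
  # round-trip: concatenating epochs reproduces the trial bit-exactly
  rebuilt <- do.call(cbind, lapply(1:10, function(e) ep$data[e, , ]))
  expect_identical(rebuilt, unname(rec$samples))

  ep2 <- segment_epochs(matrix(0, 4, 420), epoch_ms = 500, fs = 420)
  expect_equal(dim(ep2$data)[1], 2)
  expect_error(segment_epochs(matrix(0, 4, 419), epoch_ms = 500, fs = 420),
               "segmentation error")
})

test_that("epoch rejection applies noise, peak, and whole-epoch rules strictly", {
  ep0 <- segment_epochs(matrix(0, 10, 4200), fs = 420)
  clean <- reject_epochs(ep0)
  expect_true(all(clean$valid))

  # >10% of one channel-epoch above 30 uV -> only that channel-epoch
  x <- matrix(0, 10, 4200)
  x[4, 421:(420 + 47)] <- 31   # 47/420 ~ 11.2% of epoch 2
  r <- reject_epochs(segment_epochs(x, fs = 420))
  expect_false(r$valid[4, 2])
  expect_equal(sum(!r$valid), 1)

  # exactly 10% does not trigger (strict inequality)
  x2 <- matrix(0, 10, 4200)
  x2[4, 421:(420 + 42)] <- 31
  expect_true(all(reject_epochs(segment_epochs(x2, fs = 420))$valid))

  # single 70 uV samples: 7 sensors -> per-channel only; 8 -> whole epoch
  x7 <- matrix(0, 10, 4200)
  x7[1:7, 900] <- 70
  r7 <- reject_epochs(segment_epochs(x7, fs = 420))
  expect_equal(sum(!r7$valid[, 3]), 7)
  expect_true(all(r7$valid[8:10, 3]))
  x8 <- matrix(0, 10, 4200)
  x8[1:8, 900] <- 70
  r8 <- reject_epochs(segment_epochs(x8, fs = 420))
  expect_false(any(r8$valid[, 3]))
  expect_equal(r8$cleaning_report$fully_rejected_epochs, 3L)
  expect_true(all(r8$valid[, -3]))
})

test_that("artifact ledger predicts the rejection output exactly", {
  prot <- adult_protocol()
  mont <- tiny_montage(12)
  cond <- condition_spec("in_phase")
  truth <- single_harmonic_truth(cond, mont, rmax = 0.5, phase = 0.4)
  rec <- synthesize_trial(cond, prot, truth, mont, noise = NULL, seed = 2)
  rec <- inject_artifacts(rec, list(
    bad_channels = list(list(channel = 2, amplitude = 35, frac = 0.2)),
    spikes = list(list(sample = 2 * 420 + 100, channels = 3:10,
                       amplitude = 70))))

  bad <- detect_bad_sensors(rec, amp_thresh = 30, frac = 0.15)
  expect_identical(bad, rec$artifact_ledger$bad_channels[[1]]$channel)

  rec2 <- interpolate_sensors(rec, bad, mont)
  ep <- reject_epochs(segment_epochs(rec2))
  # ledger: the spike sits in epoch 3 on 8 channels -> whole-epoch rejection
  spike_epoch <- (rec$artifact_ledger$spikes[[1]]$samples - 1) %/% 420 + 1
  expect_false(any(ep$valid[, spike_epoch]))
  expect_true(all(ep$valid[, -spike_epoch]))
})
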