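# Dual recording holding one known signal per channel, both participants.
rec_from_signals <- function(..., fs) {
  m <- do.call(rbind, list(...))
  dual_recording(m, m, sampling_rate = fs)
}

test_that("downsampling halves the sample count and keeps amplitudes", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x5 <- sin(2 * pi * 5 * t)
  rec <- rec_from_signals(x5, x5 + 0.1, fs = fs)
  down <- eeg_downsample(rec, 250)
  expect_equal(down$sampling_rate, 250)
  expect_equal(ncol(down$signals[[1]]), length(t) / 2)

  # interior of the downsampled 5 Hz sinusoid matches the analytic one
  t2 <- t[seq(1, length(t), by = 2)]
  ref <- sin(2 * pi * 5 * t2)
  interior <- 200:(length(t2) - 200)
  expect_lt(max(abs(down$signals[[1]][1, interior] - ref[interior])), 0.01)

  expect_identical(eeg_downsample(rec, fs), rec)
  expect_error(eeg_downsample(rec, 600), "exceeds")
  expect_error(eeg_downsample(rec, 300), "divide")
})

test_that("band-pass isolates the in-band component with zero phase lag", {
  fs <- 250
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  mix <- sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t)
  rec <- rec_from_signals(mix, mix, fs = fs)
  out <- eeg_bandpass(rec, 8, 12)
  expect_equal(out$band_tag, "alpha")
  interior <- 500:(length(t) - 500)
  target <- sin(2 * pi * 10 * t)
  expect_gt(cor(out$signals[[1]][1, interior], target[interior]), 0.99)

  # zero-phase: cross-correlation with the in-band reference peaks at lag 0
  x <- out$signals[[1]][1, interior]
  y <- target[interior]
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    idx <- seq_along(x)
    ok <- idx + l >= 1 & idx + l <= length(y)
    cor(x[idx[ok]], y[idx[ok] + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)

  expect_error(eeg_bandpass(rec, 12, 8), "low < high")
  expect_error(eeg_bandpass(rec, 8, 200), "low < high")
})

test_that("filtering commutes with time reversal (zero-phase property)", {
  fs <- 250
  set.seed(21)
  x <- rnorm(fs * 10)
  rec_f <- rec_from_signals(x, x, fs = fs)
  rec_r <- rec_from_signals(rev(x), rev(x), fs = fs)
  fwd <- eeg_bandpass(rec_f, 8, 12)$signals[[1]][1, ]
  bwd <- eeg_bandpass(rec_r, 8, 12)$signals[[1]][1, ]
  # narrow-band two-pass transients decay over ~3 s; compare the interior
  interior <- 750:(length(x) - 750)
  expect_lt(max(abs(fwd[interior] - rev(bwd)[interior])), 1e-5)
})

test_that("bad-channel interpolation is a convex smooth-field estimator", {
  fs <- 125
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  n_ch <- 29
  # identical signal everywhere: interpolation must reproduce it exactly
  s_t <- sin(2 * pi * 3 * t)
  same <- matrix(rep(s_t, n_ch), nrow = n_ch, byrow = TRUE)
  rec <- dual_recording(same, same, fs,
                        bad_channels = list("Cz", character(0)))
  fixed <- interpolate_bad_channels(rec)
  expect_equal(fixed$signals[[1]]["Cz", ], s_t, tolerance = 1e-10)

  # no bad channels: no-op
  rec2 <- dual_recording(same, same, fs)
  expect_identical(interpolate_bad_channels(rec2), rec2)

  # smooth spatial field: interpolation beats copying the nearest neighbor
  pos <- hb_montage(channels_29)
  u <- as.matrix(pos[, c("x", "y", "z")])
  u <- u / sqrt(rowSums(u^2))
  field <- function(i) 1 + u[i, 1] + 0.7 * u[i, 2] - 0.5 * u[i, 3]
  sig <- t(vapply(seq_len(n_ch), function(i) field(i) * s_t, s_t))
  bad_i <- which(channels_29 == "C3")
  rec3 <- dual_recording(sig, sig, fs,
                         bad_channels = list("C3", character(0)))
  fixed3 <- interpolate_bad_channels(rec3)
  err_interp <- sqrt(mean((fixed3$signals[[1]][bad_i, ] - sig[bad_i, ])^2))
  d <- acos(pmin(1, u %*% u[bad_i, ]))
  nn <- setdiff(order(d), bad_i)[1]
  err_nn <- sqrt(mean((sig[nn, ] - sig[bad_i, ])^2))
  expect_lt(err_interp, err_nn)

  # all channels bad is unrecoverable
  rec4 <- dual_recording(same[1:3, ], same[1:3, ], fs,
                         channel_labels = c("Fz", "Cz", "Pz"),
                         bad_channels = list(c("Fz", "Cz", "Pz"),
                                             character(0)))
  expect_error(interpolate_bad_channels(rec4), "unrecoverable")
})

test_that("Hilbert phase advances linearly for a pure sinusoid", {
  fs <- 250
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 5 * t)
  y <- cos(2 * pi * 5 * t - pi / 3)
  rec <- dual_recording(rbind(x, y), rbind(x, y), fs,
                        channel_labels = c("Fz", "Cz"),
                        band = c(4, 7), band_tag = "theta")
  ps <- hilbert_phase(rec)
  keep <- (ps$trim_samples + 1):(length(t) - ps$trim_samples)

  # unwrapped slope = 2 pi f
  ph <- ps$phases[[1]][1, keep]
  slope <- mean(diff(ph) %% (2 * pi)) * fs
  expect_equal(slope, 2 * pi * 5, tolerance = 0.01 * 2 * pi * 5)

  # constant offset pi/3 between the two channels
  dphi <- (ps$phases[[1]][1, keep] - ps$phases[[1]][2, keep]) %% (2 * pi)
  expect_equal(stats::median(dphi), pi / 3, tolerance = 0.01)

  # phases live in (-pi, pi] and match the analytic signal
  expect_true(all(ps$phases[[1]] > -pi & ps$phases[[1]] <= pi))
  expect_equal(ps$phases[[2]], Arg(ps$analytic[[2]]))
})

test_that("Hilbert phase refuses broadband and degenerate input", {
  fs <- 125
  x <- rnorm(fs * 4)
  broad <- dual_recording(rbind(x), rbind(x), fs, channel_labels = "Cz")
  expect_error(hilbert_phase(broad), "band-limited")

  flat <- dual_recording(rbind(rep(0, fs * 4)), rbind(rep(0, fs * 4)), fs,
                         channel_labels = "Cz",
                         band = c(8, 12), band_tag = "alpha")
  expect_error(hilbert_phase(flat), "degenerate")
})

test_that("channel order is preserved through every preprocessing step", {
  cfg <- sim_config(n_channels = 5, sampling_rate = 500, duration = 4,
                    noise_sd = 0.2, seed = 31)
  rec <- generate_coupled_pair(cfg)
  rec$bad_channels <- list("F3", character(0))
  labs <- rec$channel_labels
  step1 <- eeg_downsample(rec, 250)
  step2 <- eeg_bandpass(step1, 8, 12)
  step3 <- interpolate_bad_channels(step2)
  ps <- hilbert_phase(step3)
  expect_identical(step1$channel_labels, labs)
  expect_identical(step2$channel_labels, labs)
  expect_identical(step3$channel_labels, labs)
  expect_identical(rownames(ps$phases[[1]]), labs)
})
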