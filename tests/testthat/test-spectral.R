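tone_ve <- function(freq = 55, amp = 1, step_at = NULL, step_ratio = 1,
                    fs = 300, n_trials = 3) {
  n <- 8 * fs
  times <- -4 + (seq_len(n) - 1) / fs
  a <- rep(amp, n)
  if (!is.null(step_at)) a[times >= step_at] <- amp * step_ratio
  x <- a * sin(2 * pi * freq * times)
  as_virtual_electrode(epoch_set(matrix(rep(x, n_trials), n_trials,
                                        byrow = TRUE), times, fs, pad_s = 2.5))
}

test_that("the stated multitaper parameters give six DPSS tapers", {
  nw <- 0.5 * 7
  expect_equal(floor(2 * nw - 1), 6)
  h <- dpss_tapers(150, nw)
  expect_equal(ncol(h), 6)
  expect_equal(colSums(h^2), rep(1, 6), tolerance = 1e-10)
  expect_equal(max(abs(crossprod(h) - diag(6))), 0, tolerance = 1e-8)
})

test_that("a stationary tone gives a flat ridge at its frequency", {
  tf <- multitaper_tfr(tone_ve(55))
  ridge <- tf$freqs[apply(tf$power, 2, which.max)]
  expect_true(all(abs(ridge - 55) <= 2))
  p55 <- tf$power[tf$freqs == 56, ]
  expect_lt(sd(p55) / mean(p55), 0.05)
})

test_that("an amplitude step of sqrt(2) doubles multitaper power", {
  tf <- multitaper_tfr(tone_ve(55, step_at = 0, step_ratio = sqrt(2)))
  fi <- which.min(abs(tf$freqs - 55))
  pre <- mean(tf$power[fi, tf$times < -0.4])
  post <- mean(tf$power[fi, tf$times > 0.4])
  expect_lt(abs(post / pre - 2), 0.2)
  bc <- band_power_change(tf, c(40, 70))
  expect_lt(abs(bc$change_db - 3.0103), 0.15)
})

test_that("Hanning TFR resolves alpha tones and their changes", {
  ta <- hanning_tfr(tone_ve(10))
  expect_equal(ta$freqs[which.max(rowMeans(ta$power))], 10)

  # two equal tones at the band edges come out balanced
  fs <- 300; n <- 8 * fs
  times <- -4 + (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 8 * times) + sin(2 * pi * 12 * times)
  ve <- as_virtual_electrode(epoch_set(matrix(x, 1), times, fs, pad_s = 2.5))
  tp <- rowMeans(hanning_tfr(ve)$power)
  expect_lt(abs(tp[1] / tp[5] - 1), 0.2)

  # halved amplitude: -6.02 dB
  th <- hanning_tfr(tone_ve(10, step_at = 0, step_ratio = 0.5))
  bc <- band_power_change(th, c(8, 13))
  expect_lt(abs(bc$change_db - 20 * log10(0.5)), 0.25)
})

test_that("band power change follows the stated dB arithmetic on synthetic TFRs", {
  freqs <- seq(40, 70, 2)
  times <- seq(-1.5, 1.5, 0.05)
  p <- matrix(1, length(freqs), length(times))
  p[, times >= 0] <- 2
  tf <- fake_tfr(freqs, times, p)
  expect_equal(band_power_change(tf, c(40, 70))$change_db, 10 * log10(2),
               tolerance = 1e-12)
  expect_equal(band_power_change(tf, c(40, 70))$change_db, 3.0103,
               tolerance = 1e-4)
  flat <- fake_tfr(freqs, times, matrix(4, length(freqs), length(times)))
  expect_equal(band_power_change(flat, c(40, 70))$change_db, 0)
  zero <- fake_tfr(freqs, times, matrix(0, length(freqs), length(times)))
  expect_error(band_power_change(zero, c(40, 70)), "baseline")
})

test_that("dB change is invariant to global amplitude scaling", {
  ve <- quick_ve(quick_cfg(n_trials = 10, seed = 11))
  ve2 <- ve
  ve2$data <- ve$data * 7.3
  b1 <- band_power_change(multitaper_tfr(ve), c(40, 70))$change_db
  b2 <- band_power_change(multitaper_tfr(ve2), c(40, 70))$change_db
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("peak frequency picks the largest interior maximum, flagging monotone spectra", {
  freqs <- seq(40, 70, 2)
  times <- seq(-1.5, 1.5, 0.05)
  base <- matrix(1, length(freqs), length(times))
  stim <- base
  # two local maxima: higher at 48 than at 62
  bump <- function(f0, h) h * exp(-(freqs - f0)^2 / 8)
  stim[, times >= 0] <- 1 + bump(48, 3) + bump(62, 2)
  tf <- fake_tfr(freqs, times, ifelse(col(stim) > length(times) / 2, stim, base))
  p <- peak_frequency(fake_tfr(freqs, times,
                               cbind(base[, times < 0], stim[, times >= 0])),
                      c(40, 70))
  expect_equal(p$peak_hz, 48)
  expect_true(p$interior)

  mono <- cbind(base[, times < 0],
                matrix(10^(seq(0, 1, length.out = length(freqs)) / 10),
                       length(freqs), sum(times >= 0)))
  pm <- peak_frequency(fake_tfr(freqs, times, mono), c(40, 70))
  expect_equal(pm$peak_hz, 70)
  expect_false(pm$interior)
})

test_that("baseline power scales quadratically and matches a Welch oracle", {
  ve <- noise_ve(n_trials = 60, seed = 12)
  tf <- multitaper_tfr(ve)
  bp <- baseline_band_power(tf, c(40, 70))
  ve2 <- ve
  ve2$data <- ve$data * 2
  expect_equal(baseline_band_power(multitaper_tfr(ve2), c(40, 70)) / bp, 4,
               tolerance = 1e-10)
  # Welch oracle on the same data, same band
  psd <- rowMeans(apply(ve_matrix(ve), 1, function(x) {
    w <- oracle_welch(x, ve$fs, seg_s = 1)
    w$psd
  }))
  fr <- oracle_welch(ve_matrix(ve)[1, ], ve$fs, seg_s = 1)$freq
  expect_lt(abs(bp / mean(psd[fr >= 40 & fr <= 70]) - 1), 0.15)
})

test_that("multitaper white-noise spectrum is flat across the gamma band", {
  ve <- noise_ve(n_trials = 100, seed = 13)
  tf <- multitaper_tfr(ve)
  m <- rowMeans(tf$power)
  expect_lt(max(m) / min(m), 1.5)
})

test_that("peak detection follows the suppression trough for net decreases", {
  freqs <- 8:13
  times <- seq(-1.5, 1.5, 0.1)
  base <- matrix(1, length(freqs), length(times))
  stim <- base
  dip <- 10^(-(2 * exp(-(freqs - 11)^2 / 2)) / 10)   # strongest drop at 11 Hz
  stim[, times >= 0] <- dip
  p <- peak_frequency(fake_tfr(freqs, times,
                               cbind(base[, times < 0], stim[, times >= 0])),
                      c(8, 13))
  expect_equal(p$peak_hz, 11)
  expect_equal(p$sign, -1)
  expect_true(p$interior)
})
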