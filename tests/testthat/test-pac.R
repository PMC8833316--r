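sine_ve <- function(freq, fs = 300, amp = 1, am_freq = NULL, am_depth = 0,
                    n_trials = 2) {
  n <- 8 * fs
  times <- -4 + (seq_len(n) - 1) / fs
  a <- amp * (1 + am_depth * cos(2 * pi * (am_freq %||% 0) * times))
  x <- a * sin(2 * pi * freq * times)
  as_virtual_electrode(epoch_set(matrix(rep(x, n_trials), n_trials,
                                        byrow = TRUE), times, fs, pad_s = 2.5))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("extracted phase advances at the band frequency with cosine convention", {
  ve <- sine_ve(10, fs = 1000)
  ph <- extract_phase(ve, 10)[1, ]
  idx <- which(ve$times > -1 & ve$times < 1)
  slope <- coef(lm(unwrap <- cumsum(c(ph[idx][1], atan2(
    sin(diff(ph[idx])), cos(diff(ph[idx]))))) ~ ve$times[idx]))[2]
  expect_lt(abs(slope / (2 * pi * 10) - 1), 0.01)
  # cosine convention: phase ~ 0 at signal peaks
  x <- ve$data[1, 1, idx]
  pk <- idx[which(diff(sign(diff(x))) == -2) + 1]
  dphi <- atan2(sin(extract_phase(ve, 10)[1, pk]), cos(extract_phase(ve, 10)[1, pk]))
  expect_lt(max(abs(dphi)) * 180 / pi, 5)
})

test_that("the phase filter attenuates off-band tones", {
  ve <- sine_ve(13)                       # 3 Hz off a 10 Hz centre
  amp_in_band <- Mod(oracle_hilbert(
    butter_filter(ve$data[1, 1, ], ve$fs, filter_spec("bandpass", 9, 11))))
  mid <- which(ve$times > -1 & ve$times < 1)
  expect_gt(20 * log10(1 / max(amp_in_band[mid])), 10)
})

test_that("envelope extraction recovers amplitude modulation when the band is wide enough", {
  ve <- sine_ve(60, am_freq = 10, am_depth = 0.6)
  env <- extract_amplitude(ve, 60, half_bw = 13)[1, ]
  idx <- which(ve$times > -1 & ve$times < 1)
  # envelope spectrum peaks at the 10 Hz modulation frequency
  sp <- Mod(fft(env[idx] - mean(env[idx])))^2
  fr <- (seq_along(idx) - 1) / length(idx) * ve$fs
  sub <- which(fr > 2 & fr < 50)
  expect_lt(abs(fr[sub[which.max(sp[sub])]] - 10), 1)

  # flat tone: constant envelope
  ve0 <- sine_ve(60)
  env0 <- extract_amplitude(ve0, 60, half_bw = 13)[1, idx]
  expect_lt(sd(env0) / mean(env0), 0.05)

  # too-narrow band degrades modulation-depth recovery
  depth <- function(e) (max(e) - min(e)) / (max(e) + min(e))
  env5 <- extract_amplitude(ve, 60, half_bw = 5)[1, idx]
  expect_lt(depth(env5), depth(env[idx]))
  expect_error(extract_amplitude(ve0, 140, half_bw = 13), "Nyquist")
})

test_that("MVL matches hand computation and its analytic properties", {
  # 4-point oracle: |2 - 1 + 0i| = 1 -> 1 / (sqrt(4) * sqrt(7))
  expect_equal(mvl_ozkurt(c(0, pi / 2, pi, 3 * pi / 2), c(2, 1, 1, 1)),
               1 / (2 * sqrt(7)), tolerance = 1e-12)
  # uniform phases, constant amplitude: zero
  ph <- seq(0, 2 * pi, length.out = 41)[-41]
  expect_lt(mvl_ozkurt(ph, rep(3, 40)), 1e-10)
  # perfectly concentrated: exactly 1
  expect_equal(mvl_ozkurt(rep(1.1, 7), rep(4, 7)), 1, tolerance = 1e-12)
  # bounds and amplitude-scale invariance on random inputs
  set.seed(20)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    p <- runif(n, -pi, pi)
    a <- rexp(n)
    v <- mvl_ozkurt(p, a)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    expect_equal(mvl_ozkurt(p, a * runif(1, 0.1, 50)), v, tolerance = 1e-12)
  }
  expect_error(mvl_ozkurt(c(0, 1), c(0, 0)), "zero")
  expect_error(mvl_ozkurt(c(0, 1), c(1, -1)), ">= 0")
  expect_error(mvl_ozkurt(c(0, 1, 2), c(1, 1)), "lengths")
})

test_that("comodulogram grids and null level behave as declared", {
  ve <- noise_ve(n_trials = 40, seed = 21)
  cm <- comodulogram(ve)
  expect_equal(dim(cm$values), c(7, 34))
  expect_equal(cm$phase_freqs, 7:13)
  expect_equal(cm$amp_freqs, seq(34, 100, 2))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  expect_lt(max(cm$values), 0.1)
})

test_that("programmed coupling is localised to the right comodulogram bin", {
  cfg <- quick_cfg(n_trials = 30, coupling_m = 0.8, seed = 22)
  cm <- corrected_comodulogram(quick_ve(cfg))
  pk <- arrayInd(which.max(cm$values), dim(cm$values))
  expect_lte(abs(cm$phase_freqs[pk[1]] - cfg$alpha_freq), 1)
  expect_lte(abs(cm$amp_freqs[pk[2]] - cfg$gamma_freq), 2)
  expect_true(cm$corrected)
  expect_true(all(cm$values >= -1 & cm$values <= 1))
})

test_that("baseline correction cancels stationary coupling and keeps induced coupling", {
  # same coupling pre and post onset: corrected values at the noise scale
  cfg_st <- quick_cfg(n_trials = 25, coupling_m = 0.6, coupling_m_base = 0.6,
                      gamma_amp_stim = 1.5, alpha_amp_stim = 3, seed = 23)
  cm_st <- corrected_comodulogram(quick_ve(cfg_st))
  cm_unc <- comodulogram(quick_ve(cfg_st))
  expect_lt(max(abs(cm_st$values)), 0.05)

  # coupling only post onset: corrected ~ uncorrected at the peak bin
  cfg_in <- quick_cfg(n_trials = 25, coupling_m = 0.6, coupling_m_base = 0,
                      seed = 23)
  ve_in <- quick_ve(cfg_in)
  cm_cor <- corrected_comodulogram(ve_in)
  cm_raw <- comodulogram(ve_in)
  pk <- which.max(cm_raw$values)
  expect_lt(abs(cm_cor$values[pk] - cm_raw$values[pk]),
            0.25 * cm_raw$values[pk])
  expect_error(corrected_comodulogram(ve_in, stim_win = c(0.3, 1.5),
                                      base_win = c(-1.5, -0.5)), "equal")
})

test_that("uncoupled PAC sits at the trial-shuffled surrogate level", {
  cfg <- quick_cfg(n_trials = 20, coupling_m = 0, seed = 24)
  ve <- quick_ve(cfg)
  ph <- extract_phase(ve, 10)
  am <- extract_amplitude(ve, 55)
  idx <- which(ve$times >= 0.3 & ve$times <= 1.5)
  obs <- mvl_ozkurt(as.numeric(t(ph[, idx])), as.numeric(t(am[, idx])))
  set.seed(24)
  surr <- replicate(200, {
    shuf <- sample(nrow(am))
    mvl_ozkurt(as.numeric(t(ph[, idx])), as.numeric(t(am[shuf, idx])))
  })
  expect_lt(abs(obs - mean(surr)), 3 * sd(surr))
})

test_that("per-trial MVL mode agrees with concatenated mode on stationary coupling", {
  cfg <- quick_cfg(n_trials = 12, coupling_m = 0.8, noise_amp = 0.3, seed = 25)
  ve <- quick_ve(cfg)
  cc <- comodulogram(ve, phase_freqs = 9:11, amp_freqs = c(54, 56))
  ct <- comodulogram(ve, phase_freqs = 9:11, amp_freqs = c(54, 56),
                     per_trial = TRUE)
  # same coupling structure; estimates differ only by estimator variance
  expect_equal(which.max(cc$values), which.max(ct$values))
  expect_lt(max(abs(cc$values - ct$values)), 0.1)
})

test_that("comodulograms are insensitive to analysing at the raw or decimated rate", {
  cfg <- subject_sim_config(fs_raw = 1000, n_trials = 12, coupling_m = 0.8,
                            seed = 26)
  ep <- simulate_subject(cfg)
  cm_raw <- corrected_comodulogram(as_virtual_electrode(ep),
                                   phase_freqs = 9:11,
                                   amp_freqs = seq(48, 62, 2))
  cm_dec <- corrected_comodulogram(as_virtual_electrode(preprocess_epochs(ep)),
                                   phase_freqs = 9:11,
                                   amp_freqs = seq(48, 62, 2))
  expect_equal(which.max(cm_raw$values), which.max(cm_dec$values))
  expect_lt(max(abs(cm_raw$values - cm_dec$values)), 0.05)
})
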