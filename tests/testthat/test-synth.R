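test_that("1/f noise has the requested spectral slope and is reproducible", {
  fit_slope <- function(x, fs) {
    w <- oracle_welch(x, fs, seg_s = 2)
    keep <- w$freq >= 1 & w$freq <= 100
    unname(coef(lm(log10(w$psd[keep]) ~ log10(w$freq[keep])))[2])
  }
  pink <- one_over_f_noise(1, 120, 1000, seed = 3)
  expect_gt(fit_slope(pink, 1000), -1.3)
  expect_lt(fit_slope(pink, 1000), -0.7)
  white <- one_over_f_noise(0, 120, 1000, seed = 3)
  expect_lt(abs(fit_slope(white, 1000)), 0.3)
  expect_identical(one_over_f_noise(1, 5, 500, seed = 9),
                   one_over_f_noise(1, 5, 500, seed = 9))
  expect_lt(abs(mean(pink)), 1e-8)
  expect_error(one_over_f_noise(1, 5, -10), "fs")
  expect_error(one_over_f_noise(-1, 5, 100), "exponent")
})

test_that("zero coupling gives a flat gamma envelope; full coupling peaks at the preferred phase", {
  cfg <- quick_cfg(fs_raw = 1000, coupling_m = 0, noise_amp = 0,
                   alpha_amp_stim = 0, alpha_amp_base = 0)
  x <- make_pac_signal(cfg, 4, stim_on = TRUE, phase0 = 0.7, psi0 = 0.2)
  env <- Mod(oracle_hilbert(x))
  mid <- env[400:3600]
  expect_lt(max(mid) - min(mid), 1e-6 * max(mid))

  pref <- pi / 3
  cfg2 <- quick_cfg(fs_raw = 1000, coupling_m = 1, noise_amp = 0,
                    alpha_amp_stim = 0, alpha_amp_base = 0,
                    coupling_phase_pref = pref, alpha_freq = 10,
                    gamma_freq = 55)
  x2 <- make_pac_signal(cfg2, 4, stim_on = TRUE, phase0 = 0.7, psi0 = 0.2)
  env2 <- Mod(oracle_hilbert(x2))
  t <- (seq_along(x2) - 1) / 1000
  alpha_phase <- (2 * pi * 10 * t + 0.7) %% (2 * pi)
  # analytic phase at each envelope peak must sit within 10 deg of pref
  interior <- 400:3600
  pk <- interior[which(diff(sign(diff(env2[interior]))) == -2) + 1]
  pk <- pk[env2[pk] > 0.9 * max(env2[interior])]
  dphi <- atan2(sin(alpha_phase[pk] - pref), cos(alpha_phase[pk] - pref))
  expect_lt(max(abs(dphi)) * 180 / pi, 10)
})

test_that("gamma power is invariant to the programmed modulation depth", {
  pwr <- vapply(c(0, 0.5, 1), function(m) {
    cfg <- quick_cfg(fs_raw = 1000, coupling_m = m, noise_amp = 0,
                     alpha_amp_stim = 0, alpha_amp_base = 0)
    mean(make_pac_signal(cfg, 10, TRUE, phase0 = 0, psi0 = 0)^2)
  }, numeric(1))
  expect_lt(max(abs(pwr / pwr[1] - 1)), 0.01)
})

test_that("simulate_subject records exact ground-truth dB and epoch geometry", {
  cfg <- quick_cfg(n_trials = 3, gamma_amp_base = 1, gamma_amp_stim = 1)
  ep <- simulate_subject(cfg)
  expect_identical(ep$truth$gamma_change_db, 0)

  cfg2 <- quick_cfg(n_trials = 3, gamma_amp_base = 1, gamma_amp_stim = sqrt(2))
  ep2 <- simulate_subject(cfg2)
  expect_equal(ep2$truth$gamma_change_db, 20 * log10(sqrt(2)), tolerance = 1e-12)
  expect_equal(ep2$truth$gamma_change_db, 3.0103, tolerance = 1e-4)

  # default design: 110 trials, 1.5 s pre/post analysis window, 2.5 s padding
  def <- subject_sim_config()
  expect_equal(def$n_trials, 110)
  expect_equal(c(def$epoch_pre_s, def$epoch_post_s, def$pad_s), c(1.5, 1.5, 2.5))
  d <- dim(ep$data)
  expect_equal(d, c(3, 1, round((1.5 + 1.5 + 5) * cfg$fs_raw)))
  expect_equal(min(ep$times), -(1.5 + 2.5))
  expect_lt(abs(max(ep$times) - (1.5 + 2.5 - 1 / cfg$fs_raw)), 1e-9)
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_subject(quick_cfg(n_trials = 2, seed = 42))
  b <- simulate_subject(quick_cfg(n_trials = 2, seed = 42))
  expect_identical(a$data, b$data)
})

test_that("config validation rejects invalid values", {
  expect_error(quick_cfg(coupling_m = 1.2), "coupling_m")
  expect_error(quick_cfg(gamma_amp_base = -1), "amplitudes")
  expect_error(quick_cfg(n_trials = 0), "n_trials")
  expect_error(quick_cfg(alpha_freq = NaN), "non-finite")
})

test_that("cohort defaults give 18 + 16 subjects and zero-SD groups are homogeneous", {
  spec <- cohort_spec()
  expect_equal(spec$n_group_a + spec$n_group_b, 34)
  small <- cohort_spec(
    n_group_a = 2, n_group_b = 2,
    base_cfg = quick_cfg(n_trials = 2),
    group_a = list(n_trials = 2, gamma_db_sd = 0, alpha_db_sd = 0,
                   coupling_m_sd = 0, gamma_freq_sd = 0, alpha_freq_sd = 0),
    group_b = list(n_trials = 2), master_seed = 7)
  cohort <- simulate_cohort(small)
  expect_length(cohort, 4)
  expect_equal(vapply(cohort, function(s) s$group, ""),
               c("patient", "patient", "control", "control"))
  tr <- lapply(cohort[1:2], `[[`, "truth")
  expect_equal(tr[[1]]$gamma_change_db, tr[[2]]$gamma_change_db)
  expect_equal(tr[[1]]$coupling_m, tr[[2]]$coupling_m)
})

test_that("cohort parameter draws reproduce the generating Cohen's d", {
  # population d of the generating normals: (3.20 - 2.27) / 1.26
  d_pop <- (3.20 - 2.27) / 1.26
  spec <- cohort_spec()
  ds <- replicate(200, {
    seed <- sample.int(1e6, 1)
    ga <- vapply(1:18, function(i) {
      cfg <- megosc:::draw_subject_cfg(spec, spec$group_a,
                                       megosc:::derive_seed(seed, i))
      20 * log10(cfg$gamma_amp_stim / cfg$gamma_amp_base)
    }, numeric(1))
    gb <- vapply(1:16, function(i) {
      cfg <- megosc:::draw_subject_cfg(spec, spec$group_b,
                                       megosc:::derive_seed(seed, 100 + i))
      20 * log10(cfg$gamma_amp_stim / cfg$gamma_amp_base)
    }, numeric(1))
    independent_t(ga, gb)$d
  })
  expect_equal(mean(ds), d_pop, tolerance = 3 * sd(ds) / sqrt(length(ds)) / d_pop + 0.05)
})

test_that("sensor projection is exact for unit lead fields and linear in sources", {
  model <- toy_source_model()
  src <- simulate_subject(quick_cfg(n_trials = 2, seed = 3))
  # unit-vector lead-field column: channel 3 carries the source exactly
  m2 <- model
  m2$leadfield[, 5] <- 0
  m2$leadfield[3, 5] <- 1
  sens <- project_to_sensors(src, m2, 5, sensor_noise_amp = 0)
  expect_equal(sens$data[, 3, ], src$data[, 1, ])
  expect_equal(max(abs(sens$data[, 1, ])), 0)

  # linearity: projecting the sum equals the sum of projections
  s1 <- project_to_sensors(src, model, 2, 0)
  s2 <- project_to_sensors(src, model, 9, 0)
  both <- model$leadfield[, 2, drop = FALSE] %*% src$data[1, 1, ] +
          model$leadfield[, 9, drop = FALSE] %*% src$data[1, 1, ]
  expect_equal(s1$data[1, , ] + s2$data[1, , ], unname(both), tolerance = 1e-12)

  # strongest band power lands on the sensor with the largest lead-field weight
  g <- which(model$roi_mask)[2]
  sens3 <- project_to_sensors(src, model, g, sensor_noise_amp = 1e-3, seed = 1)
  bp <- butter_filter(t(matrix(sens3$data[1, , ], nrow = dim(sens3$data)[2])),
                      sens3$fs, filter_spec("bandpass", 40, 70))
  expect_equal(which.max(apply(bp, 2, var)),
               which.max(abs(model$leadfield[, g])))
  expect_error(project_to_sensors(src, model, 1000), "source_index")
})

test_that("measured MVL increases with programmed modulation depth", {
  ms <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- vapply(ms, function(m) {
    cfg <- quick_cfg(n_trials = 8, coupling_m = m, noise_amp = 0, seed = 2)
    ve <- quick_ve(cfg)
    ph <- extract_phase(ve, cfg$alpha_freq)
    am <- extract_amplitude(ve, cfg$gamma_freq)
    idx <- which(ve$times >= 0.3 & ve$times <= 1.5)
    mvl_ozkurt(as.numeric(ph[, idx]), as.numeric(am[, idx]))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
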