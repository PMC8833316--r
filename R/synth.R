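#' Subject-level simulation parameters
#'
#' Defines one synthetic subject's signal model: a 1/f background, an
#' ongoing alpha oscillation whose amplitude drops after stimulus onset, a
#' narrow-band induced gamma oscillation whose amplitude rises after onset,
#' and alpha-phase to gamma-amplitude coupling of controllable modulation
#' depth.  Each trial is generated as
#' \deqn{x(t) = a_\alpha \sin(2\pi f_\alpha t + \phi_0) +
#'       g(t)\sin(2\pi f_\gamma t + \psi_0) + \mathrm{noise}(t),}
#' with gamma envelope
#' \deqn{g(t) = a_\gamma \frac{1 + m\cos(\phi_\alpha(t) - \phi_{pref})}
#'   {\sqrt{1 + m^2/2}},}
#' where \eqn{\phi_\alpha(t)} is the instantaneous alpha phase.  Because
#' the mean square of \eqn{1 + m\cos(\cdot)} is \eqn{1 + m^2/2}, this
#' normalisation keeps total gamma power exactly independent of the
#' modulation depth \eqn{m}, so coupling strength and power change can be
#' manipulated separately.  Trial phases \eqn{\phi_0,\psi_0}
#' are randomised per trial, so stimulus responses are induced, not evoked.
#'
#' @param fs_raw Raw sampling rate (Hz); epochs are later decimated.
#' @param n_trials Number of trials.
#' @param epoch_pre_s,epoch_post_s Analysis window before/after onset (s).
#' @param pad_s Extra padding on each side, absorbing filter edges (s).
#' @param alpha_freq Alpha oscillation frequency (Hz).
#' @param alpha_amp_base,alpha_amp_stim Alpha amplitude before/after onset.
#' @param gamma_freq Gamma oscillation frequency (Hz).
#' @param gamma_amp_base,gamma_amp_stim Gamma amplitude before/after onset.
#' @param coupling_m Post-onset modulation depth of the gamma envelope by
#'   alpha phase, in `[0, 1]`.
#' @param coupling_m_base Pre-onset modulation depth (default 0: coupling
#'   is stimulus-induced).
#' @param coupling_phase_pref Preferred alpha phase of the gamma envelope
#'   maximum (radians, cosine convention).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_amp Standard deviation of the background noise.
#' @param seed Integer seed for this subject's trial stream.
#' @return A list of class `subject_sim_config`.
#' @export
subject_sim_config <- function(fs_raw = 1000, n_trials = 110,
                               epoch_pre_s = 1.5, epoch_post_s = 1.5,
                               pad_s = 2.5,
                               alpha_freq = 10, alpha_amp_base = 3,
                               alpha_amp_stim = 3 * 10^(-2 / 20),
                               gamma_freq = 55, gamma_amp_base = 1.5,
                               gamma_amp_stim = 1.5 * 10^(3 / 20),
                               coupling_m = 0.3, coupling_m_base = 0,
                               coupling_phase_pref = 0,
                               noise_exponent = 1, noise_amp = 1,
                               seed = 1L) {
  cfg <- list(fs_raw = fs_raw, n_trials = n_trials,
              epoch_pre_s = epoch_pre_s, epoch_post_s = epoch_post_s,
              pad_s = pad_s, alpha_freq = alpha_freq,
              alpha_amp_base = alpha_amp_base, alpha_amp_stim = alpha_amp_stim,
              gamma_freq = gamma_freq, gamma_amp_base = gamma_amp_base,
              gamma_amp_stim = gamma_amp_stim, coupling_m = coupling_m,
              coupling_m_base = coupling_m_base,
              coupling_phase_pref = coupling_phase_pref,
              noise_exponent = noise_exponent, noise_amp = noise_amp,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "subject_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (!all(is.finite(num))) stop("non-finite simulation config value")
  if (cfg$coupling_m < 0 || cfg$coupling_m > 1 ||
      cfg$coupling_m_base < 0 || cfg$coupling_m_base > 1)
    stop("coupling_m must lie in [0, 1]")
  amps <- c(cfg$alpha_amp_base, cfg$alpha_amp_stim, cfg$gamma_amp_base,
            cfg$gamma_amp_stim, cfg$noise_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (cfg$n_trials < 1) stop("n_trials must be >= 1")
  if (cfg$epoch_pre_s <= 0 || cfg$epoch_post_s <= 0 || cfg$pad_s < 0)
    stop("epoch windows must be positive")
  if (cfg$noise_exponent < 0) stop("noise_exponent must be >= 0")
  invisible(cfg)
}

#' 1/f^beta background noise
#'
#' Spectrally shaped Gaussian noise: a white series is shaped in the
#' frequency domain by \eqn{f^{-\beta/2}} (DC removed) and standardised to
#' zero mean, unit variance.  The log-log power spectral density slope over
#' 1-100 Hz approaches \eqn{-\beta} for long series.
#'
#' @param exponent Spectral slope beta (>= 0; 0 gives white noise).
#' @param duration_s Duration (s).
#' @param fs Sampling rate (Hz), > 0.
#' @param seed Optional integer seed; the same seed gives the identical
#'   series.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
one_over_f_noise <- function(exponent, duration_s, fs, seed = NULL) {
  if (fs <= 0) stop("fs must be > 0")
  if (exponent < 0) stop("exponent must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  stopifnot(n >= 2)
  w <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]          # mirror to physical frequency
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate one trial of the coupled alpha-gamma signal
#'
#' @param cfg A [subject_sim_config()].
#' @param duration_s Trial duration (s), > 0.
#' @param stim_on If `TRUE`, stimulus-period amplitudes and coupling depth
#'   are used; otherwise baseline values.
#' @param t0 Time of the first sample (s); alpha/gamma phases are continuous
#'   functions of absolute time plus the per-trial offsets.
#' @param phase0,psi0 Alpha/gamma phase offsets (radians); drawn uniformly
#'   from the current RNG stream when `NULL`.
#' @return Numeric time series of length `round(duration_s * fs_raw)`.
#' @export
make_pac_signal <- function(cfg, duration_s, stim_on = TRUE, t0 = 0,
                            phase0 = NULL, psi0 = NULL) {
  validate_sim_config(cfg)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (is.null(phase0)) phase0 <- stats::runif(1, 0, 2 * pi)
  if (is.null(psi0)) psi0 <- stats::runif(1, 0, 2 * pi)
  n <- round(duration_s * cfg$fs_raw)
  t <- t0 + (seq_len(n) - 1) / cfg$fs_raw
  a_alpha <- if (stim_on) cfg$alpha_amp_stim else cfg$alpha_amp_base
  a_gamma <- if (stim_on) cfg$gamma_amp_stim else cfg$gamma_amp_base
  m <- if (stim_on) cfg$coupling_m else cfg$coupling_m_base
  phi <- 2 * pi * cfg$alpha_freq * t + phase0
  env <- a_gamma * (1 + m * cos(phi - cfg$coupling_phase_pref)) /
         sqrt(1 + m^2 / 2)
  x <- a_alpha * sin(phi) + env * sin(2 * pi * cfg$gamma_freq * t + psi0)
  if (cfg$noise_amp > 0)
    x <- x + cfg$noise_amp * one_over_f_noise(cfg$noise_exponent, duration_s,
                                              cfg$fs_raw)
  x
}

#' Simulate a single-channel epoched subject recording
#'
#' Generates `n_trials` epochs covering
#' `[-(epoch_pre_s + pad_s), epoch_post_s + pad_s)` seconds around stimulus
#' onset at the raw sampling rate.  Pre-onset samples use baseline
#' amplitudes and coupling, post-onset samples the stimulus values; alpha
#' and gamma phases are continuous across the onset.  The returned
#' `epoch_set` records the programmed ground truth: dB amplitude changes
#' (`20 log10` of the stimulus/baseline amplitude ratio) and coupling depth.
#'
#' @param cfg A [subject_sim_config()].
#' @param subject,group Metadata labels.
#' @return An [epoch_set()] with one channel.
#' @export
simulate_subject <- function(cfg, subject = "s01", group = NA_character_) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$fs_raw
  pre_s <- cfg$epoch_pre_s + cfg$pad_s
  post_s <- cfg$epoch_post_s + cfg$pad_s
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  times <- (seq_len(n_pre + n_post) - n_pre - 1) / fs
  dat <- array(0, c(cfg$n_trials, 1L, n_pre + n_post))
  for (tr in seq_len(cfg$n_trials)) {
    phase0 <- stats::runif(1, 0, 2 * pi)
    psi0 <- stats::runif(1, 0, 2 * pi)
    pre <- make_pac_signal(cfg, pre_s, stim_on = FALSE, t0 = -pre_s,
                           phase0 = phase0, psi0 = psi0)
    post <- make_pac_signal(cfg, post_s, stim_on = TRUE, t0 = 0,
                            phase0 = phase0, psi0 = psi0)
    dat[tr, 1L, ] <- c(pre, post)
  }
  truth <- list(
    gamma_change_db = 20 * log10(cfg$gamma_amp_stim / cfg$gamma_amp_base),
    alpha_change_db = 20 * log10(cfg$alpha_amp_stim / cfg$alpha_amp_base),
    coupling_m = cfg$coupling_m, alpha_freq = cfg$alpha_freq,
    gamma_freq = cfg$gamma_freq)
  epoch_set(dat, times, fs, subject = subject, group = group,
            pad_s = cfg$pad_s, truth = truth)
}

#' Cohort-level simulation design
#'
#' Describes a two-group study: group sizes, a template subject
#' configuration, and per-group distributions (mean and between-subject SD)
#' of the stimulus-induced gamma change (dB), alpha change (dB), coupling
#' depth, and oscillation peak frequencies.  The defaults emulate a
#' patient/control MEG grating study: 18 vs 16 subjects with roughly 110
#' and 117 clean trials each, gamma power increases of 3.20 vs 2.27 dB
#' (between-subject SD 1.26 dB), alpha decreases of -1.57 vs -1.99 dB
#' (SD 1.4 dB), and alpha-gamma coupling reduced in the patient group.
#'
#' @param n_group_a,n_group_b Subject counts (>= 2).
#' @param group_a,group_b Named lists overriding entries of
#'   [cohort_group_defaults()] for each group.
#' @param base_cfg Template [subject_sim_config()]; per-subject draws
#'   overwrite its amplitude/frequency/coupling fields.
#' @param master_seed Integer seed from which all per-subject seeds derive.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 18, n_group_b = 16,
                        group_a = list(), group_b = list(),
                        base_cfg = subject_sim_config(),
                        master_seed = 1L) {
  if (n_group_a < 2 || n_group_b < 2) stop("group sizes must be >= 2")
  ga <- utils::modifyList(cohort_group_defaults("patient"), group_a)
  gb <- utils::modifyList(cohort_group_defaults("control"), group_b)
  for (g in list(ga, gb))
    if (any(unlist(g[grep("_sd$", names(g))]) < 0))
      stop("between-subject SDs must be >= 0")
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 group_a = ga, group_b = gb, base_cfg = base_cfg,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Default per-group generating distributions
#'
#' @param group `"patient"` or `"control"`.
#' @return Named list of group-level means and between-subject SDs.
#' @export
cohort_group_defaults <- function(group = c("patient", "control")) {
  group <- match.arg(group)
  if (group == "patient")
    list(label = "patient", n_trials = 110,
         gamma_db_mean = 3.20, gamma_db_sd = 1.26,
         alpha_db_mean = -1.57, alpha_db_sd = 1.4,
         coupling_m_mean = 0.04, coupling_m_sd = 0.065,
         gamma_freq_mean = 53.2, gamma_freq_sd = 3,
         alpha_freq_mean = 10.8, alpha_freq_sd = 1)
  else
    list(label = "control", n_trials = 117,
         gamma_db_mean = 2.27, gamma_db_sd = 1.26,
         alpha_db_mean = -1.99, alpha_db_sd = 1.4,
         coupling_m_mean = 0.12, coupling_m_sd = 0.065,
         gamma_freq_mean = 52.6, gamma_freq_sd = 3,
         alpha_freq_mean = 10.7, alpha_freq_sd = 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one subject's config from a group distribution.
draw_subject_cfg <- function(spec, grp, seed) {
  set.seed(seed)
  cfg <- spec$base_cfg
  cfg$n_trials <- grp$n_trials
  g_db <- stats::rnorm(1, grp$gamma_db_mean, grp$gamma_db_sd)
  a_db <- stats::rnorm(1, grp$alpha_db_mean, grp$alpha_db_sd)
  cfg$gamma_amp_stim <- cfg$gamma_amp_base * 10^(g_db / 20)
  cfg$alpha_amp_stim <- cfg$alpha_amp_base * 10^(a_db / 20)
  cfg$coupling_m <- clamp(stats::rnorm(1, grp$coupling_m_mean,
                                       grp$coupling_m_sd), 0, 1)
  cfg$gamma_freq <- clamp(stats::rnorm(1, grp$gamma_freq_mean,
                                       grp$gamma_freq_sd), 42, 68)
  cfg$alpha_freq <- clamp(stats::rnorm(1, grp$alpha_freq_mean,
                                       grp$alpha_freq_sd), 8.5, 12.5)
  cfg$seed <- derive_seed(seed, 1L)
  cfg
}

#' Simulate a two-group cohort
#'
#' Draws each subject's generating parameters from the group distributions
#' in a [cohort_spec()] (seeds derived deterministically from
#' `master_seed`), then simulates each subject with [simulate_subject()].
#'
#' @param spec A [cohort_spec()].
#' @return List of [epoch_set()] objects with group labels; the drawn
#'   per-subject ground truth is recorded in each element's `truth`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", spec$n_group_a + spec$n_group_b)
  k <- 0L
  for (gi in 1:2) {
    grp <- if (gi == 1) spec$group_a else spec$group_b
    n <- if (gi == 1) spec$n_group_a else spec$n_group_b
    for (i in seq_len(n)) {
      k <- k + 1L
      cfg <- draw_subject_cfg(spec, grp, derive_seed(spec$master_seed, k))
      out[[k]] <- simulate_subject(cfg, subject = sprintf("%s%02d", grp$label, i),
                                   group = grp$label)
    }
  }
  out
}
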