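# Shared fixture builders.  Everything is generated in code at test time.

# Small, fast subject configuration: simulated directly at the analysis
# rate (no decimation stage) unless a test needs the raw-rate chain.
quick_cfg <- function(..., fs_raw = 300, n_trials = 20, seed = 1L) {
  subject_sim_config(fs_raw = fs_raw, n_trials = n_trials, seed = seed, ...)
}

quick_ve <- function(cfg = quick_cfg()) {
  as_virtual_electrode(simulate_subject(cfg))
}

# White-noise virtual electrode (for null-behaviour checks).
noise_ve <- function(n_trials = 20, fs = 300, dur = c(-4, 4), pad = 2.5,
                     seed = 1) {
  set.seed(seed)
  n <- round((dur[2] - dur[1]) * fs)
  times <- dur[1] + (seq_len(n) - 1) / fs
  as_virtual_electrode(epoch_set(matrix(rnorm(n_trials * n), n_trials, n),
                                 times, fs, pad_s = pad))
}

# Independent FFT-based analytic signal (oracle; deliberately separate
# from the package's implementation path).
oracle_hilbert <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  fft(X * h, inverse = TRUE) / n
}

# Welch-style averaged periodogram (oracle), two-sided density scale.
oracle_welch <- function(x, fs, seg_s = 2) {
  nseg <- floor(seg_s * fs)
  k <- floor(length(x) / nseg)
  P <- 0
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)]
    P <- P + Mod(fft(seg - mean(seg)))^2 / (nseg * fs)
  }
  list(freq = (seq_len(nseg) - 1) / nseg * fs, psd = P / k)
}

# Synthetic time-frequency object with prescribed per-bin power levels.
fake_tfr <- function(freqs, times, power) {
  structure(list(power = power, freqs = freqs, times = times,
                 taper_info = list(method = "synthetic"), fs = NA,
                 subject = "fake", group = NA), class = "tfr")
}

# Brute-force cluster-test oracle: t.test per bin, recursive flood fill,
# independent of the package's vectorised implementation.
oracle_cluster_p <- function(A, B, connectivity = 4) {
  n1 <- length(A); n2 <- length(B); n <- n1 + n2
  all_mats <- c(A, B)
  dm <- dim(A[[1]])
  tmap_for <- function(ia) {
    ib <- setdiff(seq_len(n), ia)
    t_bin <- function(i) {
      x <- vapply(all_mats[ia], `[`, numeric(1), i)
      y <- vapply(all_mats[ib], `[`, numeric(1), i)
      unname(t.test(x, y, var.equal = TRUE)$statistic)
    }
    matrix(vapply(seq_len(prod(dm)), t_bin, numeric(1)), dm[1], dm[2])
  }
  comps <- function(mask) {
    lab <- matrix(0L, dm[1], dm[2]); cur <- 0L
    fill <- function(i, j, id) {
      if (i < 1 || j < 1 || i > dm[1] || j > dm[2]) return()
      if (!mask[i, j] || lab[i, j] != 0L) return()
      lab[i, j] <<- id
      fill(i - 1, j, id); fill(i + 1, j, id)
      fill(i, j - 1, id); fill(i, j + 1, id)
    }
    for (j in seq_len(dm[2])) for (i in seq_len(dm[1]))
      if (mask[i, j] && lab[i, j] == 0L) { cur <- cur + 1L; fill(i, j, cur) }
    lab
  }
  tcrit <- qt(0.975, n - 2)
  stat_tails <- function(tm) {
    out <- c(pos = 0, neg = 0)
    for (s in c(1, -1)) {
      mask <- if (s > 0) tm > tcrit else tm < -tcrit
      if (!any(mask)) next
      lab <- comps(mask)
      v <- vapply(seq_len(max(lab)), function(k) max(abs(tm[lab == k])),
                  numeric(1))
      out[if (s > 0) "pos" else "neg"] <- max(v)
    }
    out
  }
  labelings <- combn(n, n1)
  null <- t(apply(labelings, 2, function(ia) stat_tails(tmap_for(ia))))
  obs_t <- tmap_for(seq_len(n1))
  obs <- stat_tails(obs_t)
  list(p_pos = mean(null[, "pos"] >= obs["pos"] - 1e-12),
       p_neg = mean(null[, "neg"] >= obs["neg"] - 1e-12),
       obs = obs)
}
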