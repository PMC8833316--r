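#' End-to-end replication configuration
#'
#' Bundles every stage's settings: the cohort design, the toy forward
#' model and which grid point hosts the simulated source, sensor noise,
#' pre-processing, beamformer, spectral, PAC and statistics parameters.
#'
#' @param cohort A [cohort_spec()].
#' @param model A [toy_source_model()].
#' @param source_index Grid point of the simulated source; default is the
#'   first ROI point.
#' @param sensor_noise_amp SD of sensor noise added by the forward
#'   projection.
#' @param target_fs Analysis sampling rate after decimation (Hz).
#' @param gamma_band,alpha_band Analysis bands (Hz).
#' @param stim_win,base_win Stimulus/baseline windows (s).
#' @param lambda_pct Beamformer regularisation.
#' @param phase_freqs,amp_freqs PAC comodulogram grids (Hz).
#' @param n_perm,connectivity,cluster_stat Cluster-test settings.
#' @param ve_weights `"gamma"` (default): the virtual electrode applies the
#'   gamma-band-derived spatial filter to broadband data; `"broadband"`:
#'   the filter is recomputed from broadband covariance at the selected
#'   grid point.
#' @param seed Master seed; every stage's randomness derives from it.
#' @return List of class `replication_config`.
#' @export
replication_config <- function(cohort = cohort_spec(),
                               model = toy_source_model(),
                               source_index = which(model$roi_mask)[1],
                               sensor_noise_amp = 0.3,
                               target_fs = 300,
                               gamma_band = c(40, 70), alpha_band = c(8, 13),
                               stim_win = c(0.3, 1.5),
                               base_win = c(-1.5, -0.3),
                               lambda_pct = 5,
                               phase_freqs = 7:13,
                               amp_freqs = seq(34, 100, 2),
                               n_perm = 10000, connectivity = 4,
                               cluster_stat = "max",
                               ve_weights = c("gamma", "broadband"),
                               seed = 1L) {
  ve_weights <- match.arg(ve_weights)
  structure(list(cohort = cohort, model = model, source_index = source_index,
                 sensor_noise_amp = sensor_noise_amp, target_fs = target_fs,
                 gamma_band = gamma_band, alpha_band = alpha_band,
                 stim_win = stim_win, base_win = base_win,
                 lambda_pct = lambda_pct, phase_freqs = phase_freqs,
                 amp_freqs = amp_freqs, ve_weights = ve_weights,
                 n_perm = n_perm,
                 connectivity = connectivity, cluster_stat = cluster_stat,
                 seed = as.integer(seed)),
            class = "replication_config")
}

#' Per-subject analysis: sensors to metrics
#'
#' Runs one subject's sensor epochs through the full chain: pre-processing
#' (band-pass, notch, decimation), gamma/alpha source power maps, ROI peak
#' selection, virtual-electrode extraction, spectral metrics, and the
#' baseline-corrected comodulogram.
#'
#' @param sensors Multi-channel [epoch_set()].
#' @param config A [replication_config()].
#' @return List: `metrics` (one-row data.frame), `comodulogram`,
#'   `roi_index`, `gamma_map`, `ve`.
#' @export
analyze_subject <- function(sensors, config) {
  ep <- preprocess_epochs(sensors, target_fs = config$target_fs)
  gmap <- source_power_map(ep, config$model, config$gamma_band,
                           config$stim_win, config$base_win,
                           config$lambda_pct)
  roi <- select_roi_peak(gmap, config$model)
  filt <- if (identical(config$ve_weights, "broadband")) {
    Cb <- covariance_window(ep, config$base_win[1], config$base_win[2])
    Cs <- covariance_window(ep, config$stim_win[1], config$stim_win[2])
    lcmv_filter(config$model, roi, regularize((Cb + Cs) / 2, config$lambda_pct),
                config$lambda_pct)
  } else gmap$filters[[roi]]
  ve <- virtual_electrode(ep, filt)
  tg <- multitaper_tfr(ve)
  ta <- hanning_tfr(ve)
  g_change <- band_power_change(tg, config$gamma_band, config$stim_win,
                                config$base_win)
  a_change <- band_power_change(ta, config$alpha_band, config$stim_win,
                                config$base_win)
  g_peak <- peak_frequency(tg, config$gamma_band, config$stim_win,
                           config$base_win)
  a_peak <- peak_frequency(ta, config$alpha_band, config$stim_win,
                           config$base_win)
  comod <- corrected_comodulogram(ve, config$stim_win, config$base_win,
                                  config$phase_freqs, config$amp_freqs)
  metrics <- data.frame(
    subject = sensors$subject, group = sensors$group,
    gamma_db = g_change$change_db, alpha_db = a_change$change_db,
    gamma_peak_hz = g_peak$peak_hz, gamma_peak_interior = g_peak$interior,
    alpha_peak_hz = a_peak$peak_hz, alpha_peak_interior = a_peak$interior,
    gamma_baseline_power = baseline_band_power(tg, config$gamma_band,
                                               config$base_win),
    roi_index = roi,
    truth_gamma_db = sensors$truth$gamma_change_db %||% NA_real_,
    truth_alpha_db = sensors$truth$alpha_change_db %||% NA_real_,
    truth_coupling_m = sensors$truth$coupling_m %||% NA_real_,
    stringsAsFactors = FALSE)
  list(metrics = metrics, comodulogram = comod, roi_index = roi,
       gamma_map = gmap, ve = ve)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end replication experiment
#'
#' Simulates the cohort, projects each subject's source series to the toy
#' sensor array, analyses every subject with [analyze_subject()], and
#' performs the group comparisons: independent t-tests (with Cohen's d)
#' for gamma/alpha power change, peak frequencies and baseline gamma
#' power, plus the cluster-based permutation test and per-bin effect sizes
#' on the corrected comodulograms.
#'
#' @param config A [replication_config()].
#' @param progress Print per-subject progress lines.
#' @return Object of class `meg_replication`: `metrics` (per-subject
#'   data.frame), `tests` (named list of `group_test`), `cluster`
#'   (`cluster_result`), `effect` (comodulogram effect sizes),
#'   `comodulograms`, `config`, `config_hash`, `log`.
#' @export
run_replication <- function(config = replication_config(), progress = FALSE) {
  stopifnot(inherits(config, "replication_config"))
  config$cohort$master_seed <- derive_seed(config$seed, 101L)
  t_start <- Sys.time()
  cohort <- simulate_cohort(config$cohort)
  metrics <- list(); comods <- list()
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    sensors <- project_to_sensors(sub, config$model, config$source_index,
                                  config$sensor_noise_amp,
                                  seed = derive_seed(config$seed, 500L + i))
    res <- analyze_subject(sensors, config)
    metrics[[i]] <- res$metrics
    comods[[i]] <- res$comodulogram
    if (progress)
      message(sprintf("[%2d/%d] %s: gamma %+0.2f dB (truth %+0.2f), ROI %d",
                      i, length(cohort), sub$subject,
                      res$metrics$gamma_db, res$metrics$truth_gamma_db,
                      res$roi_index))
  }
  metrics <- do.call(rbind, metrics)
  ga <- metrics$group == config$cohort$group_a$label
  a_idx <- which(ga); b_idx <- which(!ga)
  tests <- list(
    gamma_power = independent_t(metrics$gamma_db[a_idx], metrics$gamma_db[b_idx]),
    gamma_peak = independent_t(metrics$gamma_peak_hz[a_idx],
                               metrics$gamma_peak_hz[b_idx]),
    alpha_power = independent_t(metrics$alpha_db[a_idx], metrics$alpha_db[b_idx]),
    alpha_peak = independent_t(metrics$alpha_peak_hz[a_idx],
                               metrics$alpha_peak_hz[b_idx]),
    gamma_baseline = independent_t(metrics$gamma_baseline_power[a_idx],
                                   metrics$gamma_baseline_power[b_idx]))
  cluster <- cluster_permutation(comods[a_idx], comods[b_idx],
                                 n_perm = config$n_perm,
                                 seed = derive_seed(config$seed, 900L),
                                 connectivity = config$connectivity,
                                 cluster_stat = config$cluster_stat)
  effect <- comodulogram_effect_size(comods[a_idx], comods[b_idx])
  structure(list(metrics = metrics, tests = tests, cluster = cluster,
                 effect = effect, comodulograms = comods,
                 group_a = config$cohort$group_a$label,
                 group_b = config$cohort$group_b$label,
                 config = config, config_hash = config_hash(config),
                 log = list(seed = config$seed,
                            started = format(t_start),
                            elapsed_s = as.numeric(difftime(Sys.time(),
                                                            t_start, units = "secs")),
                            n_subjects = nrow(metrics))),
            class = "meg_replication")
}

#' @export
print.meg_replication <- function(x, ...) {
  cat(sprintf("<meg_replication> %d + %d subjects (%s vs %s), seed %d, config %s\n",
              sum(x$metrics$group == x$group_a),
              sum(x$metrics$group == x$group_b),
              x$group_a, x$group_b, x$log$seed, x$config_hash))
  for (nm in names(x$tests)) {
    cat(sprintf("  %-15s", nm)); print(x$tests[[nm]])
  }
  sig <- vapply(x$cluster$clusters, `[[`, TRUE, "significant")
  cat(sprintf("  PAC clusters: %d found, %d significant (per-tail alpha %.3f); max |d| = %.2f\n",
              length(sig), sum(sig), x$cluster$decision_alpha,
              abs(x$effect$max_d)))
  invisible(x)
}

#' @export
summary.meg_replication <- function(object, ...) {
  m <- object$metrics
  agg <- stats::aggregate(m[c("gamma_db", "alpha_db", "gamma_peak_hz",
                              "alpha_peak_hz", "gamma_baseline_power")],
                          by = list(group = m$group), mean)
  structure(list(group_means = agg, tests = object$tests,
                 cluster = object$cluster, max_d = object$effect$max_d,
                 max_bin = object$effect$max_bin), class = "summary.meg_replication")
}

#' @export
print.summary.meg_replication <- function(x, ...) {
  cat("Group means:\n"); print(x$group_means, digits = 4)
  cat("\nGroup tests:\n")
  for (nm in names(x$tests)) { cat(sprintf("  %-15s", nm)); print(x$tests[[nm]]) }
  cat("\n"); print(x$cluster)
  cat(sprintf("Max comodulogram |d| = %.3f at phase %g Hz / amp %g Hz\n",
              abs(x$max_d), x$max_bin[1], x$max_bin[2]))
  invisible(x)
}

#' @export
plot.meg_replication <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
  ga <- x$metrics$group == x$group_a
  avg <- function(idx) Reduce(`+`, lapply(x$comodulograms[which(idx)],
                                          `[[`, "values")) / sum(idx)
  pf <- x$cluster$phase_freqs; af <- x$cluster$amp_freqs
  graphics::image(pf, af, avg(ga), xlab = "phase (Hz)", ylab = "amplitude (Hz)",
                  main = paste("mean PAC:", x$group_a))
  graphics::image(pf, af, avg(!ga), xlab = "phase (Hz)", ylab = "amplitude (Hz)",
                  main = paste("mean PAC:", x$group_b))
  graphics::image(pf, af, x$cluster$tmap, xlab = "phase (Hz)",
                  ylab = "amplitude (Hz)", main = "t map")
  invisible(x)
}

#' Write the replication results bundle
#'
#' Per-subject metrics as CSV, the group tests / cluster result / effect
#' sizes / run log as JSON (embedding the config hash and master seed).
#'
#' @param results A [run_replication()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_replication <- function(results, dir) {
  stopifnot(inherits(results, "meg_replication"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$metrics, file.path(dir, "subject_metrics.csv"),
                   row.names = FALSE)
  summ <- list(
    schema_version = "1.0",
    config_hash = results$config_hash,
    seed = results$log$seed,
    tests = lapply(results$tests, function(tt)
      tt[c("t", "df", "p", "d", "mean_a", "mean_b", "n1", "n2")]),
    clusters = lapply(results$cluster$clusters, function(cl)
      list(sign = cl$sign, cluster_stat = cl$cluster_stat,
           p_perm = cl$p_perm, significant = cl$significant,
           bins = apply(cl$bins, 1, as.numeric, simplify = FALSE))),
    n_permutations = results$cluster$n_permutations,
    max_effect_d = results$effect$max_d,
    max_effect_bin = as.list(results$effect$max_bin),
    log = results$log)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
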