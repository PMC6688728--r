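#' Eigen-MAR specifications for the three coupling states
#'
#' One spec per coupling level: all states share the resonance frequency,
#' pole magnitude, node-1 weight and phase lag; only the node-2 weight (the
#' coupling strength) differs.
#'
#' @param levels Coupling levels (node-2 weights), default low/medium/high
#'   `c(0.3, 0.6, 0.9)`.
#' @param frequency,magnitude,phase_lag,fs,noise_sd Shared eigen-parameters
#'   (see [eigen_mar_spec()]).
#' @return List of [eigen_mar_spec()] objects, one per level.
#' @export
mar_state_specs <- function(levels = c(0.3, 0.6, 0.9), frequency = 20,
                            magnitude = 0.9, phase_lag = pi / 4, fs = 250,
                            noise_sd = 1) {
  lapply(levels, function(w2) {
    eigen_mar_spec(frequency = frequency, magnitude = magnitude,
                   weight_node1 = 1, weight_node2 = w2,
                   phase_lag = phase_lag, fs = fs, noise_sd = noise_sd)
  })
}

#' Simulate one two-node run with ground truth
#'
#' Draws a state sequence for the regime (or a single constant state for the
#' static condition), simulates the two-node system (switching MAR or
#' Jansen-Rit with time-varying coupling), optionally degrades it to a
#' target SNR, and returns signals plus the ground-truth coupling
#' timecourse.
#'
#' @param model `"mar"` or `"nmm"`.
#' @param regime A [state_regime()], or `"static"` for constant coupling at
#'   the medium level.
#' @param duration Seconds of data (default 300).
#' @param fs Output sampling rate (default 250).
#' @param snr Amplitude SNR of added white noise (`Inf` = none).
#' @param levels Coupling levels for states low/medium/high.
#' @param static_level Index into `levels` for the static condition
#'   (default 2, medium).
#' @param nmm_params,k_scale Jansen-Rit parameters and coupling scale (NMM
#'   only).
#' @return List with `signals` (`n x 2`, attr `fs`), `truth`
#'   (`ground_truth`), `seq` (`state_sequence`), `band` (the model's
#'   analysis band) and `fs`.
#' @export
simulate_pair <- function(model = c("mar", "nmm"), regime,
                          duration = 300, fs = 250, snr = Inf,
                          levels = c(0.3, 0.6, 0.9), static_level = 2L,
                          nmm_params = jansen_rit_params(), k_scale = 40) {
  model <- match.arg(model)
  if (identical(regime, "static")) {
    seq <- build_state_sequence(duration, n_states = length(levels), fs = fs,
                                labels = static_level - 1L)
  } else {
    lt <- sample_lifetimes(regime, duration)
    seq <- build_state_sequence(lt, n_states = length(levels), fs = fs)
  }
  truth <- coupling_timecourse(seq, levels)
  if (model == "mar") {
    specs <- mar_state_specs(levels, fs = fs)
    signals <- simulate_switching_mar(specs, seq)
    band <- c(15, 25)
  } else {
    signals <- simulate_two_node_nmm(nmm_params, truth, k_scale = k_scale)
    band <- c(8, 13)
  }
  if (is.finite(snr)) signals <- add_noise(signals, snr)
  list(signals = signals, truth = truth, seq = seq, band = band, fs = fs)
}

#' Default log-spaced window-length grid
#'
#' @param n Number of window lengths (default 12 for scaled-down runs; the
#'   paper-scale grid uses 80).
#' @param range Length-2 numeric, seconds (default 0.25 to 30).
#' @return Numeric vector of widths in seconds.
#' @export
window_grid <- function(n = 12L, range = c(0.25, 30)) {
  exp(seq(log(range[1L]), log(range[2L]), length.out = n))
}

#' Correlation and error against ground truth across window lengths
#'
#' For each iteration a fresh two-node run is simulated; for each metric and
#' window length the sliding-window estimates are spline-interpolated to the
#' sample grid and scored against the ground-truth coupling timecourse.
#'
#' @param model `"mar"` or `"nmm"`.
#' @param regime A [state_regime()].
#' @param widths Window lengths in seconds.
#' @param metrics Metric names (default all five).
#' @param iterations Number of realizations (default 20).
#' @param snr Amplitude SNR (default `Inf`).
#' @param seed Base seed; iteration `i` uses `seed + i`.
#' @param duration Seconds per realization (default 300).
#' @return List of arrays `r` and `mae`, each
#'   `iterations x widths x metrics` (dimnames set), plus `widths`,
#'   `metrics`.
#' @export
experiment_truth_scores <- function(model, regime, widths,
                                    metrics = c("AEC", "COH", "iCO", "PLV",
                                                "PLI"),
                                    iterations = 20L, snr = Inf, seed = 1L,
                                    duration = 300) {
  dn <- list(iteration = NULL, width = sprintf("%.3g", widths),
             metric = metrics)
  r <- mae <- array(NA_real_, c(iterations, length(widths),
                                length(metrics)), dimnames = dn)
  for (it in seq_len(iterations)) {
    set.seed(seed + it)
    sim <- simulate_pair(model, regime, duration = duration, snr = snr)
    n <- nrow(sim$signals)
    xf <- bandpass(sim$signals, sim$band, sim$fs)
    for (w in seq_along(widths)) {
      sers <- sliding_metrics(xf, metrics, window_spec(widths[w], sim$fs),
                              sim$band, fs = sim$fs, prefiltered = TRUE)
      for (m in seq_along(metrics)) {
        series <- sers[[metrics[m]]]
        if (sum(is.finite(series$values)) < 4L) next
        est <- interpolate_estimates(series, n, sim$fs)
        sc <- score_against_truth(est, sim$truth)
        r[it, w, m] <- sc$r
        mae[it, w, m] <- sc$mae
      }
    }
  }
  list(r = r, mae = mae, widths = widths, metrics = metrics)
}

#' Static-versus-dynamic summary-statistic experiment
#'
#' Simulates matched static and dynamic runs, computes the four summary
#' statistics of each metric's window-value distribution per iteration, and
#' runs a Mann-Whitney test per metric, window length and statistic.
#'
#' @inheritParams experiment_truth_scores
#' @param alpha Flag level for the tests (default 0.01).
#' @return A data frame with one row per metric x width x statistic:
#'   medians of both conditions, `U`, `p` and `flag`.
#' @export
experiment_static_dynamic <- function(model, regime, widths,
                                      metrics = c("AEC", "COH", "iCO",
                                                  "PLV", "PLI"),
                                      iterations = 20L, snr = 1,
                                      seed = 1L, duration = 300,
                                      alpha = 0.01) {
  stat_names <- c("std", "skewness", "kurtosis", "excursion")
  res <- array(NA_real_,
               c(2L, iterations, length(widths), length(metrics),
                 length(stat_names)))
  for (cond in 1:2) { # 1 = dynamic, 2 = static
    for (it in seq_len(iterations)) {
      set.seed(seed + 1000L * cond + it)
      sim <- simulate_pair(model, if (cond == 1L) regime else "static",
                           duration = duration, snr = snr)
      xf <- bandpass(sim$signals, sim$band, sim$fs)
      for (w in seq_along(widths)) {
        sers <- sliding_metrics(xf, metrics, window_spec(widths[w], sim$fs),
                                sim$band, fs = sim$fs, prefiltered = TRUE)
        for (m in seq_along(metrics)) {
          series <- sers[[metrics[m]]]
          if (sum(is.finite(series$values)) < 4L) next
          res[cond, it, w, m, ] <-
            distribution_summaries(series$values[is.finite(series$values)])
        }
      }
    }
  }
  out <- expand.grid(metric = metrics, width = widths, stat = stat_names,
                     stringsAsFactors = FALSE)
  out$median_dynamic <- out$median_static <- out$U <- out$p <- NA_real_
  out$flag <- NA
  for (i in seq_len(nrow(out))) {
    m <- match(out$metric[i], metrics)
    w <- match(out$width[i], widths)
    s <- match(out$stat[i], stat_names)
    dyn <- res[1L, , w, m, s]
    sta <- res[2L, , w, m, s]
    if (sum(is.finite(dyn)) < 5L || sum(is.finite(sta)) < 5L) next
    tst <- static_vs_dynamic_test(dyn[is.finite(dyn)], sta[is.finite(sta)],
                                  alpha = alpha)
    out$median_dynamic[i] <- stats::median(dyn, na.rm = TRUE)
    out$median_static[i] <- stats::median(sta, na.rm = TRUE)
    out$U[i] <- tst$U
    out$p[i] <- tst$p
    out$flag[i] <- tst$flag && out$median_dynamic[i] > out$median_static[i]
  }
  out
}

#' SNR sweep of the correlation with ground truth
#'
#' For each SNR level, runs [experiment_truth_scores()] at the window length
#' matched to the regime's mean state duration and collects the correlation
#' values.
#'
#' @inheritParams experiment_truth_scores
#' @param snrs SNR levels (default `c(0.5, 1, 3, 5, 10)`).
#' @param width Window length in seconds; default the regime's mean state
#'   duration (the most favorable condition).
#' @return Array `iterations x snrs x metrics` of correlations, with
#'   attribute `snrs`.
#' @export
experiment_snr_sweep <- function(model, regime,
                                 snrs = c(0.5, 1, 3, 5, 10),
                                 metrics = c("AEC", "COH", "iCO", "PLV",
                                             "PLI"),
                                 iterations = 10L, seed = 1L,
                                 duration = 300, width = NULL) {
  if (is.null(width)) width <- regime$mean_duration
  out <- array(NA_real_, c(iterations, length(snrs), length(metrics)),
               dimnames = list(NULL, sprintf("%g", snrs), metrics))
  for (s in seq_along(snrs)) {
    sc <- experiment_truth_scores(model, regime, widths = width,
                                  metrics = metrics,
                                  iterations = iterations, snr = snrs[s],
                                  seed = seed, duration = duration)
    out[, s, ] <- sc$r[, 1L, ]
  }
  attr(out, "snrs") <- snrs
  out
}

#' Restrict templates to the union of their mask nodes
#'
#' Scaled-down network runs keep every node that belongs to at least one
#' resting-state network and drop the unconnected remainder; mask indices
#' are re-mapped to the reduced node set.
#'
#' @param templates An `rsn_templates`.
#' @return A reduced `rsn_templates`.
#' @export
subset_templates <- function(templates) {
  stopifnot(inherits(templates, "rsn_templates"))
  nodes <- sort(unique(unlist(templates$masks)))
  masks <- lapply(templates$masks, function(idx) match(idx, nodes))
  rsn_templates(templates$centroids[nodes, , drop = FALSE], masks)
}

#' Sliding connectivity for a network run with optional leakage handling
#'
#' Implements the study's pipeline ordering: the raw signals are band-pass
#' filtered once; if `mix = TRUE` they are first linearly mixed
#' (inverse-distance leakage model). For the leakage-sensitive metrics
#' (AEC, COH, PLV) `correct = TRUE` applies symmetric multivariate
#' orthogonalization to the filtered series before windowing; PLI and iCO
#' are always computed on uncorrected signals.
#'
#' @param signals `n x N` matrix (attr `fs`).
#' @param metric Metric name.
#' @param window A [window_spec()].
#' @param band Analysis band, Hz.
#' @param centroids Node centroids (mm), required when `mix = TRUE`.
#' @param mix Apply inverse-distance linear mixing first.
#' @param correct Apply symmetric orthogonalization (only honored for AEC,
#'   COH, PLV).
#' @return A `connectivity_tensor`.
#' @export
network_connectivity <- function(signals, metric, window, band,
                                 centroids = NULL, mix = FALSE,
                                 correct = FALSE) {
  fs <- attr(signals, "fs")
  X <- signals
  if (mix) {
    if (is.null(centroids)) stop("`centroids` required for mixing",
                                 call. = FALSE)
    X <- linear_mix(X, centroids)
  }
  Xf <- bandpass(X, band, fs)
  if (correct && metric %in% c("AEC", "COH", "PLV")) {
    Xf <- symmetric_orthogonalize(Xf)
  }
  attr(Xf, "fs") <- fs
  sliding_connectivity(Xf, metric, window, band, fs = fs,
                       prefiltered = TRUE)
}

#' Network experiment: within- vs. outside-RSN connectivity
#'
#' Simulates a delayed Jansen-Rit network whose structural connectivity
#' tensor activates one resting-state network at a time, estimates
#' sliding-window connectivity tensors for the requested metrics and window
#' lengths (optionally under linear mixing with or without symmetric
#' leakage correction), and pools the per-window within/outside means over
#' iterations into one Mann-Whitney contrast per metric x width.
#'
#' @param templates An `rsn_templates` (use [subset_templates()] for
#'   scaled-down runs).
#' @param regime A [state_regime()].
#' @param widths Window lengths in seconds.
#' @param metrics Metric names.
#' @param iterations Number of seeded realizations.
#' @param duration Seconds per realization.
#' @param snr Amplitude SNR of sensor noise added to the node signals.
#' @param k Global coupling of the network simulation.
#' @param mix,correct Leakage options passed to [network_connectivity()].
#' @param seed Base seed.
#' @param params Jansen-Rit parameters.
#' @param alpha Flag level.
#' @return Data frame: one row per metric x width with pooled medians,
#'   `U`, `p`, `flag`.
#' @export
experiment_network <- function(templates, regime, widths,
                               metrics = c("AEC", "COH", "iCO", "PLV",
                                           "PLI"),
                               iterations = 5L, duration = 60, snr = 3,
                               k = 6, mix = FALSE, correct = FALSE,
                               seed = 1L, params = jansen_rit_params(),
                               alpha = 0.01) {
  band <- c(8, 13)
  fs <- 250
  out <- expand.grid(metric = metrics, width = widths,
                     stringsAsFactors = FALSE)
  pooled <- vector("list", nrow(out))
  for (it in seq_len(iterations)) {
    set.seed(seed + it)
    lt <- sample_lifetimes(regime, duration)
    seq <- build_state_sequence(lt, n_states = length(templates$masks),
                                fs = fs)
    st <- build_structural_tensor(templates, seq)
    delays <- build_delays(templates$centroids)
    cfg <- nmm_network_config(st, delays = delays, k = k, fs_out = fs)
    signals <- simulate_network(params, cfg)
    if (is.finite(snr)) signals <- add_noise(signals, snr)
    attr(signals, "fs") <- fs
    # share the filtered (and corrected) series across metrics per pipeline
    X <- if (mix) linear_mix(signals, templates$centroids) else signals
    Xf <- bandpass(X, band, fs)
    attr(Xf, "fs") <- fs
    corrected <- correct & metrics %in% c("AEC", "COH", "PLV")
    Xc <- if (any(corrected)) {
      tmp <- symmetric_orthogonalize(Xf)
      attr(tmp, "fs") <- fs
      tmp
    } else NULL
    for (w in unique(out$width)) {
      win <- window_spec(w, fs)
      for (grp in unique(corrected)) {
        ms <- metrics[corrected == grp]
        tensors <- sliding_metrics(if (grp) Xc else Xf, ms, win, band,
                                   fs = fs, prefiltered = TRUE)
        for (m in ms) {
          i <- which(out$metric == m & out$width == w)
          ctr <- within_outside_contrast(tensors[[m]], templates, seq,
                                         alpha = alpha)
          pooled[[i]] <- rbind(pooled[[i]], ctr$windows)
        }
      }
    }
  }
  out$median_within <- out$median_outside <- out$U <- out$p <- NA_real_
  out$flag <- NA
  for (i in seq_len(nrow(out))) {
    wdf <- pooled[[i]]
    ok <- is.finite(wdf$mean_within) & is.finite(wdf$mean_outside)
    wt <- suppressWarnings(
      stats::wilcox.test(wdf$mean_within[ok], wdf$mean_outside[ok],
                         exact = FALSE))
    out$median_within[i] <- stats::median(wdf$mean_within[ok])
    out$median_outside[i] <- stats::median(wdf$mean_outside[ok])
    out$U[i] <- unname(wt$statistic)
    out$p[i] <- wt$p.value
    out$flag[i] <- wt$p.value < alpha &&
      out$median_within[i] > out$median_outside[i]
  }
  out
}
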