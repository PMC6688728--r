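#' Add white noise at a prescribed signal-to-noise ratio
#'
#' SNR is defined as the amplitude ratio: per channel, white Gaussian noise
#' with standard deviation `channel sd / snr` is added, so the output
#' variance is `signal variance * (1 + 1/snr^2)`. `snr = Inf` returns the
#' input unchanged. Set `power = TRUE` to interpret `snr` as a power ratio
#' (noise sd = signal sd / sqrt(snr)).
#'
#' @param X Numeric vector or `n x N` matrix.
#' @param snr Signal-to-noise ratio (> 0); presets in the study are 1, 3, 5.
#' @param power Interpret `snr` as a power ratio instead of amplitude.
#' @return Noisy data shaped like `X` (attributes preserved).
#' @export
add_noise <- function(X, snr, power = FALSE) {
  if (!is.numeric(snr) || snr <= 0) {
    stop("`snr` must be positive", call. = FALSE)
  }
  if (is.infinite(snr)) return(X)
  amp_snr <- if (power) sqrt(snr) else snr
  vec <- !is.matrix(X)
  Xm <- as.matrix(X)
  sds <- apply(Xm, 2L, stats::sd)
  noise <- matrix(stats::rnorm(length(Xm)), nrow(Xm), ncol(Xm))
  noise <- sweep(noise, 2L, sds / amp_snr, `*`)
  out <- Xm + noise
  if (vec) out <- drop(out)
  attributes(out)[c("fs")] <- attributes(X)[c("fs")]
  if (!vec) dim(out) <- dim(Xm)
  out
}

#' Excursions from the median
#'
#' Non-stationarity statistic for a connectivity series: with `m` the series
#' median, maximal runs of consecutive samples strictly on one side of `m`
#' are identified, and the statistic is the sum over runs of
#' `(run length in samples) * (max |value - m| within the run)`. It is zero
#' iff the series never leaves its median; longer and larger excursions give
#' greater evidence for genuine fluctuations.
#'
#' @param series Numeric vector (length >= 3).
#' @param length_exponent,height_exponent Optional exponents applied to the
#'   run length and run height before the product (both default 1).
#' @return Non-negative scalar.
#' @examples
#' excursion_statistic(c(0, 0, 1, 1, 0, 0)) # one run of 2 at height 1 -> 2
#' @export
excursion_statistic <- function(series, length_exponent = 1,
                                height_exponent = 1) {
  if (length(series) < 3L) stop("series too short", call. = FALSE)
  m <- stats::median(series)
  side <- sign(series - m)
  r <- rle(side)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  total <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) next
    h <- max(abs(series[starts[k]:ends[k]] - m))
    total <- total + r$lengths[k]^length_exponent * h^height_exponent
  }
  total
}

#' Distribution summary statistics of a connectivity series
#'
#' Standard deviation (n - 1 denominator), sample skewness and kurtosis
#' (standardized third and fourth moments; a Gaussian has kurtosis 3), and
#' the excursion-from-the-median statistic.
#'
#' @param series Numeric vector (>= 4 values) or a `connectivity_series`.
#' @return Named numeric vector `c(std, skewness, kurtosis, excursion)`.
#' @export
distribution_summaries <- function(series) {
  if (inherits(series, "connectivity_series")) series <- series$values
  series <- series[is.finite(series)]
  if (length(series) < 4L) {
    stop("need at least 4 windows for summary statistics", call. = FALSE)
  }
  m <- mean(series)
  s <- sqrt(mean((series - m)^2))
  z <- if (s > 0) (series - m) / s else series * 0
  c(std = stats::sd(series),
    skewness = mean(z^3),
    kurtosis = mean(z^4),
    excursion = excursion_statistic(series))
}

#' Mann-Whitney test of a dynamic vs. static summary statistic
#'
#' Two-sided rank-sum test between the per-iteration summary statistics of
#' the dynamic and static conditions at one window length; the null (all
#' observed variability is a static system plus noise) is rejected at
#' `alpha = 0.01`, independently per window length.
#'
#' @param stats_dynamic,stats_static Numeric vectors of per-iteration values
#'   (>= 5 each).
#' @param alpha Rejection level (default 0.01).
#' @return List with `U` (rank-sum statistic for the dynamic sample), `p`,
#'   and `flag` (`p < alpha`).
#' @export
static_vs_dynamic_test <- function(stats_dynamic, stats_static,
                                   alpha = 0.01) {
  if (length(stats_dynamic) < 5L || length(stats_static) < 5L) {
    stop("need at least 5 iterations per condition", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(stats_dynamic, stats_static, exact = FALSE,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, flag = wt$p.value < alpha)
}

#' Interpolate window estimates onto the sample grid
#'
#' Natural cubic spline through the `(window center, value)` knots evaluated
#' at every sample time; times outside the first/last window center are
#' clamped to the respective end value. Needed because the ground truth is
#' fully sampled while the sliding window yields one estimate per window.
#'
#' @param series A `connectivity_series` (>= 4 windows).
#' @param n_samples Number of output samples.
#' @param fs Output sampling rate, Hz (default: the series' `fs`).
#' @return Numeric vector of length `n_samples`.
#' @export
interpolate_estimates <- function(series, n_samples, fs = NULL) {
  stopifnot(inherits(series, "connectivity_series"))
  if (is.null(fs)) fs <- series$fs
  keep <- is.finite(series$values)
  x <- series$window_centers[keep]
  y <- series$values[keep]
  if (length(y) < 4L) {
    stop("need at least 4 windows for cubic spline interpolation",
         call. = FALSE)
  }
  t_out <- (seq_len(n_samples) - 0.5) / fs
  t_clamped <- pmin(pmax(t_out, x[1L]), x[length(x)])
  stats::spline(x, y, xout = t_clamped, method = "natural")$y
}

#' Error and correlation of an interpolated estimate against ground truth
#'
#' `mae` is the mean absolute difference between the per-sample estimate and
#' the ground-truth coupling timecourse; `r` is their Pearson correlation.
#' The truth is affinely rescaled to `[0, 1]` over the supplied coupling
#' levels (Pearson r is unaffected; mae is reported on that scale). A
#' constant truth (static condition) leaves `r` undefined (`NA`).
#'
#' @param interpolated Numeric per-sample estimate vector.
#' @param truth A `ground_truth` timecourse or numeric vector of equal
#'   length.
#' @param rescale_truth Rescale truth to `[0, 1]` before comparison
#'   (default TRUE).
#' @return List with `mae` and `r`.
#' @export
score_against_truth <- function(interpolated, truth, rescale_truth = TRUE) {
  tv <- if (inherits(truth, "ground_truth")) truth$values else truth
  if (length(interpolated) != length(tv)) {
    stop("estimate and truth must have equal length", call. = FALSE)
  }
  if (rescale_truth) {
    rng <- range(tv)
    if (diff(rng) > 0) tv <- (tv - rng[1L]) / diff(rng)
  }
  r <- if (stats::sd(tv) == 0 || stats::sd(interpolated) == 0) NA_real_ else
    stats::cor(interpolated, tv)
  list(mae = mean(abs(interpolated - tv)), r = r)
}

#' Friedman test of the window-length effect
#'
#' Non-parametric repeated-measures test of whether window length affects
#' the per-iteration correlations (or errors): rows are iterations, columns
#' window lengths. Uses the tie-corrected Friedman rank statistic with
#' `df = (number of window lengths) - 1`.
#'
#' @param values Numeric matrix `iterations x window lengths` (no missing
#'   cells; >= 2 columns, >= 5 rows).
#' @return List with `chisq`, `df` and `p`.
#' @export
window_effect_test <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop("missing cells in the iterations x window-lengths table",
         call. = FALSE)
  }
  if (ncol(values) < 2L || nrow(values) < 5L) {
    stop("need >= 2 window lengths and >= 5 iterations", call. = FALSE)
  }
  if (all(apply(values, 1L, function(z) max(z) == min(z)))) {
    # every row fully tied: no evidence of a window-length effect
    return(list(chisq = 0, df = ncol(values) - 1L, p = 1))
  }
  ft <- stats::friedman.test(values)
  list(chisq = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

#' Within- vs. outside-network connectivity contrast
#'
#' For each window, the active resting-state network is the majority ground
#' truth state within that window; the contrast compares the mean estimated
#' connectivity over edges inside the active mask's complete subgraph with
#' the mean over all other off-diagonal edges. Per tensor, a Mann-Whitney
#' test across windows compares the two per-window means; the flag requires
#' `p < alpha` with the within median exceeding the outside median.
#'
#' @param tensor A `connectivity_tensor`.
#' @param templates An `rsn_templates` (masks over the tensor's nodes).
#' @param truth A `state_sequence` time-aligned with the tensor (same `fs`
#'   as the signals the tensor came from).
#' @param alpha Flag level (default 0.01).
#' @return List with per-window data frame `windows`
#'   (`center_s, active, mean_within, mean_outside`), plus `U`, `p`, `flag`.
#' @export
within_outside_contrast <- function(tensor, templates, truth,
                                    alpha = 0.01) {
  stopifnot(inherits(tensor, "connectivity_tensor"),
            inherits(templates, "rsn_templates"),
            inherits(truth, "state_sequence"))
  N <- dim(tensor$values)[1L]
  W <- dim(tensor$values)[3L]
  fs <- tensor$fs
  half <- tensor$width / 2
  off_diag <- upper.tri(matrix(0, N, N))
  mean_within <- mean_outside <- numeric(W)
  active <- integer(W)
  for (k in seq_len(W)) {
    i0 <- max(1L, round((tensor$window_centers[k] - half) * fs) + 1L)
    i1 <- min(length(truth$labels),
              round((tensor$window_centers[k] + half) * fs))
    lab <- truth$labels[i0:i1]
    act <- as.integer(names(which.max(table(lab))))
    active[k] <- act
    mask <- templates$masks[[act + 1L]]
    if (length(mask) < 2L) stop("active mask too small", call. = FALSE)
    inside <- matrix(FALSE, N, N)
    inside[mask, mask] <- TRUE
    slice <- tensor$values[, , k]
    mean_within[k] <- mean(slice[inside & off_diag], na.rm = TRUE)
    mean_outside[k] <- mean(slice[!inside & off_diag], na.rm = TRUE)
  }
  ok <- is.finite(mean_within) & is.finite(mean_outside)
  wt <- suppressWarnings(
    stats::wilcox.test(mean_within[ok], mean_outside[ok], exact = FALSE))
  flag <- wt$p.value < alpha &&
    stats::median(mean_within[ok]) > stats::median(mean_outside[ok])
  list(windows = data.frame(center_s = tensor$window_centers,
                            active = active,
                            mean_within = mean_within,
                            mean_outside = mean_outside),
       U = unname(wt$statistic), p = wt$p.value, flag = flag)
}
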