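#' Sliding-window specification
#'
#' @param width Window width in seconds (> 0; at least 8 samples at `fs`).
#' @param fs Sampling rate in Hz.
#' @param overlap Fractional overlap between consecutive windows, in
#'   `[0, 1)`; the study convention is 0.5.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width, fs, overlap = 0.5) {
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  if (overlap < 0 || overlap >= 1) {
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  }
  if (round(width * fs) < 8) {
    stop("window must span at least 8 samples", call. = FALSE)
  }
  structure(list(width = width, fs = fs, overlap = overlap),
            class = "window_spec")
}

#' Sliding-window index ranges
#'
#' Half-open sample ranges `[start, start + w)` with stride
#' `w * (1 - overlap)` rounded to samples; the trailing partial window is
#' dropped, so the count is `floor((n - w) / stride) + 1`.
#'
#' @param n_samples Total series length in samples.
#' @param spec A [window_spec()].
#' @return Data frame with 1-based columns `start`, `end` (inclusive) and
#'   `center_s` (window center time in seconds).
#' @examples
#' nrow(window_slices(1000, window_spec(200 / 250, fs = 250))) # 9 windows
#' @export
window_slices <- function(n_samples, spec) {
  stopifnot(inherits(spec, "window_spec"))
  w <- round(spec$width * spec$fs)
  if (w > n_samples) {
    stop("window longer than the series", call. = FALSE)
  }
  stride <- max(1L, round(w * (1 - spec$overlap)))
  starts <- seq.int(0L, n_samples - w, by = stride)
  data.frame(start = starts + 1L, end = starts + w,
             center_s = (starts + w / 2) / spec$fs)
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forwards and backwards
#' (`filtfilt`), giving zero group delay and doubled stop-band attenuation.
#'
#' @param x Numeric vector or `n x N` matrix (channels in columns).
#' @param band Length-2 numeric band edges in Hz, inside `(0, fs/2)`.
#' @param fs Sampling rate in Hz.
#' @return Filtered data with the same shape as `x`.
#' @export
bandpass <- function(x, band, fs) {
  if (band[1L] <= 0 || band[2L] >= fs / 2 || band[1L] >= band[2L]) {
    stop("`band` must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    out <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
    dim(out) <- dim(x)
    out
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Analytic signal: amplitude envelope and instantaneous phase
#'
#' FFT-based discrete Hilbert transform: negative frequencies are zeroed and
#' positive frequencies doubled, so `envelope * exp(1i * phase)` reconstructs
#' the analytic signal exactly.
#'
#' @param x Numeric vector or `n x N` matrix of band-limited signals.
#' @return List with `envelope` (>= 0) and `phase` (in `(-pi, pi]`), each
#'   shaped like `x`.
#' @export
analytic_signal <- function(x) {
  one <- function(v) {
    n <- length(v)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[c(1L, n / 2 + 1L)] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[1L] <- 1
      h[2:((n + 1L) / 2)] <- 2
    }
    stats::fft(stats::fft(v) * h, inverse = TRUE) / n
  }
  if (is.matrix(x)) {
    a <- apply(x, 2L, one)
    dim(a) <- dim(x)
  } else {
    a <- one(x)
  }
  list(envelope = Mod(a), phase = Arg(a))
}

#' Amplitude envelope correlation for one window
#'
#' Pearson correlation between two amplitude envelopes. A zero-variance
#' envelope leaves the correlation undefined: the value is returned as `NA`
#' (flagged, not silently zero).
#'
#' @param env_x,env_y Equal-length numeric envelope vectors.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
aec <- function(env_x, env_y) {
  if (length(env_x) != length(env_y)) {
    stop("envelopes must have equal length", call. = FALSE)
  }
  if (stats::sd(env_x) == 0 || stats::sd(env_y) == 0) return(NA_real_)
  stats::cor(env_x, env_y)
}

#' Phase locking value for one window
#'
#' Modulus of the mean phasor of the instantaneous phase difference:
#' `|mean(exp(1i * (phase_x - phase_y)))|`.
#'
#' @param phase_x,phase_y Equal-length numeric phase vectors (radians).
#' @return Value in `[0, 1]`.
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("phases must have equal length", call. = FALSE)
  }
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Phase lag index for one window
#'
#' Modulus of the mean sign of the sine of the phase difference; quantifies
#' the asymmetry of the phase-difference distribution and is blind to
#' zero-lag coupling (`sign(0)` contributes 0).
#'
#' @param phase_x,phase_y Equal-length numeric phase vectors (radians).
#' @return Value in `[0, 1]`.
#' @export
pli <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("phases must have equal length", call. = FALSE)
  }
  abs(mean(sign(sin(phase_x - phase_y))))
}

# Internal: Welch segment plan inside one window of w samples.
# Segment width min(w/4, 1 s), floored at 8 samples and capped at 2w/3 so at
# least two 50%-overlapping segments always fit; segments are Hann-tapered
# and zero-padded to nfft for band resolution.
welch_plan <- function(w, fs, band) {
  seg <- min(floor(w / 4), round(fs))
  seg <- max(seg, 8L)
  seg <- min(seg, floor(2 * w / 3))
  if (seg < 4L) {
    stop("window too short for Welch segment averaging", call. = FALSE)
  }
  step <- max(1L, floor(seg / 2))
  starts <- seq.int(0L, w - seg, by = step)
  if (length(starts) < 2L) {
    stop("window too short for >= 2 Welch segments", call. = FALSE)
  }
  nfft <- max(256L, 2^ceiling(log2(seg)))
  freqs <- (0:(nfft / 2)) * fs / nfft
  bins <- which(freqs >= band[1L] & freqs <= band[2L])
  if (length(bins) == 0L) {
    stop("no spectral bins inside the analysis band", call. = FALSE)
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  # tapered DFT basis restricted to the band bins; identical to a
  # zero-padded length-nfft FFT evaluated at those bins
  E <- exp(-2i * pi * outer(0:(seg - 1L), bins - 1L) / nfft) * taper
  list(seg = seg, starts = starts, nfft = nfft, bins = bins, taper = taper,
       E = E)
}

# Internal: band coherency matrices for one multichannel window.
# Returns COH and iCO matrices (band-averaged |C| and |Im C|).
window_coherence <- function(X, fs, band, plan = NULL) {
  w <- nrow(X)
  N <- ncol(X)
  pl <- if (is.null(plan)) welch_plan(w, fs, band) else plan
  nb <- length(pl$bins)
  if (N == 2L) {
    s11 <- s22 <- numeric(nb)
    s12 <- complex(nb)
    for (s in pl$starts) {
      seg <- X[(s + 1L):(s + pl$seg), , drop = FALSE]
      seg <- sweep(seg, 2L, colMeans(seg))
      F <- crossprod(pl$E, seg)          # nb x 2 band-bin spectra
      s11 <- s11 + Mod(F[, 1L])^2
      s22 <- s22 + Mod(F[, 2L])^2
      s12 <- s12 + F[, 1L] * Conj(F[, 2L])
    }
    den <- sqrt(s11 * s22)
    C <- ifelse(den > 0, s12 / den, 0i)
    coh12 <- mean(Mod(C))
    ico12 <- mean(abs(Im(C)))
    coh <- matrix(c(1, coh12, coh12, 1), 2L, 2L)
    ico <- matrix(c(0, ico12, ico12, 0), 2L, 2L)
    return(list(coh = coh, ico = ico))
  }
  Sxy <- array(0i, c(N, N, nb))
  for (s in pl$starts) {
    seg <- X[(s + 1L):(s + pl$seg), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))
    F <- crossprod(pl$E, seg)
    for (b in seq_len(nb)) {
      Sxy[, , b] <- Sxy[, , b] + outer(F[b, ], Conj(F[b, ]))
    }
  }
  coh <- ico <- matrix(0, N, N)
  for (b in seq_len(nb)) {
    S <- Sxy[, , b]
    d <- sqrt(Re(diag(S)))
    den <- outer(d, d)
    C <- ifelse(den > 0, S / den, 0i)
    coh <- coh + Mod(C)
    ico <- ico + abs(Im(C))
  }
  list(coh = coh / nb, ico = ico / nb)
}

#' Band coherence and imaginary coherence for one window
#'
#' Coherency `C(f) = Sxy / sqrt(Sxx Syy)` from Hann-tapered,
#' 50%-overlapping Welch segments inside the window; `COH` is the band
#' average of `|C(f)|` and `iCO` the band average of `|Im C(f)|`, so
#' `iCO <= COH` always.
#'
#' @param x,y Equal-length band-passed signal vectors (one window).
#' @param band Length-2 numeric, Hz.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector `c(COH = ..., iCO = ...)`, both in `[0, 1]`.
#' @export
coherence_pair <- function(x, y, band, fs) {
  if (length(x) != length(y)) {
    stop("signals must have equal length", call. = FALSE)
  }
  wc <- window_coherence(cbind(x, y), fs, band)
  c(COH = wc$coh[1L, 2L], iCO = wc$ico[1L, 2L])
}

#' Sliding-window connectivity for a pair or a network
#'
#' The band-pass filter and the analytic transform are applied once to the
#' full-length series (avoiding per-window edge transients); each window's
#' metric is then computed from the windowed envelope/phase samples
#' (coherence from the window's own Welch segments). With two channels a
#' `connectivity_series` for the pair is returned; with more, a
#' `connectivity_tensor` over all unordered pairs.
#'
#' @param signals Numeric `n x N` matrix, channels in columns.
#' @param metric One of `"AEC"`, `"COH"`, `"iCO"`, `"PLV"`, `"PLI"`.
#' @param window A [window_spec()].
#' @param band Length-2 numeric band in Hz.
#' @param fs Sampling rate in Hz (default: the `fs` attribute of `signals`).
#' @param prefiltered Set `TRUE` if `signals` are already band-passed (e.g.
#'   after leakage correction of the filtered series).
#' @return A `connectivity_series` (N = 2) or `connectivity_tensor` (N > 2).
#' @export
sliding_connectivity <- function(signals, metric = c("AEC", "COH", "iCO",
                                                     "PLV", "PLI"),
                                 window, band, fs = NULL,
                                 prefiltered = FALSE) {
  metric <- match.arg(metric)
  sliding_metrics(signals, metric, window, band, fs = fs,
                  prefiltered = prefiltered)[[metric]]
}

#' Sliding-window connectivity for several metrics in one pass
#'
#' Shares the band-pass filter, the analytic transform and the window loop
#' across all requested metrics (COH and iCO come from a single
#' cross-spectral computation per window), which is substantially faster
#' than calling [sliding_connectivity()] per metric. Results are identical.
#'
#' @inheritParams sliding_connectivity
#' @param metrics Character vector of metric names.
#' @return Named list of `connectivity_series` / `connectivity_tensor`
#'   objects, one per requested metric.
#' @export
sliding_metrics <- function(signals, metrics, window, band, fs = NULL,
                            prefiltered = FALSE) {
  stopifnot(inherits(window, "window_spec"))
  bad <- setdiff(metrics, c("AEC", "COH", "iCO", "PLV", "PLI"))
  if (length(bad) > 0L) {
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  signals <- as.matrix(signals)
  if (is.null(fs)) fs <- attr(signals, "fs")
  if (is.null(fs)) stop("`fs` is required", call. = FALSE)
  N <- ncol(signals)
  xf <- if (prefiltered) signals else bandpass(signals, band, fs)
  sl <- window_slices(nrow(signals), window)
  W <- nrow(sl)
  needs_analytic <- any(metrics %in% c("AEC", "PLV", "PLI"))
  needs_coh <- any(metrics %in% c("COH", "iCO"))
  if (needs_analytic) an <- analytic_signal(xf)
  if (needs_coh) {
    plan <- welch_plan(sl$end[1L] - sl$start[1L] + 1L, fs, band)
  }
  vals <- lapply(metrics, function(m) array(NA_real_, c(N, N, W)))
  names(vals) <- metrics
  for (k in seq_len(W)) {
    idx <- sl$start[k]:sl$end[k]
    if (needs_coh) {
      wc <- window_coherence(xf[idx, , drop = FALSE], fs, band, plan)
    }
    if (any(metrics %in% c("PLV", "PLI"))) {
      Z <- exp(1i * an$phase[idx, , drop = FALSE])
    }
    for (m in metrics) {
      M <- switch(m,
        AEC = {
          E <- an$envelope[idx, , drop = FALSE]
          sds <- apply(E, 2L, stats::sd)
          Cm <- suppressWarnings(stats::cor(E))
          Cm[sds == 0, ] <- NA_real_
          Cm[, sds == 0] <- NA_real_
          Cm
        },
        PLV = Mod(crossprod(Conj(Z), Z)) / length(idx),
        PLI = {
          out <- matrix(0, N, N)
          for (j in seq_len(N)) {
            out[, j] <- abs(colMeans(sign(Im(Z * Conj(Z[, j])))))
          }
          out
        },
        COH = wc$coh,
        iCO = wc$ico
      )
      diag(M) <- 0
      vals[[m]][, , k] <- M
    }
  }
  out <- Map(function(v, m) {
    if (N == 2L) {
      structure(
        list(metric = m, values = v[1L, 2L, ], window_centers = sl$center_s,
             band = band, fs = fs, width = window$width),
        class = "connectivity_series"
      )
    } else {
      structure(
        list(metric = m, values = v, window_centers = sl$center_s,
             band = band, fs = fs, width = window$width),
        class = "connectivity_tensor"
      )
    }
  }, vals, names(vals))
  names(out) <- metrics
  out
}

#' @export
print.connectivity_series <- function(x, ...) {
  cat(sprintf(
    "<connectivity_series> %s, %d windows of %g s (band %g-%g Hz)\n",
    x$metric, length(x$values), x$width, x$band[1L], x$band[2L]))
  invisible(x)
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<connectivity_tensor> %s, %d x %d nodes x %d windows of %g s (band %g-%g Hz)\n",
    x$metric, d[1L], d[2L], d[3L], x$width, x$band[1L], x$band[2L]))
  invisible(x)
}

#' Export a pairwise connectivity series to CSV
#'
#' @param series A `connectivity_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_series <- function(series, path) {
  stopifnot(inherits(series, "connectivity_series"))
  utils::write.csv(
    data.frame(window_center_s = series$window_centers,
               value = series$values),
    path, row.names = FALSE)
  invisible(path)
}
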