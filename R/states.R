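#' Hidden-state regimes with Gamma-distributed lifetimes
#'
#' A state regime fixes the distribution of ground-truth state lifetimes.
#' Lifetimes are drawn from a Gamma distribution with the given `shape` and
#' scale `mean_duration / shape`, so the analytic mean lifetime equals
#' `mean_duration` for any shape. The three named regimes use the mean state
#' durations of the study conditions (fast 125 ms, medium 1 s, slow 3 s);
#' `mixed` draws each lifetime from one of the three with equal probability.
#'
#' @param name One of `"fast"`, `"medium"`, `"slow"`, `"mixed"`.
#' @param mean_duration Mean state lifetime in seconds. Defaults to the
#'   regime's standard value (0.125, 1, 3; ignored for `"mixed"`).
#' @param shape Gamma shape parameter (dimensionless, > 0). Default 2 gives
#'   unimodal, positively skewed lifetimes.
#' @return An object of class `state_regime`.
#' @examples
#' state_regime("fast")
#' state_regime("slow", shape = 3)
#' @export
state_regime <- function(name = c("fast", "medium", "slow", "mixed"),
                         mean_duration = NULL, shape = 2) {
  name <- match.arg(name)
  defaults <- c(fast = 0.125, medium = 1, slow = 3, mixed = NA_real_)
  if (is.null(mean_duration)) mean_duration <- unname(defaults[name])
  if (name != "mixed") {
    if (!is.numeric(mean_duration) || length(mean_duration) != 1L ||
        !is.finite(mean_duration) || mean_duration <= 0) {
      stop("`mean_duration` must be a positive scalar", call. = FALSE)
    }
  }
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0) {
    stop("`shape` must be a positive scalar", call. = FALSE)
  }
  structure(
    list(name = name, mean_duration = mean_duration, shape = shape,
         mixture_means = c(fast = 0.125, medium = 1, slow = 3)),
    class = "state_regime"
  )
}

#' @export
print.state_regime <- function(x, ...) {
  if (x$name == "mixed") {
    cat(sprintf("<state_regime> mixed (equal mixture of means %s s), shape %g\n",
                paste(x$mixture_means, collapse = "/"), x$shape))
  } else {
    cat(sprintf("<state_regime> %s: Gamma mean %g s, shape %g (scale %g s)\n",
                x$name, x$mean_duration, x$shape,
                x$mean_duration / x$shape))
  }
  invisible(x)
}

#' Sample state lifetimes from a regime
#'
#' Draws i.i.d. Gamma lifetimes (for `mixed`, each draw first picks one of the
#' fast/medium/slow component means with equal probability) until their
#' cumulative sum reaches `total_duration`; the final lifetime is truncated so
#' the cumulative sum equals `total_duration` exactly.
#'
#' @param regime A [state_regime()].
#' @param total_duration Total sequence duration in seconds (> 0).
#' @return Numeric vector of lifetimes in seconds summing to `total_duration`.
#' @examples
#' set.seed(1)
#' lt <- sample_lifetimes(state_regime("medium"), 60)
#' sum(lt)
#' @export
sample_lifetimes <- function(regime, total_duration) {
  stopifnot(inherits(regime, "state_regime"))
  if (!is.numeric(total_duration) || length(total_duration) != 1L ||
      !is.finite(total_duration) || total_duration <= 0) {
    stop("`total_duration` must be a positive scalar", call. = FALSE)
  }
  draw <- function(n) {
    if (regime$name == "mixed") {
      means <- sample(regime$mixture_means, n, replace = TRUE)
      stats::rgamma(n, shape = regime$shape, scale = means / regime$shape)
    } else {
      stats::rgamma(n, shape = regime$shape,
                    scale = regime$mean_duration / regime$shape)
    }
  }
  mean_lt <- if (regime$name == "mixed") mean(regime$mixture_means) else
    regime$mean_duration
  # draw in blocks until the budget is filled
  est <- max(16L, ceiling(total_duration / mean_lt * 1.5))
  lifetimes <- numeric(0)
  while (sum(lifetimes) < total_duration) {
    lifetimes <- c(lifetimes, draw(est))
    est <- max(16L, ceiling(est / 2))
  }
  cum <- cumsum(lifetimes)
  keep <- which(cum >= total_duration)[1L]
  lifetimes <- lifetimes[seq_len(keep)]
  lifetimes[keep] <- lifetimes[keep] - (cum[keep] - total_duration)
  lifetimes
}

#' Build a labelled state sequence from lifetimes
#'
#' Assigns each lifetime a state label drawn uniformly from the labels
#' excluding the previous segment's label (no self-transitions: every segment
#' boundary is a genuine state change), then expands to a per-sample label
#' vector at rate `fs`. Labels are integers `0 .. n_states - 1`.
#'
#' @param lifetimes Numeric vector of segment durations in seconds.
#' @param n_states Number of distinct states (>= 2).
#' @param fs Sampling rate in Hz.
#' @param labels Optional integer vector of per-segment labels (overrides the
#'   random assignment; used for deterministic constructions).
#' @return An object of class `state_sequence` with fields `fs`, `labels`
#'   (per-sample), `segment_labels`, `lifetimes`, `n_states`,
#'   `total_duration`.
#' @examples
#' seq <- build_state_sequence(c(1, 1), n_states = 2, fs = 100)
#' length(seq$labels)
#' @export
build_state_sequence <- function(lifetimes, n_states, fs, labels = NULL) {
  if (length(lifetimes) == 0L) {
    stop("`lifetimes` must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    stop("all lifetimes must be positive and finite", call. = FALSE)
  }
  if (n_states < 2L) stop("`n_states` must be >= 2", call. = FALSE)
  n_seg <- length(lifetimes)
  if (is.null(labels)) {
    labels <- integer(n_seg)
    labels[1L] <- sample.int(n_states, 1L) - 1L
    if (n_seg > 1L) {
      for (i in 2:n_seg) {
        choices <- setdiff(0:(n_states - 1L), labels[i - 1L])
        labels[i] <- if (length(choices) == 1L) choices else
          sample(choices, 1L)
      }
    }
  } else {
    if (length(labels) != n_seg) {
      stop("`labels` must match `lifetimes` in length", call. = FALSE)
    }
    if (any(labels < 0L | labels >= n_states)) {
      stop("labels out of range", call. = FALSE)
    }
  }
  # sample-quantized segment boundaries: segment i covers samples in
  # [round(cum[i-1]*fs), round(cum[i]*fs))
  bounds <- round(c(0, cumsum(lifetimes)) * fs)
  n_samples <- bounds[length(bounds)]
  counts <- diff(bounds)
  per_sample <- rep.int(as.integer(labels), counts)
  structure(
    list(fs = fs, labels = per_sample, segment_labels = as.integer(labels),
         lifetimes = as.numeric(lifetimes), n_states = as.integer(n_states),
         total_duration = sum(lifetimes), n_samples = as.integer(n_samples)),
    class = "state_sequence"
  )
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf(
    "<state_sequence> %d states, %d segments, %.3g s at %g Hz (%d samples)\n",
    x$n_states, length(x$segment_labels), x$total_duration, x$fs,
    length(x$labels)))
  invisible(x)
}

#' Run-length decode a state sequence back into lifetimes
#'
#' Inverse of the sample expansion in [build_state_sequence()], up to sample
#' quantization: consecutive runs of equal per-sample labels are converted
#' back to `(label, duration)` pairs.
#'
#' @param seq A `state_sequence`.
#' @return A data.frame with columns `label` and `duration_s`.
#' @export
decode_lifetimes <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  r <- rle(seq$labels)
  data.frame(label = r$values, duration_s = r$lengths / seq$fs)
}

#' Map state labels to a piecewise-constant coupling timecourse
#'
#' Produces the ground-truth coupling strength per sample (two-node case) or
#' an active-network index per sample (network case): the per-sample value is
#' `level_map[label]`, so the timecourse is piecewise constant with change
#' points at the state boundaries.
#'
#' @param seq A `state_sequence`.
#' @param level_map Named or positional numeric vector mapping label `k`
#'   (0-based) to a coupling value; must cover all labels present.
#' @return An object of class `ground_truth` with fields `fs` and `values`.
#' @examples
#' seq <- build_state_sequence(c(1, 1, 1), 3, fs = 50, labels = c(0, 2, 1))
#' tc <- coupling_timecourse(seq, c(0.3, 0.6, 0.9))
#' unique(tc$values)
#' @export
coupling_timecourse <- function(seq, level_map) {
  stopifnot(inherits(seq, "state_sequence"))
  present <- sort(unique(seq$labels))
  if (max(present) + 1L > length(level_map)) {
    stop("`level_map` does not cover all labels in the sequence",
         call. = FALSE)
  }
  structure(
    list(fs = seq$fs, values = as.numeric(level_map[seq$labels + 1L])),
    class = "ground_truth"
  )
}

#' Serialize a state sequence to CSV
#'
#' Writes one row per segment: `segment_index`, `label`, `duration_s`.
#'
#' @param seq A `state_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "state_sequence"))
  df <- data.frame(segment_index = seq_along(seq$segment_labels),
                   label = seq$segment_labels,
                   duration_s = seq$lifetimes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
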