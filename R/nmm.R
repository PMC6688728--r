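#' Jansen-Rit neural-mass parameters
#'
#' The canonical published parameter set for the Jansen-Rit model of a
#' cortical column: an excitatory and an inhibitory interneuron population
#' coupled to a pyramidal population whose membrane potential stands in for
#' the MEG/EEG signal. Rate constants `a = 1/tau_e` and `b = 1/tau_i` are in
#' 1/s; gains in mV; the sigmoid `S(v) = 2 e0 / (1 + exp(r (v0 - v)))` maps
#' membrane potential to firing rate and is bounded in `(0, 2 e0)`.
#'
#' The default drive (`drive_mean = 220` 1/s) puts the uncoupled unit well
#' inside the limit-cycle regime (past the Hopf bifurcation), so the node
#' oscillates in the alpha band; `drive_sd` sets the white-noise drive around
#' that mean.
#'
#' @param He,Hi Excitatory/inhibitory synaptic gain, mV.
#' @param a,b Inverse lumped time constants, 1/s.
#' @param C1,C2,C3,C4 Dimensionless intra-column connectivity constants.
#' @param e0 Half-maximum firing rate, 1/s.
#' @param v0 Sigmoid threshold, mV.
#' @param r Sigmoid steepness, 1/mV.
#' @param drive_mean,drive_sd Mean and sd of the noise drive, 1/s.
#' @return An object of class `jansen_rit_params`.
#' @examples
#' p <- jansen_rit_params()
#' jr_sigmoid(p$v0, p) # equals e0 at threshold
#' @export
jansen_rit_params <- function(He = 3.25, Hi = 22, a = 100, b = 50,
                              C1 = 135, C2 = 0.8 * 135, C3 = 0.25 * 135,
                              C4 = 0.25 * 135, e0 = 2.5, v0 = 6, r = 0.56,
                              drive_mean = 220, drive_sd = 8) {
  vals <- c(He = He, Hi = Hi, a = a, b = b, e0 = e0, r = r)
  if (any(vals <= 0)) {
    stop("gains, rate constants, e0 and r must be positive", call. = FALSE)
  }
  structure(
    list(He = He, Hi = Hi, a = a, b = b, C1 = C1, C2 = C2, C3 = C3, C4 = C4,
         e0 = e0, v0 = v0, r = r, drive_mean = drive_mean,
         drive_sd = drive_sd),
    class = "jansen_rit_params"
  )
}

#' @export
print.jansen_rit_params <- function(x, ...) {
  cat(sprintf(
    "<jansen_rit_params> He %g, Hi %g mV; a %g, b %g 1/s; drive %g +/- %g 1/s\n",
    x$He, x$Hi, x$a, x$b, x$drive_mean, x$drive_sd))
  invisible(x)
}

#' Jansen-Rit sigmoid (membrane potential to firing rate)
#'
#' @param v Membrane potential, mV.
#' @param params A [jansen_rit_params()].
#' @return Firing rate in 1/s, bounded in `(0, 2 e0)`.
#' @export
jr_sigmoid <- function(v, params) {
  2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
}

#' Deterministic Jansen-Rit drift
#'
#' Right-hand side of the six-dimensional Jansen-Rit ODE for one node. The
#' state is `(y0, y1, y2, y3, y4, y5)`: the three post-synaptic potentials
#' and their derivatives; the node's output signal is `y1 - y2`. `input` is
#' the total excitatory input in 1/s (mean drive plus any coupling term);
#' noise is not part of the drift.
#'
#' @param state Numeric length-6 state vector.
#' @param params A [jansen_rit_params()].
#' @param input Excitatory input in 1/s.
#' @return Length-6 derivative vector.
#' @export
jansen_rit_drift <- function(state, params, input = params$drive_mean) {
  if (length(state) != 6L || any(!is.finite(state))) {
    stop("state must be a finite length-6 vector", call. = FALSE)
  }
  p <- params
  y <- state
  c(y[4], y[5], y[6],
    p$He * p$a * jr_sigmoid(y[2] - y[3], p) - 2 * p$a * y[4] - p$a^2 * y[1],
    p$He * p$a * (input + p$C2 * jr_sigmoid(p$C1 * y[1], p)) -
      2 * p$a * y[5] - p$a^2 * y[2],
    p$Hi * p$b * p$C4 * jr_sigmoid(p$C3 * y[1], p) -
      2 * p$b * y[6] - p$b^2 * y[3])
}

#' One stochastic Heun step
#'
#' Predictor-corrector (Heun) update for an SDE with additive noise in one
#' state component: the same Wiener increment is applied in the predictor
#' and the corrector, so with `g = 0` the step reduces to the deterministic
#' second-order Heun scheme.
#'
#' @param state Numeric state vector.
#' @param dt Time step, s (> 0).
#' @param drift Function `state -> derivative`.
#' @param g Noise amplitude multiplying the Wiener increment.
#' @param dW Wiener increment for this step (typically `sqrt(dt) * rnorm(1)`).
#' @param noise_slot Index of the state component receiving the noise.
#' @return Updated state vector.
#' @export
heun_sde_step <- function(state, dt, drift, g = 0, dW = 0, noise_slot = 5L) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (g != 0 && noise_slot > length(state)) {
    stop("`noise_slot` out of range", call. = FALSE)
  }
  f1 <- drift(state)
  pred <- state + dt * f1
  if (g != 0) pred[noise_slot] <- pred[noise_slot] + g * dW
  f2 <- drift(pred)
  out <- state + dt * (f1 + f2) / 2
  if (g != 0) out[noise_slot] <- out[noise_slot] + g * dW
  if (any(!is.finite(out)) || max(abs(out)) > 1e8) {
    stop("integration diverged", call. = FALSE)
  }
  out
}

#' Algebraic fixed point of an uncoupled Jansen-Rit node
#'
#' Solves the equilibrium of the deterministic drift at constant input by
#' root-finding on the scalar pyramidal potential `v = y1 - y2`; derivative
#' states are zero at equilibrium. In the limit-cycle regime this fixed
#' point is unstable but still defines the resting value used to initialize
#' simulations and delay buffers.
#'
#' @param params A [jansen_rit_params()].
#' @param input Constant excitatory input in 1/s.
#' @return Length-6 state vector at equilibrium.
#' @export
jansen_rit_fixed_point <- function(params, input = params$drive_mean) {
  p <- params
  fv <- function(v) {
    y0 <- (p$He / p$a) * jr_sigmoid(v, p)
    y1 <- (p$He / p$a) * (input + p$C2 * jr_sigmoid(p$C1 * y0, p))
    y2 <- (p$Hi / p$b) * p$C4 * jr_sigmoid(p$C3 * y0, p)
    (y1 - y2) - v
  }
  v <- stats::uniroot(fv, c(-100, 100), extendInt = "yes",
                      tol = 1e-12)$root
  y0 <- (p$He / p$a) * jr_sigmoid(v, p)
  y1 <- (p$He / p$a) * (input + p$C2 * jr_sigmoid(p$C1 * y0, p))
  y2 <- (p$Hi / p$b) * p$C4 * jr_sigmoid(p$C3 * y0, p)
  c(y0, y1, y2, 0, 0, 0)
}

#' Conduction-delay matrix from node centroids
#'
#' `delay_ij = ||c_i - c_j|| / v` with centroid coordinates in mm and
#' conduction velocity `v` in m/s (units reconciled internally). The result
#' is symmetric with a zero diagonal.
#'
#' @param centroids Numeric matrix `N x 3`, coordinates in mm.
#' @param v Conduction velocity in m/s (default 10).
#' @return `N x N` delay matrix in seconds.
#' @examples
#' build_delays(rbind(c(0, 0, 0), c(100, 0, 0)), v = 10)[1, 2] # 10 ms
#' @export
build_delays <- function(centroids, v = 10) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3L) stop("centroids must be N x 3", call. = FALSE)
  if (!is.numeric(v) || v <= 0) {
    stop("conduction velocity must be positive", call. = FALSE)
  }
  d_mm <- as.matrix(stats::dist(centroids))
  (d_mm / 1000) / v
}

#' Time-varying structural connectivity from resting-state network states
#'
#' At every sample exactly one resting-state network (RSN) is active: all
#' node pairs inside the active mask are connected with unit weight and all
#' other pairs are disconnected (nodes outside the active network stay
#' active but unconnected). The tensor is stored run-length-compressed by
#' state segment; use [structural_slice()] for the per-sample `N x N` view.
#'
#' @param templates An `rsn_templates` object (see [load_rsn_templates()]).
#' @param seq A `state_sequence` whose labels index the four masks (0-3).
#' @return An object of class `structural_tensor`: per-segment matrices plus
#'   segment sample boundaries at `seq$fs`.
#' @export
build_structural_tensor <- function(templates, seq) {
  stopifnot(inherits(templates, "rsn_templates"),
            inherits(seq, "state_sequence"))
  n_masks <- length(templates$masks)
  if (any(seq$segment_labels < 0L | seq$segment_labels >= n_masks)) {
    stop("sequence labels out of range for the supplied masks",
         call. = FALSE)
  }
  N <- nrow(templates$centroids)
  mask_mats <- lapply(templates$masks, function(idx) {
    M <- matrix(0, N, N)
    M[idx, idx] <- 1
    diag(M) <- 0
    M
  })
  bounds <- round(c(0, cumsum(seq$lifetimes)) * seq$fs)
  structure(
    list(n_nodes = N, fs = seq$fs,
         segment_labels = seq$segment_labels,
         segment_matrices = mask_mats[seq$segment_labels + 1L],
         bounds = as.integer(bounds),
         n_samples = as.integer(bounds[length(bounds)])),
    class = "structural_tensor"
  )
}

#' @export
print.structural_tensor <- function(x, ...) {
  cat(sprintf(
    "<structural_tensor> %d nodes x %d samples at %g Hz (%d segments)\n",
    x$n_nodes, x$n_samples, x$fs, length(x$segment_labels)))
  invisible(x)
}

#' Per-sample slice of a structural tensor
#'
#' @param tensor A `structural_tensor`.
#' @param sample 1-based sample index.
#' @return The `N x N` structural matrix active at that sample.
#' @export
structural_slice <- function(tensor, sample) {
  stopifnot(inherits(tensor, "structural_tensor"))
  if (sample < 1L || sample > tensor$n_samples) {
    stop("sample index out of range", call. = FALSE)
  }
  seg <- findInterval(sample - 1L, tensor$bounds, rightmost.closed = FALSE)
  tensor$segment_matrices[[seg]]
}

#' Configuration for a delayed Jansen-Rit network simulation
#'
#' @param structural Either a constant `N x N` weight matrix or a
#'   `structural_tensor` from [build_structural_tensor()]. Weights must be
#'   non-negative with a zero diagonal.
#' @param delays `N x N` symmetric matrix of conduction delays in seconds
#'   (default: no delays).
#' @param k Global coupling scalar multiplying the structural weights.
#' @param duration Simulated duration in seconds (after burn-in). Required
#'   for constant `structural`; defaults to the tensor's duration otherwise.
#' @param dt Integration step in seconds (default 1e-4).
#' @param fs_out Output sampling rate in Hz after decimation (default 250).
#' @param burn Burn-in in seconds discarded before output; default
#'   `max(1, max delay)`.
#' @return An object of class `nmm_network_config`.
#' @export
nmm_network_config <- function(structural, delays = NULL, k = 6,
                               duration = NULL, dt = 1e-4, fs_out = 250,
                               burn = NULL) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (inherits(structural, "structural_tensor")) {
    N <- structural$n_nodes
    if (is.null(duration)) duration <- structural$n_samples / structural$fs
  } else {
    structural <- as.matrix(structural)
    N <- nrow(structural)
    if (ncol(structural) != N) stop("structural must be square", call. = FALSE)
    if (any(structural < 0) || any(diag(structural) != 0)) {
      stop("structural weights must be >= 0 with a zero diagonal",
           call. = FALSE)
    }
    if (is.null(duration)) {
      stop("`duration` is required for a constant structural matrix",
           call. = FALSE)
    }
  }
  if (is.null(delays)) delays <- matrix(0, N, N)
  delays <- as.matrix(delays)
  if (nrow(delays) != N || ncol(delays) != N ||
      max(abs(delays - t(delays))) > 1e-12 || any(delays < 0)) {
    stop("`delays` must be a symmetric non-negative N x N matrix",
         call. = FALSE)
  }
  if (is.null(burn)) burn <- max(1, max(delays))
  structure(
    list(n_nodes = N, structural = structural, delays = delays, k = k,
         duration = duration, dt = dt, fs_out = fs_out, burn = burn),
    class = "nmm_network_config"
  )
}

# Internal: run the compiled integrator for a set of coupling segments.
# seg_mats: list of N x N coupling matrices (already scaled by k);
# seg_end_samples: segment ends in output samples (last = duration * fs_out).
run_nmm <- function(params, n_nodes, seg_mats, seg_end_samples, delays,
                    dt, fs_out, burn) {
  decim <- round(1 / (dt * fs_out))
  if (abs(decim - 1 / (dt * fs_out)) > 1e-9) {
    stop("1/(dt * fs_out) must be an integer decimation factor",
         call. = FALSE)
  }
  burn_steps <- round(burn * fs_out) * decim
  n_steps <- burn_steps + seg_end_samples[length(seg_end_samples)] * decim
  seg_ends <- as.integer(burn_steps + seg_end_samples * decim)
  coupling <- array(unlist(seg_mats), c(n_nodes, n_nodes, length(seg_mats)))
  delay_steps <- matrix(as.integer(round(delays / dt)), n_nodes, n_nodes)
  init <- jansen_rit_fixed_point(params)
  init_sig <- jr_sigmoid(init[2] - init[3], params)
  out <- nmm_simulate_cpp(n_nodes, as.integer(n_steps), dt, unclass(params),
                          coupling, seg_ends, delay_steps, init, init_sig,
                          as.integer(decim), as.integer(burn_steps))
  attr(out, "fs") <- fs_out
  out
}

#' Simulate two Jansen-Rit nodes with time-varying coupling
#'
#' The coupling parameter `k` is a time series rather than a constant: the
#' ground-truth coupling timecourse (piecewise-constant levels from the state
#' sequence) scaled by `k_scale` enters each node's excitatory drive as
#' `k(t) * S(output of the other node)`.
#'
#' @param params A [jansen_rit_params()].
#' @param truth A `ground_truth` coupling timecourse at the output rate
#'   (values conventionally in `[0, 0.9]`).
#' @param k_scale Scale factor from coupling level to the drive units of the
#'   model (1/s per unit firing rate).
#' @param dt Integration step, s.
#' @param burn Burn-in in seconds (discarded; default 1).
#' @return Matrix `n_samples x 2` of node outputs at `truth$fs`, with
#'   attribute `fs`.
#' @export
simulate_two_node_nmm <- function(params, truth, k_scale = 40, dt = 1e-4,
                                  burn = 1) {
  stopifnot(inherits(params, "jansen_rit_params"),
            inherits(truth, "ground_truth"))
  r <- rle(truth$values)
  seg_ends <- cumsum(r$lengths)
  seg_mats <- lapply(r$values, function(level) {
    k_scale * level * matrix(c(0, 1, 1, 0), 2, 2)
  })
  run_nmm(params, 2L, seg_mats, seg_ends, matrix(0, 2, 2), dt,
          truth$fs, burn)
}

#' Simulate a delayed Jansen-Rit network
#'
#' Node `i`'s coupling input at time `t` is
#' `k * sum_j W_ij(t) * S(output_j(t - delay_ij))`, with the structural
#' weights `W(t)` taken from a constant matrix or a time-varying structural
#' tensor and delayed firing rates served from a ring buffer initialized at
#' the uncoupled fixed point. The first `burn` seconds are discarded.
#'
#' @param params A [jansen_rit_params()].
#' @param config An [nmm_network_config()].
#' @return Matrix `n_samples x N` at `config$fs_out`, with attribute `fs`.
#' @export
simulate_network <- function(params, config) {
  stopifnot(inherits(params, "jansen_rit_params"),
            inherits(config, "nmm_network_config"))
  fs_out <- config$fs_out
  n_out <- round(config$duration * fs_out)
  if (inherits(config$structural, "structural_tensor")) {
    st <- config$structural
    if (st$fs != fs_out) {
      stop("structural tensor rate must equal `fs_out`", call. = FALSE)
    }
    seg_ends <- pmin(st$bounds[-1L], n_out)
    keep <- which(seg_ends > c(0, utils::head(seg_ends, -1L)))
    seg_mats <- lapply(st$segment_matrices[keep],
                       function(M) config$k * M)
    seg_ends <- seg_ends[keep]
    seg_ends[length(seg_ends)] <- n_out
  } else {
    seg_mats <- list(config$k * config$structural)
    seg_ends <- n_out
  }
  run_nmm(params, config$n_nodes, seg_mats, seg_ends, config$delays,
          config$dt, fs_out, config$burn)
}
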