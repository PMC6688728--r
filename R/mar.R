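#' Eigen-parameter specification of a two-node resonant MAR(2) process
#'
#' A single resonant mode of an order-2 multivariate autoregressive process
#' is specified through the eigenstructure of its companion matrix: a pole at
#' `magnitude * exp(+/- 2i * pi * frequency / fs)` whose eigenvector projects
#' into the two channels with moduli proportional to
#' `(weight_node1, weight_node2)` and relative phase `phase_lag`. The weight
#' into node 1 is held fixed while the weight into node 2 sets the strength
#' of the phase-locked coupling between the nodes.
#'
#' @param frequency Resonant frequency in Hz (must be below `fs / 2`).
#' @param magnitude Pole modulus in (0, 1); closer to 1 means a sharper
#'   resonance.
#' @param weight_node1 Mode weight in node 1 (held fixed across states).
#' @param weight_node2 Mode weight in node 2, in `[0, 0.9]`; 0 leaves the
#'   nodes uncoupled.
#' @param phase_lag Fixed inter-node phase offset in radians.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Innovation standard deviation per node.
#' @param inert_ratio Modulus of the remaining (inert) companion eigenvalue
#'   pair relative to `magnitude`, in `(0, 1)`. The inert pair sits at the
#'   same frequency but is private to node 2, giving that node a resonant
#'   floor of its own so that band coherence grows monotonically with
#'   `weight_node2` (and is exactly 0 at `weight_node2 = 0`).
#' @return An object of class `eigen_mar_spec`.
#' @examples
#' eigen_mar_spec(weight_node2 = 0.6)
#' @export
eigen_mar_spec <- function(frequency = 20, magnitude = 0.9,
                           weight_node1 = 1, weight_node2 = 0.6,
                           phase_lag = pi / 4, fs = 250, noise_sd = 1,
                           inert_ratio = 0.8) {
  if (magnitude <= 0 || magnitude >= 1) {
    stop("`magnitude` must lie in (0, 1) for stability", call. = FALSE)
  }
  if (frequency <= 0 || frequency >= fs / 2) {
    stop("`frequency` must lie in (0, fs/2)", call. = FALSE)
  }
  if (weight_node2 < 0 || weight_node2 > 0.9) {
    stop("`weight_node2` must lie in [0, 0.9]", call. = FALSE)
  }
  if (weight_node1 <= 0) {
    stop("`weight_node1` must be positive", call. = FALSE)
  }
  if (inert_ratio <= 0 || inert_ratio >= 1) {
    stop("`inert_ratio` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(frequency = frequency, magnitude = magnitude,
         weight_node1 = weight_node1, weight_node2 = weight_node2,
         phase_lag = phase_lag, fs = fs, order = 2L, noise_sd = noise_sd,
         inert_ratio = inert_ratio),
    class = "eigen_mar_spec"
  )
}

#' @export
print.eigen_mar_spec <- function(x, ...) {
  cat(sprintf(
    "<eigen_mar_spec> %g Hz pole |z| = %g at fs %g Hz; weights (%g, %g), phase lag %.3g rad\n",
    x$frequency, x$magnitude, x$weight_node1, x$weight_node2, x$phase_lag))
  invisible(x)
}

#' Transform eigen-parameters into MAR(2) coefficient matrices
#'
#' Builds the 4x4 companion matrix with the prescribed complex-conjugate
#' eigenvalue pair and mode shape and reads the lag-1 and lag-2 parameter
#' matrices off its top block. The companion matrix is assembled as
#' `V L V^-1` from eigenvectors in companion form `[lambda * u; u]`: the
#' resonant pair at `magnitude * exp(+/- i theta)` with mode shape
#' `u = (weight_node1, weight_node2 * exp(i * phase_lag))`, plus an inert
#' conjugate pair at the same frequency with modulus
#' `inert_ratio * magnitude` and mode shape `(0, 1)` (a private resonance of
#' node 2). Placing all eigenvectors in companion form makes the assembled
#' matrix an exact companion matrix, so the coefficient blocks can be read
#' off directly. For `weight_node2 = 0` the matrix is block diagonal: zero
#' cross-terms, and the parametric coherence between the nodes is
#' identically 0.
#'
#' @param spec An [eigen_mar_spec()].
#' @return An object of class `mar_coefficients`: list with `A` (list of two
#'   2x2 real matrices), `noise_sd`, `fs`, `order`.
#' @examples
#' coeffs <- eigen_to_mar(eigen_mar_spec())
#' Mod(eigen(companion_matrix(coeffs))$values)
#' @export
eigen_to_mar <- function(spec) {
  stopifnot(inherits(spec, "eigen_mar_spec"))
  theta <- 2 * pi * spec$frequency / spec$fs
  lambda <- spec$magnitude * exp(1i * theta)
  mu <- spec$inert_ratio * spec$magnitude * exp(1i * theta)
  u1 <- c(spec$weight_node1, spec$weight_node2 * exp(1i * spec$phase_lag))
  u2 <- c(0, 1)
  V <- cbind(c(lambda * u1, u1), c(Conj(lambda * u1), Conj(u1)),
             c(mu * u2, u2), c(Conj(mu * u2), Conj(u2)))
  L <- diag(c(lambda, Conj(lambda), mu, Conj(mu)))
  C <- V %*% L %*% solve(V)
  if (max(abs(Im(C))) > 1e-8) {
    stop("companion construction failed to produce a real matrix",
         call. = FALSE)
  }
  C <- Re(C)
  A1 <- C[1:2, 1:2]
  A2 <- C[1:2, 3:4]
  structure(
    list(A = list(A1, A2), noise_sd = rep(spec$noise_sd, 2L), fs = spec$fs,
         order = 2L),
    class = "mar_coefficients"
  )
}

#' Companion matrix of a MAR process
#'
#' Standard block form: the lag matrices across the top row, an identity
#' subdiagonal, zeros elsewhere. Its eigenvalues are the process poles; all
#' must lie inside the unit circle for stability.
#'
#' @param coeffs A `mar_coefficients` object.
#' @return A `(2p) x (2p)` matrix.
#' @export
companion_matrix <- function(coeffs) {
  stopifnot(inherits(coeffs, "mar_coefficients"))
  p <- coeffs$order
  d <- nrow(coeffs$A[[1L]])
  C <- matrix(0, d * p, d * p)
  for (tau in seq_len(p)) {
    C[1:d, ((tau - 1L) * d + 1L):(tau * d)] <- coeffs$A[[tau]]
  }
  if (p > 1L) {
    C[(d + 1L):(d * p), 1:(d * (p - 1L))] <- diag(d * (p - 1L))
  }
  C
}

#' Simulate a switching-state two-node MAR realization
#'
#' Filters white Gaussian noise through the state-dependent parameter
#' matrices: at sample `t`, `X_t = A1^(s_t) X_{t-1} + A2^(s_t) X_{t-2} + e_t`
#' where `s_t` is the per-sample state label. At a state boundary the new
#' matrices are applied instantly, using the running past samples as history
#' (no re-initialization), so no transients are inserted.
#'
#' @param specs_per_label List of [eigen_mar_spec()] objects, one per state
#'   label (label `k` uses `specs_per_label[[k + 1]]`). All specs must share
#'   `fs`; conventionally they differ only in `weight_node2`.
#' @param seq A `state_sequence` from [build_state_sequence()].
#' @return Numeric matrix of dimension `n_samples x 2`, with attribute `fs`.
#' @examples
#' seq <- build_state_sequence(c(1, 1), 2, fs = 250, labels = c(0, 1))
#' specs <- list(eigen_mar_spec(weight_node2 = 0.3),
#'               eigen_mar_spec(weight_node2 = 0.9))
#' x <- simulate_switching_mar(specs, seq)
#' dim(x)
#' @export
simulate_switching_mar <- function(specs_per_label, seq) {
  stopifnot(inherits(seq, "state_sequence"))
  n_lab <- max(seq$labels) + 1L
  if (length(specs_per_label) < n_lab) {
    stop("`specs_per_label` must cover all labels in `seq`", call. = FALSE)
  }
  fs_all <- vapply(specs_per_label, function(s) s$fs, numeric(1))
  if (length(unique(fs_all)) != 1L || fs_all[1L] != seq$fs) {
    stop("all specs and the state sequence must share one `fs`",
         call. = FALSE)
  }
  coeffs <- lapply(specs_per_label, eigen_to_mar)
  for (cf in coeffs) {
    if (max(Mod(eigen(companion_matrix(cf), only.values = TRUE)$values)) >=
        1) {
      stop("unstable MAR specification", call. = FALSE)
    }
  }
  n <- length(seq$labels)
  A1 <- vapply(coeffs, function(cf) cf$A[[1L]], matrix(0, 2, 2))
  A2 <- vapply(coeffs, function(cf) cf$A[[2L]], matrix(0, 2, 2))
  noise <- matrix(stats::rnorm(2L * n, sd = coeffs[[1L]]$noise_sd[1L]), n, 2L)
  x <- mar_filter_cpp(A1, A2, seq$labels, noise)
  if (any(!is.finite(x))) stop("MAR simulation diverged", call. = FALSE)
  attr(x, "fs") <- seq$fs
  x
}

#' Parametric cross-spectral matrix of a MAR process
#'
#' Evaluates `S(f) = H(f) Sigma H(f)^H` with transfer function
#' `H(f) = (I - sum_tau A_tau exp(-2i pi f tau / fs))^-1` and diagonal
#' innovation covariance. The result is Hermitian positive semi-definite at
#' every frequency with real non-negative diagonal.
#'
#' @param coeffs A `mar_coefficients` object.
#' @param freqs Numeric vector of frequencies in Hz.
#' @return Complex array `2 x 2 x length(freqs)`.
#' @export
parametric_cross_spectrum <- function(coeffs, freqs) {
  stopifnot(inherits(coeffs, "mar_coefficients"))
  if (max(Mod(eigen(companion_matrix(coeffs),
                    only.values = TRUE)$values)) >= 1) {
    stop("unstable MAR coefficients", call. = FALSE)
  }
  d <- nrow(coeffs$A[[1L]])
  Sigma <- diag(coeffs$noise_sd^2, d)
  out <- array(complex(real = 0), c(d, d, length(freqs)))
  for (k in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[k] / coeffs$fs)
    Af <- diag(d) + 0i
    for (tau in seq_len(coeffs$order)) {
      Af <- Af - coeffs$A[[tau]] * z^tau
    }
    H <- solve(Af)
    # one-sided density in per-Hz units
    out[, , k] <- (2 / coeffs$fs) * H %*% Sigma %*% Conj(t(H))
  }
  out
}

#' Band-averaged parametric coherence of a two-node MAR process
#'
#' Convenience wrapper: mean over the band of `|S12| / sqrt(S11 S22)`
#' computed from [parametric_cross_spectrum()].
#'
#' @param coeffs A `mar_coefficients` object.
#' @param band Length-2 numeric, Hz.
#' @param n_freq Number of evaluation frequencies across the band.
#' @return Scalar in `[0, 1]`.
#' @export
parametric_band_coherence <- function(coeffs, band = c(15, 25),
                                      n_freq = 64L) {
  freqs <- seq(band[1L], band[2L], length.out = n_freq)
  S <- parametric_cross_spectrum(coeffs, freqs)
  num <- Mod(S[1, 2, ])
  den <- sqrt(Re(S[1, 1, ]) * Re(S[2, 2, ]))
  co <- ifelse(den > 0, num / den, 0)
  mean(co)
}
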