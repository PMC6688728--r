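# Naive single-purpose reference implementations used as oracles.

naive_aec <- function(ex, ey) {
  n <- length(ex)
  mx <- sum(ex) / n; my <- sum(ey) / n
  sxy <- sxx <- syy <- 0
  for (t in seq_len(n)) {
    sxy <- sxy + (ex[t] - mx) * (ey[t] - my)
    sxx <- sxx + (ex[t] - mx)^2
    syy <- syy + (ey[t] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

naive_plv <- function(px, py) {
  s <- 0i
  for (t in seq_along(px)) s <- s + exp(1i * (px[t] - py[t]))
  Mod(s / length(px))
}

naive_pli <- function(px, py) {
  s <- 0
  for (t in seq_along(px)) s <- s + sign(sin(px[t] - py[t]))
  abs(s / length(px))
}

unwrap_phase <- function(p) {
  cumsum(c(p[1], Arg(exp(1i * diff(p)))))
}

# theoretical stationary autocovariance of a stable MAR(2) via the discrete
# Lyapunov equation on the companion form, solved by vectorization
mar_autocov <- function(coeffs, max_lag = 2L) {
  C <- companion_matrix(coeffs)
  d <- 2L
  Q <- matrix(0, 4, 4)
  Q[1:2, 1:2] <- diag(coeffs$noise_sd^2)
  P <- matrix(solve(diag(16) - kronecker(C, C), as.vector(Q)), 4, 4)
  lags <- list(P[1:2, 1:2])
  Pk <- P
  for (k in seq_len(max_lag)) {
    Pk <- C %*% Pk
    lags[[k + 1L]] <- Pk[1:2, 1:2]
  }
  lags
}

# exact Friedman statistic for a table with no ties within rows
friedman_by_hand <- function(values) {
  r <- t(apply(values, 1L, rank))
  n <- nrow(values); k <- ncol(values)
  12 * n / (k * (k + 1)) * sum((colMeans(r) - (k + 1) / 2)^2)
}

# planted four-block connectivity tensor: disjoint node sets active in
# disjoint window ranges, optional additive noise
planted_tensor <- function(n_per_block = 5L, w_per_block = 6L, noise = 0) {
  nb <- 4L
  N <- nb * n_per_block
  W <- nb * w_per_block
  tens <- array(0, c(N, N, W))
  masks <- split(seq_len(N), rep(seq_len(nb), each = n_per_block))
  for (b in seq_len(nb)) {
    wins <- ((b - 1L) * w_per_block + 1L):(b * w_per_block)
    for (w in wins) {
      M <- matrix(0, N, N)
      M[masks[[b]], masks[[b]]] <- 1
      diag(M) <- 0
      tens[, , w] <- M
    }
  }
  if (noise > 0) {
    eps <- array(abs(stats::rnorm(length(tens), sd = noise)), dim(tens))
    eps <- (eps + aperm(eps, c(2, 1, 3))) / 2
    for (w in seq_len(dim(tens)[3])) diag(eps[, , w]) <- 0
    tens <- tens + eps
  }
  list(tensor = tens, masks = masks)
}

tiny_templates <- function(n = 12L) {
  set.seed(42)
  cent <- matrix(stats::rnorm(n * 3, sd = 30), n, 3)
  rsn_templates(cent, list(DMN = 1:4, SMN = 5:7, FPN = 8:10,
                           VIS = 11:12)[1:4])
}
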