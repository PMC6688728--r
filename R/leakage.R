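#' Inverse-distance linear mixing matrix
#'
#' Models signal leakage between reconstructed sources as a zero-lag linear
#' combination: `x~_i = x_i + sum_{j != i} x_j / d_ij` with `d_ij` the
#' Euclidean distance between node centroids in mm. The mixing matrix is
#' `M = I + W` with `W_ij = 1 / d_ij` off the diagonal.
#'
#' @param centroids Numeric `N x 3` matrix of node coordinates in mm.
#' @return `N x N` symmetric mixing matrix.
#' @export
mixing_matrix <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2L) stop("need at least 2 nodes", call. = FALSE)
  d <- as.matrix(stats::dist(centroids))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident centroids: mixing weights undefined", call. = FALSE)
  }
  W <- 1 / d
  diag(W) <- 0
  diag(nrow(centroids)) + W
}

#' Apply zero-lag linear mixing to multichannel signals
#'
#' @param X Numeric `n x N` matrix, channels in columns.
#' @param centroids Numeric `N x 3` matrix of node coordinates in mm.
#' @return Mixed `n x N` matrix (attributes of `X` preserved).
#' @export
linear_mix <- function(X, centroids) {
  X <- as.matrix(X)
  M <- mixing_matrix(centroids)
  if (ncol(X) != nrow(M)) {
    stop("channel count must match centroid count", call. = FALSE)
  }
  out <- X %*% M   # M symmetric: (M x_t)' = x_t' M
  attr(out, "fs") <- attr(X, "fs")
  out
}

#' Symmetric multivariate leakage correction
#'
#' Removes all zero-lag correlations between channels at once by finding the
#' closest set of mutually orthogonal channels to the data in the Frobenius
#' sense: the demeaned data matrix is approximated by `O %*% D` with
#' orthonormal columns `O` and a per-channel positive scaling `D`, iterating
#' orthogonal-Procrustes updates (polar decomposition for `O`, column dot
#' products for `D`) until the relative change in the objective falls below
#' `tol`. No channel is privileged: permuting input channels permutes output
#' channels identically.
#'
#' @param X Numeric `n x N` matrix, `n >= N`, full column rank.
#' @param tol Relative convergence tolerance on the objective
#'   (default 1e-10).
#' @param max_iter Maximum number of iterations (default 500).
#' @return Corrected `n x N` matrix with mutually orthogonal (zero-lag
#'   uncorrelated) columns; attributes `iterations` and `converged` record
#'   the iteration count and convergence status, `fs` is preserved.
#' @export
symmetric_orthogonalize <- function(X, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X); N <- ncol(X)
  if (n < N) stop("need at least as many samples as channels", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  if (sv$d[N] < 1e-10 * sv$d[1L]) {
    stop("rank-deficient input: symmetric orthogonalization undefined",
         call. = FALSE)
  }
  polar <- function(A) {
    s <- svd(A)
    s$u %*% t(s$v)
  }
  O <- polar(Xc)
  d <- diag(crossprod(O, Xc))
  obj_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    O <- polar(sweep(Xc, 2L, d, `*`))
    d <- diag(crossprod(O, Xc))
    obj <- sum((Xc - sweep(O, 2L, d, `*`))^2)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * obj_old) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!converged) {
    warning(sprintf(
      "symmetric orthogonalization did not converge in %d iterations",
      max_iter))
  }
  out <- sweep(O, 2L, d, `*`)
  if (any(abs(d) < 1e-12)) {
    warning("a channel collapsed to zero during orthogonalization")
  }
  attr(out, "fs") <- attr(X, "fs")
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}
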