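#' Orthogonally constrained non-negative tensor factorization
#'
#' Decomposes a third-order connectivity tensor `T` (`N x N x W`) into `L`
#' components `a_l (x) b_l (x) c_l` (outer products), minimizing the
#' Frobenius reconstruction error under the model's constraint set: the
#' spatial basis sets `A = [a_1..a_L]` and `B = [b_1..b_L]` each have
#' orthonormal columns, and the temporal loadings `c_l` are non-negative.
#' Negative tensor entries (possible for signed AEC) are clipped to zero
#' with a logged count before fitting.
#'
#' Optimization is alternating constrained least squares: `A` and `B` are
#' updated by an orthogonal-Procrustes (polar) step, and `C` by non-negative
#' least squares, which under orthonormal `A`, `B` reduces to a clipped
#' projection. Each update solves its subproblem exactly, so the objective
#' is non-increasing. Several random restarts are run and the best fit kept.
#'
#' @param tensor A `connectivity_tensor` or numeric `N x N x W` array.
#' @param L Number of components (default 4, one per resting-state
#'   network).
#' @param max_iter Maximum alternating iterations per restart (default 500).
#' @param tol Relative fit-change convergence tolerance (default 1e-8).
#' @param n_starts Random restarts (default 5).
#' @return An object of class `tensor_factors`: `a`, `b` (`N x L`,
#'   orthonormal columns), `c` (`W x L`, non-negative), `L`, `fit` (relative
#'   reconstruction error in `[0, 1]`), `converged`, `n_clipped`,
#'   `objective_trace`. Components are ordered by decreasing temporal
#'   energy `||c_l||`.
#' @export
ntf_decompose <- function(tensor, L = 4L, max_iter = 500L, tol = 1e-8,
                          n_starts = 5L) {
  vals <- if (inherits(tensor, "connectivity_tensor")) tensor$values else
    tensor
  if (!(is.array(vals) && length(dim(vals)) == 3L)) {
    stop("tensor must be an N x N x W array", call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    vals[!is.finite(vals)] <- 0
  }
  n_clipped <- sum(vals < 0)
  if (n_clipped > 0) vals[vals < 0] <- 0
  d <- dim(vals)
  N <- d[1L]; W <- d[3L]
  if (L > min(N, W)) {
    stop("L exceeds min(node count, window count)", call. = FALSE)
  }
  nrmT <- sqrt(sum(vals^2))
  if (nrmT == 0) stop("tensor is identically zero", call. = FALSE)
  # mode unfoldings (column-major): T1 = N x (N*W), T2 = N x (N*W),
  # T3 = W x (N*N)
  T1 <- matrix(aperm(vals, c(1L, 2L, 3L)), N, N * W)
  T2 <- matrix(aperm(vals, c(2L, 1L, 3L)), N, N * W)
  T3 <- matrix(aperm(vals, c(3L, 1L, 2L)), W, N * N)
  khatri_rao <- function(X, Y) {
    # columns y_l (x) x_l ... returns (nrow(Y)*nrow(X)) x L
    sapply(seq_len(ncol(X)), function(l) kronecker(X[, l], Y[, l]))
  }
  polar <- function(M) {
    s <- svd(M)
    s$u %*% t(s$v)
  }
  rand_orth <- function(n, l) qr.Q(qr(matrix(stats::rnorm(n * l), n, l)))
  # sign rectification: flipping (a_l, b_l) jointly leaves the model
  # invariant, but the non-negative C update clips components whose spatial
  # map converged with a negative sign; flip b_l so the projection of the
  # data onto each map is non-negative in aggregate
  rectify <- function(A, B) {
    proj <- T3 %*% khatri_rao(B, A)
    flip <- colSums(pmax(-proj, 0)^2) > colSums(pmax(proj, 0)^2)
    B[, flip] <- -B[, flip, drop = FALSE]
    B
  }
  best <- NULL
  for (start in seq_len(n_starts)) {
    A <- rand_orth(N, L)
    B <- rectify(A, rand_orth(N, L))
    Cl <- pmax(T3 %*% khatri_rao(B, A), 0)   # W x L
    fit_old <- Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      A <- polar(T1 %*% khatri_rao(Cl, B))
      B <- rectify(A, polar(T2 %*% khatri_rao(Cl, A)))
      Cl <- pmax(T3 %*% khatri_rao(B, A), 0)
      recon_sq <- sum(vals^2) - 2 * sum(Cl * (T3 %*% khatri_rao(B, A))) +
        sum(crossprod(Cl) * (crossprod(A) * crossprod(B)))
      fit <- sqrt(max(recon_sq, 0)) / nrmT
      trace <- c(trace, fit)
      if (is.finite(fit_old) && abs(fit_old - fit) <= tol * max(fit_old,
                                                                1e-12)) {
        converged <- TRUE
        break
      }
      fit_old <- fit
    }
    if (is.null(best) || trace[length(trace)] < best$fit) {
      best <- list(A = A, B = B, C = Cl, fit = trace[length(trace)],
                   converged = converged, trace = trace)
    }
  }
  # order by temporal energy
  energy <- sqrt(colSums(best$C^2))
  ord <- order(energy, decreasing = TRUE)
  structure(
    list(a = best$A[, ord, drop = FALSE], b = best$B[, ord, drop = FALSE],
         c = best$C[, ord, drop = FALSE], L = as.integer(L),
         fit = best$fit, converged = best$converged,
         n_clipped = n_clipped, objective_trace = best$trace),
    class = "tensor_factors"
  )
}

#' @export
print.tensor_factors <- function(x, ...) {
  cat(sprintf(
    "<tensor_factors> L = %d, relative fit error %.4g (%sconverged, %d negative entries clipped)\n",
    x$L, x$fit, if (x$converged) "" else "NOT ", x$n_clipped))
  invisible(x)
}

#' Thresholded edge mask of one spatial component
#'
#' The component's connectivity map is the symmetrized outer product
#' `(a_l b_l' + b_l a_l') / 2` with a zeroed diagonal; the mask keeps the
#' top `top_fraction` of off-diagonal edges (by value), including all ties
#' at the threshold.
#'
#' @param factors A `tensor_factors` object.
#' @param l Component index.
#' @param top_fraction Fraction of edges to keep (default 0.03, the "upper
#'   3%" convention).
#' @return Logical `N x N` symmetric matrix (edge mask).
#' @export
component_edges <- function(factors, l, top_fraction = 0.03) {
  stopifnot(inherits(factors, "tensor_factors"))
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  }
  a <- factors$a[, l]
  b <- factors$b[, l]
  M <- (outer(a, b) + outer(b, a)) / 2
  diag(M) <- 0
  ut <- upper.tri(M)
  vals <- M[ut]
  k <- ceiling(top_fraction * length(vals))
  thr <- sort(vals, decreasing = TRUE)[k]
  mask <- M >= thr
  mask[!ut & !t(ut)] <- FALSE
  mask <- mask | t(mask)
  diag(mask) <- FALSE
  mask
}

#' Match factor components to resting-state network templates
#'
#' Similarity is the Jaccard index between each component's thresholded edge
#' mask and each template's complete-subgraph edge set; the assignment is a
#' maximum-total-similarity one-to-one matching (components may remain
#' unmatched if there are more components than templates).
#'
#' @param factors A `tensor_factors` object.
#' @param templates An `rsn_templates` over the same node set.
#' @param top_fraction Edge fraction passed to [component_edges()].
#' @return List with `similarity` (`L x templates` Jaccard matrix) and
#'   `assignment` (named integer vector: template index per component, `NA`
#'   if unmatched).
#' @export
match_components <- function(factors, templates, top_fraction = 0.03) {
  stopifnot(inherits(factors, "tensor_factors"),
            inherits(templates, "rsn_templates"))
  N <- nrow(factors$a)
  n_tpl <- length(templates$masks)
  tpl_edges <- lapply(templates$masks, function(idx) {
    M <- matrix(FALSE, N, N)
    M[idx, idx] <- TRUE
    diag(M) <- FALSE
    M
  })
  ut <- upper.tri(matrix(0, N, N))
  sim <- matrix(0, factors$L, n_tpl,
                dimnames = list(NULL, names(templates$masks)))
  for (l in seq_len(factors$L)) {
    cm <- component_edges(factors, l, top_fraction)
    for (t in seq_len(n_tpl)) {
      inter <- sum(cm[ut] & tpl_edges[[t]][ut])
      uni <- sum(cm[ut] | tpl_edges[[t]][ut])
      sim[l, t] <- if (uni > 0) inter / uni else 0
    }
  }
  # exhaustive one-to-one assignment (component count is small)
  k <- min(factors$L, n_tpl)
  perm_best <- NULL
  score_best <- -Inf
  combs <- utils::combn(seq_len(factors$L), k, simplify = FALSE)
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  tpl_perms <- perms_of(seq_len(n_tpl))
  for (cc in combs) {
    for (pp in tpl_perms) {
      pk <- pp[seq_len(k)]
      s <- sum(sim[cbind(cc, pk)])
      if (s > score_best) {
        score_best <- s
        perm_best <- list(comp = cc, tpl = pk)
      }
    }
  }
  assignment <- rep(NA_integer_, factors$L)
  assignment[perm_best$comp] <- perm_best$tpl
  names(assignment) <- paste0("component_", seq_len(factors$L))
  list(similarity = sim, assignment = assignment)
}
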