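test_that("added noise realizes the prescribed amplitude SNR", {
  set.seed(41)
  x <- matrix(rnorm(75000, sd = 2), ncol = 1)
  y <- add_noise(x, 1)
  expect_equal(sd(y - x), sd(x), tolerance = 0.02)
  y3 <- add_noise(x, 3)
  expect_equal(sd(y3 - x), sd(x) / 3, tolerance = 0.02)
  expect_identical(add_noise(x, Inf), x)
  # power-ratio interpretation
  yp <- add_noise(x, 4, power = TRUE)
  expect_equal(sd(yp - x), sd(x) / 2, tolerance = 0.03)
  expect_error(add_noise(x, 0), "positive")
  # same signal, different noise across seeds
  set.seed(1); a <- add_noise(x, 1)
  set.seed(2); b <- add_noise(x, 1)
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("excursion statistic matches hand-enumerated runs", {
  expect_equal(excursion_statistic(rep(0.4, 10)), 0)
  expect_equal(excursion_statistic(c(0, 0, 1, 1, 0, 0)), 2)
  # two runs: heights 2 and 1, lengths 1 and 2 about median 0
  x <- c(0, 2, 0, -1, -1, 0)
  expect_equal(excursion_statistic(x), 1 * 2 + 2 * 1)
  # run-structure sensitivity: at matched marginals, a state-like series
  # with long runs scores strictly higher than its random permutation
  set.seed(42)
  wins <- replicate(20, {
    sq <- rep(c(-1, 1), each = 25, times = 4) + rnorm(200, sd = 0.3)
    excursion_statistic(sq) > excursion_statistic(sample(sq))
  })
  expect_true(all(wins))
  # exponents reshape the statistic monotonically
  x5 <- c(0, 0, 1, 1, 0, 0)
  expect_equal(excursion_statistic(x5, length_exponent = 2), 4)
  expect_equal(excursion_statistic(2 * x5, height_exponent = 2), 8)
})

test_that("distribution summaries match known moments", {
  set.seed(43)
  g <- rnorm(1e5)
  s <- distribution_summaries(g)
  expect_equal(unname(s["skewness"]), 0, tolerance = 0.05)
  expect_equal(unname(s["kurtosis"]), 3, tolerance = 0.1)
  e <- rexp(2e5)
  expect_equal(unname(distribution_summaries(e)["skewness"]), 2,
               tolerance = 0.1)
  # affine invariance of shape statistics
  s2 <- distribution_summaries(5 - 3 * g)
  expect_equal(unname(s2["skewness"]), -unname(s["skewness"]),
               tolerance = 1e-10)
  expect_equal(unname(s2["kurtosis"]), unname(s["kurtosis"]),
               tolerance = 1e-10)
  expect_error(distribution_summaries(c(1, 2, 3)), "4 windows")
})

test_that("Mann-Whitney wrapper matches exact enumeration", {
  set.seed(44)
  a <- rnorm(20)
  b <- rnorm(20) + 10
  res <- static_vs_dynamic_test(b, a)
  expect_equal(res$U, 400)       # complete separation: U = n1 * n2
  expect_lt(res$p, 0.01)
  expect_true(res$flag)
  # identical samples: no evidence
  res0 <- static_vs_dynamic_test(a, a)
  expect_gt(res0$p, 0.9)
  expect_false(res0$flag)
  # rank invariance under monotone transforms
  res2 <- static_vs_dynamic_test(exp(b / 5), exp(a / 5))
  expect_equal(res2$U, res$U)
  # exact enumeration oracle on tiny samples
  x <- c(1.2, 3.4, 5.1); y <- c(0.3, 2.2, 2.9)
  U_exact <- sum(outer(x, y, ">"))
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  expect_equal(unname(wt$statistic), U_exact)
  expect_error(static_vs_dynamic_test(1:3, 1:5), "5 iterations")
})

test_that("spline interpolation passes through knots and clamps the ends", {
  t_out <- (seq_len(60) - 0.5) / 10
  centers <- t_out[c(10, 20, 30, 40, 50)]   # knots on the sample grid
  vals <- c(0.2, 0.5, 0.4, 0.9, 0.3)
  series <- structure(
    list(metric = "AEC", values = vals, window_centers = centers,
         band = c(8, 13), fs = 10, width = 1),
    class = "connectivity_series")
  est <- interpolate_estimates(series, 60, fs = 10)
  expect_equal(est[c(10, 20, 30, 40, 50)], vals, tolerance = 1e-12)
  expect_true(all(abs(est[t_out < centers[1]] - vals[1]) < 1e-12))
  expect_true(all(abs(est[t_out > centers[5]] - vals[5]) < 1e-12))
  # constants reproduce exactly
  series$values <- rep(0.7, 5)
  expect_equal(interpolate_estimates(series, 60, fs = 10), rep(0.7, 60))
  # a cubic polynomial is reproduced between interior knots
  xs <- seq(0.5, 6, by = 0.5)
  cubic <- function(x) 0.1 * x^3 - 0.4 * x^2 + x
  series3 <- structure(
    list(metric = "AEC", values = cubic(xs), window_centers = xs,
         band = c(8, 13), fs = 20, width = 1),
    class = "connectivity_series")
  est3 <- interpolate_estimates(series3, 120, fs = 20)
  t3 <- (seq_len(120) - 0.5) / 20
  interior <- t3 > 2 & t3 < 4.5
  expect_equal(est3[interior], cubic(t3[interior]), tolerance = 1e-2)
  series$values <- c(1, 2, 3)
  series$window_centers <- 1:3
  expect_error(interpolate_estimates(series, 10, fs = 10), "4 windows")
})

test_that("scoring against truth honors its closed forms", {
  tr <- structure(list(fs = 10, values = rep(c(0.3, 0.9), each = 50)),
                  class = "ground_truth")
  scaled <- rep(c(0, 1), each = 50)
  sc <- score_against_truth(scaled, tr)
  expect_equal(sc$mae, 0)
  expect_equal(sc$r, 1)
  sc2 <- score_against_truth(scaled + 0.25, tr)
  expect_equal(sc2$mae, 0.25)
  expect_equal(sc2$r, 1)
  # static truth: r undefined, flagged
  tr0 <- structure(list(fs = 10, values = rep(0.6, 100)),
                   class = "ground_truth")
  sc3 <- score_against_truth(scaled, tr0, rescale_truth = FALSE)
  expect_true(is.na(sc3$r))
  # independent estimate: null correlation
  set.seed(45)
  nulls <- replicate(20, {
    est <- rnorm(75000)
    truth <- rep(rep(c(0.3, 0.9), each = 250), 150)
    abs(score_against_truth(est, truth)$r)
  })
  expect_gte(mean(nulls < 0.01), 19 / 20)
  expect_error(score_against_truth(1:10, tr), "equal length")
})

test_that("Friedman window-length test matches the exact rank statistic", {
  # strictly ordered columns in every row: chi^2 = n * (k - 1) * ... = 20
  vals <- t(replicate(10, c(1, 2, 3) + runif(3, 0, 0.1)))
  res <- window_effect_test(vals)
  expect_equal(res$chisq, 20)
  expect_equal(res$df, 2)
  expect_lt(res$p, 0.001)
  expect_equal(res$chisq, friedman_by_hand(vals))
  # identical columns: no effect
  same <- matrix(rep(rnorm(10), 3), ncol = 3)
  res0 <- window_effect_test(same + 0)
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p, 1)
  # permutation invariance
  set.seed(46)
  r <- matrix(rnorm(50), 10, 5)
  expect_equal(window_effect_test(r)$chisq,
               window_effect_test(r[, c(3, 1, 5, 2, 4)])$chisq)
  expect_error(window_effect_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("within/outside contrast counts edges and flags correctly", {
  tpl <- tiny_templates()
  seq <- build_state_sequence(c(1, 1), 4, fs = 100, labels = c(0, 1))
  N <- 12
  W <- 8
  vals <- array(0, c(N, N, W))
  centers <- seq(0.25, 2, by = 0.25)
  active <- ifelse(centers <= 1, 1, 2)
  for (k in seq_len(W)) {
    M <- matrix(0, N, N)
    mask <- tpl$masks[[active[k]]]
    M[mask, mask] <- 1
    diag(M) <- 0
    vals[, , k] <- M
  }
  tens <- structure(
    list(metric = "AEC", values = vals, window_centers = centers,
         band = c(8, 13), fs = 100, width = 0.25),
    class = "connectivity_tensor")
  ctr <- within_outside_contrast(tens, tpl, seq)
  expect_true(all(ctr$windows$mean_within == 1))
  expect_true(all(ctr$windows$mean_outside == 0))
  expect_true(ctr$flag)
  expect_equal(ctr$windows$active, active - 1)
  # i.i.d. tensor: no contrast
  set.seed(47)
  flags <- replicate(10, {
    v <- array(runif(N * N * W), c(N, N, W))
    v <- (v + aperm(v, c(2, 1, 3))) / 2
    tens$values <- v
    within_outside_contrast(tens, tpl, seq)$flag
  })
  expect_lte(sum(flags), 1)
})
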