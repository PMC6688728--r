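test_that("window arithmetic follows the half-open stride convention", {
  sl <- window_slices(1000, window_spec(200 / 250, fs = 250))
  expect_equal(nrow(sl), 9)
  expect_equal(sl$start, seq(1, 801, by = 100))
  expect_equal(sl$end - sl$start + 1, rep(200, 9))
  # zero overlap tiles disjointly
  sl0 <- window_slices(1000, window_spec(200 / 250, fs = 250, overlap = 0))
  expect_equal(sl0$start, c(1, 201, 401, 601, 801))
  expect_equal(unlist(Map(seq, sl0$start, sl0$end)), 1:1000)
  expect_error(window_slices(100, window_spec(2, fs = 250)), "longer")
  expect_error(window_spec(0.01, fs = 250), "8 samples")
  expect_error(window_spec(1, fs = 250, overlap = 1), "overlap")
})

test_that("band-pass keeps the passband and kills the stopband", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  pass <- sin(2 * pi * 20 * t)
  stopb <- sin(2 * pi * 5 * t)
  yp <- bandpass(pass, c(15, 25), fs)
  ys <- bandpass(stopb, c(15, 25), fs)
  mid <- 1000:4000
  expect_equal(max(abs(yp[mid])), 1, tolerance = 0.05)
  expect_lt(max(abs(ys[mid])), 0.01)  # >= 40 dB down
  expect_equal(bandpass(rep(0, 1000), c(15, 25), fs), rep(0, 1000))
  expect_error(bandpass(pass, c(15, 130), fs), "fs/2")
})

test_that("analytic signal recovers envelope, phase and chirp rate", {
  fs <- 250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- 3 * cos(2 * pi * 20 * t)
  an <- analytic_signal(x)
  mid <- 200:2200
  expect_equal(mean(an$envelope[mid]), 3, tolerance = 0.01)
  # relative phase of a lagged copy
  phi <- pi / 3
  y <- cos(2 * pi * 20 * t - phi)
  any_ <- analytic_signal(cbind(x, y))
  dphi <- Arg(exp(1i * (any_$phase[mid, 1] - any_$phase[mid, 2])))
  expect_equal(mean(dphi), phi, tolerance = 0.01)
  # reconstruction
  z <- an$envelope * exp(1i * an$phase)
  expect_equal(Re(z), x, tolerance = 1e-9)
  # chirp: instantaneous frequency tracks the sweep
  f0 <- 10; rate <- 2
  ch <- cos(2 * pi * (f0 * t + rate * t^2 / 2))
  ph <- analytic_signal(ch)$phase
  inst <- diff(unwrap_phase(ph)) * fs / (2 * pi)
  expect_equal(inst[1500], f0 + rate * t[1500], tolerance = 0.3)
})

test_that("pairwise metrics match their closed-form examples", {
  # AEC
  e <- runif(200, 1, 2)
  expect_equal(aec(e, e), 1)
  expect_equal(aec(e, -2 * e + 5), -1)
  expect_true(is.na(aec(rep(1, 50), e[1:50])))
  # PLV
  n <- 16
  base <- runif(n, -pi, pi)
  expect_equal(plv(base, base - 0.7), 1)
  grid <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  expect_equal(plv(grid, rep(0, n)), 0, tolerance = 1e-12)
  # PLI
  expect_equal(pli(base, base), 0)
  expect_equal(pli(base + pi / 4, base), 1)
  alt <- rep(c(pi / 4, -pi / 4), 8)
  expect_equal(pli(base + alt, base), 0)
})

test_that("null PLV scales as 1/sqrt(n)", {
  set.seed(17)
  n <- 400
  sims <- replicate(300, plv(runif(n, -pi, pi), runif(n, -pi, pi)))
  # brute-force Monte-Carlo oracle for the Rayleigh mean: sqrt(pi / (4 n))
  expect_equal(mean(sims), sqrt(pi / (4 * n)), tolerance = 0.05)
})

test_that("AEC null distribution is tight for long windows", {
  set.seed(18)
  vals <- replicate(200, aec(abs(rnorm(1000)), abs(rnorm(1000))))
  expect_gt(mean(abs(vals) < 0.1), 0.97)
})

test_that("windowed coherence separates zero-lag from lagged coupling", {
  fs <- 250
  set.seed(19)
  x <- bandpass(rnorm(fs * 8), c(15, 25), fs)
  co0 <- coherence_pair(x, x, c(15, 25), fs)
  expect_equal(unname(co0["COH"]), 1, tolerance = 1e-6)
  expect_lt(unname(co0["iCO"]), 0.05)
  # quarter cycle at band center: coherency nearly purely imaginary
  lag <- round(fs / 20 / 4)
  xq <- x[(lag + 1):length(x)]
  xs <- x[1:(length(x) - lag)]
  coq <- coherence_pair(xq, xs, c(18, 22), fs)
  expect_gt(unname(coq["iCO"] / coq["COH"]), 0.8)
  # independent noise: coherence near the Welch bias floor, not near 1
  y <- bandpass(rnorm(fs * 8), c(15, 25), fs)
  coi <- coherence_pair(x, y, c(15, 25), fs)
  expect_lt(unname(coi["COH"]), 0.5)
  expect_error(coherence_pair(x[1:5], x[1:5], c(15, 25), fs), "short|segments")
})

test_that("iCO never exceeds COH and ranges hold on random inputs", {
  fs <- 250
  set.seed(20)
  for (i in 1:20) {
    x <- bandpass(rnorm(fs * 3), c(8, 13), fs)
    y <- bandpass(rnorm(fs * 3), c(8, 13), fs)
    co <- coherence_pair(x, y, c(8, 13), fs)
    expect_lte(co["iCO"], co["COH"] + 1e-12)
    expect_gte(co["COH"], 0)
    expect_lte(co["COH"], 1)
    p1 <- runif(100, -pi, pi); p2 <- runif(100, -pi, pi)
    expect_gte(plv(p1, p2), 0); expect_lte(plv(p1, p2), 1)
    expect_gte(pli(p1, p2), 0); expect_lte(pli(p1, p2), 1)
  }
})

test_that("vectorized window metrics equal naive loop implementations", {
  set.seed(23)
  fs <- 250
  x <- bandpass(matrix(rnorm(fs * 4 * 3), ncol = 3), c(8, 13), fs)
  an <- analytic_signal(x)
  s_aec <- sliding_connectivity(x, "AEC", window_spec(1, fs), c(8, 13),
                                fs = fs, prefiltered = TRUE)
  s_plv <- sliding_connectivity(x, "PLV", window_spec(1, fs), c(8, 13),
                                fs = fs, prefiltered = TRUE)
  s_pli <- sliding_connectivity(x, "PLI", window_spec(1, fs), c(8, 13),
                                fs = fs, prefiltered = TRUE)
  sl <- window_slices(nrow(x), window_spec(1, fs))
  for (k in seq_len(nrow(sl))) {
    idx <- sl$start[k]:sl$end[k]
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      i <- pair[1]; j <- pair[2]
      expect_equal(s_aec$values[i, j, k],
                   naive_aec(an$envelope[idx, i], an$envelope[idx, j]),
                   tolerance = 1e-12)
      expect_equal(s_plv$values[i, j, k],
                   naive_plv(an$phase[idx, i], an$phase[idx, j]),
                   tolerance = 1e-12)
      expect_equal(s_pli$values[i, j, k],
                   naive_pli(an$phase[idx, i], an$phase[idx, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("all metrics are invariant to positive channel rescaling", {
  set.seed(24)
  fs <- 250
  x <- matrix(rnorm(fs * 4 * 2), ncol = 2)
  sc <- cbind(x[, 1] * 3.7, x[, 2] * 0.2)
  for (m in c("AEC", "COH", "iCO", "PLV", "PLI")) {
    s1 <- sliding_connectivity(x, m, window_spec(1, fs), c(8, 13), fs = fs)
    s2 <- sliding_connectivity(sc, m, window_spec(1, fs), c(8, 13), fs = fs)
    expect_equal(s1$values, s2$values, tolerance = 1e-8)
  }
})

test_that("pair series agree with full-length estimates for static coupling", {
  set.seed(25)
  seq1 <- build_state_sequence(120, 3, fs = 250, labels = 2)
  x <- simulate_switching_mar(mar_state_specs(), seq1)
  xf <- bandpass(x, c(15, 25), 250)
  an <- analytic_signal(xf)
  s <- sliding_connectivity(xf, "AEC", window_spec(4, 250), c(15, 25),
                            fs = 250, prefiltered = TRUE)
  full <- aec(an$envelope[, 1], an$envelope[, 2])
  expect_equal(mean(s$values), full, tolerance = 0.1)
  expect_equal(length(s$values),
               nrow(window_slices(nrow(x), window_spec(4, 250))))
})

test_that("network tensors are symmetric with zero diagonals", {
  set.seed(26)
  x <- matrix(rnorm(250 * 3 * 4), ncol = 4)
  for (m in c("AEC", "COH", "PLI")) {
    tens <- sliding_connectivity(x, m, window_spec(1, 250), c(8, 13),
                                 fs = 250)
    for (k in seq_len(dim(tens$values)[3])) {
      M <- tens$values[, , k]
      expect_equal(M, t(M), tolerance = 1e-12)
      expect_true(all(diag(M) == 0))
    }
  }
})
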