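test_that("sigmoid and fixed point satisfy their defining equations", {
  p <- jansen_rit_params()
  expect_equal(jr_sigmoid(p$v0, p), p$e0)
  expect_gt(jr_sigmoid(100, p), 2 * p$e0 - 1e-6)
  expect_lt(jr_sigmoid(-100, p), 1e-6)

  fp <- jansen_rit_fixed_point(p)
  expect_equal(max(abs(jansen_rit_drift(fp, p))), 0, tolerance = 1e-6)
})

test_that("drift rejects non-finite states", {
  p <- jansen_rit_params()
  expect_error(jansen_rit_drift(c(1, 2, NaN, 0, 0, 0), p), "finite")
})

test_that("Heun step reproduces the second-order linear update", {
  lambda <- -0.7
  dt <- 0.1
  x <- 2.5
  out <- heun_sde_step(x, dt, function(s) lambda * s)
  expect_equal(out, x * (1 + lambda * dt + (lambda * dt)^2 / 2),
               tolerance = 1e-14)
})

test_that("deterministic Heun converges at second order", {
  # dx/dt = -x, x(0) = 1, endpoint at t = 1
  run <- function(dt) {
    x <- 1
    for (i in seq_len(round(1 / dt))) {
      x <- heun_sde_step(x, dt, function(s) -s)
    }
    x
  }
  err1 <- abs(run(0.01) - exp(-1))
  err2 <- abs(run(0.005) - exp(-1))
  expect_equal(err1 / err2, 4, tolerance = 0.2)
})

test_that("the working point crosses a Hopf bifurcation as drive rises", {
  p <- jansen_rit_params()
  max_re <- function(drive) {
    fp <- jansen_rit_fixed_point(p, input = drive)
    J <- matrix(0, 6, 6)
    h <- 1e-6
    f0 <- jansen_rit_drift(fp, p, input = drive)
    for (j in 1:6) {
      dv <- fp
      dv[j] <- dv[j] + h
      J[, j] <- (jansen_rit_drift(dv, p, input = drive) - f0) / h
    }
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  expect_lt(max_re(40), 0)    # below the lower Hopf: stable focus
  expect_gt(max_re(220), 0)   # default drive: unstable (limit cycle)
  # bisect the crossing
  lo <- 40; hi <- 220
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    if (max_re(mid) < 0) lo <- mid else hi <- mid
  }
  expect_lt(lo, 220)
  expect_gt(hi, 40)
  expect_lt(hi - lo, 0.1)
})

test_that("delay matrices follow distance / velocity with symmetry", {
  cent <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 60, 0))
  D <- build_delays(cent, v = 10)
  expect_equal(D[1, 2], 0.01)          # 100 mm at 10 m/s = 10 ms
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_error(build_delays(cent, v = -1), "positive")
})

test_that("structural tensors activate one complete subgraph at a time", {
  tpl <- tiny_templates()
  seq <- build_state_sequence(c(0.5, 0.5, 0.5), 4, fs = 100,
                              labels = c(3, 0, 2))
  st <- build_structural_tensor(tpl, seq)
  # first segment: VIS mask (2 nodes) -> 2 nonzero entries (m*(m-1))
  s1 <- structural_slice(st, 10)
  m <- length(tpl$masks$VIS)
  expect_equal(sum(s1 != 0), m * (m - 1))
  expect_equal(s1, t(s1))
  expect_true(all(diag(s1) == 0))
  # union over time equals union of mask subgraphs
  union_obs <- Reduce(`|`, lapply(c(1, 60, 110), function(i) {
    structural_slice(st, i) != 0
  }))
  union_exp <- Reduce(`|`, lapply(tpl$masks[c(4, 1, 3)], function(idx) {
    M <- matrix(FALSE, 12, 12)
    M[idx, idx] <- TRUE
    diag(M) <- FALSE
    M
  }))
  expect_equal(union_obs, union_exp)
  expect_error(build_structural_tensor(
    tpl, build_state_sequence(1, 5, fs = 100, labels = 4)), "range")
})

test_that("two-node simulation is reproducible and alpha-dominant", {
  p <- jansen_rit_params()
  seq1 <- build_state_sequence(8, 2, fs = 250, labels = 0)
  tr <- coupling_timecourse(seq1, c(0, 0))
  set.seed(21)
  x1 <- simulate_two_node_nmm(p, tr)
  set.seed(21)
  x2 <- simulate_two_node_nmm(p, tr)
  expect_identical(x1, x2)
  expect_equal(nrow(x1), 2000)
  sp <- spec.pgram(ts(x1[, 1], frequency = 250), spans = 7, plot = FALSE)
  pk <- sp$freq[which.max(sp$spec)]
  expect_gte(pk, 8)
  expect_lte(pk, 13)
})

test_that("uncoupled nodes are at coherence chance level; coupling raises
           phase locking", {
  p <- jansen_rit_params()
  seq1 <- build_state_sequence(24, 2, fs = 250, labels = 0)
  plv_at <- function(level, seed) {
    tr <- coupling_timecourse(seq1, c(level, level))
    set.seed(seed)
    x <- simulate_two_node_nmm(p, tr)
    xf <- bandpass(x, c(8, 13), 250)
    s <- sliding_connectivity(xf, "PLV", window_spec(2, 250), c(8, 13),
                              fs = 250, prefiltered = TRUE)
    s$values
  }
  v0 <- unlist(lapply(1:4, function(s) plv_at(0, 30 + s)))
  v1 <- unlist(lapply(1:4, function(s) plv_at(0.9, 30 + s)))
  wt <- wilcox.test(v1, v0, alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.001)
  # uncoupled AEC near zero on long windows
  tr0 <- coupling_timecourse(seq1, c(0, 0))
  set.seed(55)
  x <- simulate_two_node_nmm(p, tr0)
  xf <- bandpass(x, c(8, 13), 250)
  a <- sliding_connectivity(xf, "AEC", window_spec(8, 250), c(8, 13),
                            fs = 250, prefiltered = TRUE)
  expect_lt(abs(mean(a$values)), 0.25)
})

test_that("network simulation respects its configuration contracts", {
  tpl <- tiny_templates()
  p <- jansen_rit_params()
  # all-zero structural matrix: independent nodes, reproducible
  cfg <- nmm_network_config(matrix(0, 4, 4), duration = 4, fs_out = 250)
  set.seed(31)
  x1 <- simulate_network(p, cfg)
  set.seed(31)
  x2 <- simulate_network(p, cfg)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(1000, 4))
  # independence: mean |AEC| across pairs small
  xf <- bandpass(x1, c(8, 13), 250)
  a <- sliding_connectivity(xf, "AEC", window_spec(2, 250), c(8, 13),
                            fs = 250, prefiltered = TRUE)
  offd <- apply(a$values, 3, function(M) mean(abs(M[upper.tri(M)])))
  expect_lt(mean(offd), 0.5)
  expect_error(nmm_network_config(matrix(-1, 2, 2), duration = 1),
               ">= 0")
  expect_error(nmm_network_config(matrix(0, 2, 2)), "duration")
})

test_that("a static connected subnetwork shows elevated within connectivity", {
  # scaled-down oracle run: 12 nodes, one 4-node clique connected
  tpl <- tiny_templates()
  p <- jansen_rit_params()
  W <- matrix(0, 12, 12)
  W[1:4, 1:4] <- 1
  diag(W) <- 0
  cfg <- nmm_network_config(W, delays = build_delays(tpl$centroids),
                            k = 6, duration = 30, fs_out = 250)
  set.seed(41)
  x <- simulate_network(p, cfg)
  attr(x, "fs") <- 250
  xf <- bandpass(x, c(8, 13), 250)
  inside <- matrix(FALSE, 12, 12)
  inside[1:4, 1:4] <- TRUE
  ut <- upper.tri(inside)
  pair_means <- function(metric) {
    tens <- sliding_connectivity(xf, metric, window_spec(4, 250), c(8, 13),
                                 fs = 250, prefiltered = TRUE)
    list(within = apply(tens$values, 3, function(M) mean(M[inside & ut])),
         outside = apply(tens$values, 3, function(M) mean(M[!inside & ut])))
  }
  co <- pair_means("COH")
  wt <- wilcox.test(co$within, co$outside, alternative = "greater",
                    exact = FALSE)
  expect_lt(wt$p.value, 0.01)
  # constant coupling drives phase coherence; amplitude correlation responds
  # only weakly but not in the wrong direction
  ae <- pair_means("AEC")
  expect_gte(median(ae$within), median(ae$outside))
})
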