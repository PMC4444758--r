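test_that("spike phases interpolate linearly between spikes", {
  r <- spike_raster(data.frame(neuron = c(1L, 1L, 1L),
                               time_ms = c(10, 30, 50)),
                    duration = 60, n_neurons = 2)
  ph <- spike_phases(r, c(10, 20, 45))
  expect_equal(ph$phase[1, 1], 0)              # exactly at a spike
  expect_equal(ph$phase[1, 2], pi)             # ISI midpoint: half cycle
  expect_equal(ph$phase[1, 3], 2 * pi * 15 / 20)
  expect_true(all(ph$valid[1, ]))
  expect_false(any(ph$valid[2, ]))             # silent neuron masked out
  # query before the first / after the last spike is invalid
  ph2 <- spike_phases(r, c(5, 55))
  expect_false(any(ph2$valid[1, ]))
})

test_that("phases match a brute-force search oracle on a random raster", {
  set.seed(3)
  ev <- do.call(rbind, lapply(1:5, function(j)
    data.frame(neuron = j, time_ms = sort(runif(8, 0, 500)))))
  r <- spike_raster(ev, 500, 5)
  qt <- runif(20, 0, 500)
  ph <- spike_phases(r, qt)
  for (j in 1:5) {
    st <- ev$time_ms[ev$neuron == j]
    for (i in seq_along(qt)) {
      k <- which(st <= qt[i])
      if (length(k) && max(k) < length(st)) {
        k <- max(k)
        expect_equal(ph$phase[j, i],
                     2 * pi * (qt[i] - st[k]) / (st[k + 1] - st[k]),
                     tolerance = 1e-12)
      } else expect_false(ph$valid[j, i])
    }
  }
})

test_that("the order parameter behaves like a Kuramoto R", {
  mk <- function(phases) {
    list(phase = matrix(phases, ncol = 1), valid = matrix(TRUE, length(phases), 1),
         times = 0)
  }
  expect_equal(sync_order_parameter(mk(rep(1.3, 50)))$R, 1)
  expect_equal(sync_order_parameter(mk(rep(c(0, pi), 25)))$R, 0,
               tolerance = 1e-12)
  set.seed(4)
  Rs <- replicate(20, sync_order_parameter(mk(runif(2500, 0, 2 * pi)))$R)
  expect_lt(mean(Rs), 0.04)  # E[R] ~ 1/sqrt(N) = 0.02 for N = 2500
  # no valid neurons: flagged as NA, not zero
  none <- list(phase = matrix(NA_real_, 3, 1), valid = matrix(FALSE, 3, 1),
               times = 0)
  expect_true(is.na(sync_order_parameter(none)$R))
  expect_equal(sync_order_parameter(none)$n_valid, 0L)
})

test_that("R is invariant to relabeling and global time shifts", {
  set.seed(8)
  base <- lapply(1:6, function(j) sort(runif(12, 0, 400)))
  mkr <- function(trains, shift = 0) {
    ev <- do.call(rbind, lapply(seq_along(trains), function(j)
      data.frame(neuron = j, time_ms = trains[[j]] + shift)))
    spike_raster(ev, 500, length(trains))
  }
  qt <- seq(100, 300, by = 10)
  r0 <- mean_r <- sync_order_parameter(spike_phases(mkr(base), qt))$R
  perm <- sync_order_parameter(spike_phases(mkr(base[c(3, 1, 6, 2, 5, 4)]),
                                            qt))$R
  expect_equal(perm, r0)
  shifted <- sync_order_parameter(spike_phases(mkr(base, 50), qt + 50))$R
  expect_equal(shifted, r0, tolerance = 1e-12)
})

test_that("a phase-locked periodic lattice yields R = 1 everywhere", {
  ev <- do.call(rbind, lapply(1:20, function(j)
    data.frame(neuron = j, time_ms = seq(10, 490, by = 25))))
  r <- spike_raster(ev, 500, 20)
  s <- sync_order_parameter(spike_phases(r, seq(20, 480, by = 7)))
  expect_true(all(abs(s$R - 1) < 1e-12))
})

test_that("population spectrum finds rate-modulation frequencies", {
  set.seed(5)
  mod_raster <- function(f_hz, dur = 3000, n_neur = 300, r0 = 20, m = 0.8) {
    tt <- seq(0.5, dur - 0.5, by = 1)
    lam <- r0 * (1 + m * sin(2 * pi * f_hz * tt / 1000)) / 1000
    ev <- do.call(rbind, lapply(seq_len(length(tt)), function(i) {
      k <- rpois(1, lam[i] * n_neur)
      if (k == 0) return(NULL)
      data.frame(neuron = sample.int(n_neur, k, replace = TRUE),
                 time_ms = tt[i] + runif(k, -0.49, 0.49))
    }))
    ev <- ev[!duplicated(ev[c("neuron", "time_ms")]), ]
    spike_raster(ev, dur, n_neur)
  }
  p10 <- population_oscillation_frequency(mod_raster(10))
  expect_true(p10$significant)
  expect_lt(abs(p10$frequency - 10), 1)
  p4 <- population_oscillation_frequency(mod_raster(4))
  expect_lt(abs(p4$frequency - 4), 0.5)
  # homogeneous Poisson: no significant peak
  hom <- mod_raster(10, m = 0)
  expect_false(population_oscillation_frequency(hom)$significant)
})

test_that("group comparison is a pooled two-sample t-test", {
  set.seed(6)
  a <- rnorm(30, 1, 0.1); b <- rnorm(30, 0, 0.1)
  res <- compare_sync_groups(a, b)
  expect_lt(res$p, 1e-6)
  expect_equal(res$mean_a, mean(a))
  # identical degenerate groups
  same <- compare_sync_groups(rep(0.5, 5), rep(0.5, 5))
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)
  # cross-check against a permutation oracle on small n
  x <- c(0.1, 0.3, 0.2, 0.25); y <- c(0.5, 0.45, 0.6, 0.4)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  perms <- combn(8, 4)
  pd <- apply(perms, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
  p_perm <- mean(pd >= obs - 1e-12)
  p_t <- compare_sync_groups(x, y)$p
  expect_lt(abs(p_perm - p_t), 0.05)
  expect_lt(p_t, 0.05)
})
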