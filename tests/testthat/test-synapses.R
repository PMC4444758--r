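test_that("receptor constants match the published table", {
  expect_equal(receptor_params("AMPA")[c("tau", "E_rev")],
               list(tau = 6, E_rev = 0))
  expect_equal(receptor_params("NMDA")[c("tau", "E_rev")],
               list(tau = 160, E_rev = 0))
  expect_equal(receptor_params("GABA")[c("tau", "E_rev")],
               list(tau = 4, E_rev = -60))
  expect_equal(receptor_params("NMDA", target = "GPi")$tau, 67)
})

test_that("gating decays exponentially and spikes add the expected impulse", {
  # homogeneous decay: h halves every tau*ln(2)
  h <- 1; dt <- 0.001
  for (i in seq_len(round(6 * log(2) / dt)))
    h <- update_gating(h, 0, tau = 6, dt = dt)
  expect_equal(h, 0.5, tolerance = 1e-3)
  # density convention: a spike raises h by 1/tau, independent of dt
  expect_equal(update_gating(0, 1, tau = 6, dt = 0.1), 1 / 6 * (1 - 0),
               tolerance = 1e-12)
  expect_equal(update_gating(0, 1, tau = 6, dt = 0.05), 1 / 6)
  # unit convention: increment dt/tau
  expect_equal(update_gating(0, 1, tau = 6, dt = 0.1, amplitude = "unit"),
               0.1 / 6)
})

test_that("stationary gating under Poisson input matches the event-driven oracle", {
  set.seed(42)
  dt <- 0.1; tau <- 6; rate <- 0.04  # spikes per ms (40 Hz)
  n_steps <- 60000
  spikes <- rbinom(n_steps, 1, rate * dt)
  h <- 0; acc <- 0
  for (t in seq_len(n_steps)) {
    h <- update_gating(h, spikes[t], tau, dt)
    if (t > 10000) acc <- acc + h
  }
  mean_euler <- acc / (n_steps - 10000)
  st <- which(spikes == 1) * dt
  href <- ref_gating_event(st, tau, jump = 1 / tau, t_end = n_steps * dt,
                           dt_grid = 1)
  mean_ref <- mean(href[1001:length(href)])
  expect_lt(abs(mean_euler - mean_ref) / mean_ref, 0.05)
  # and the stationary mean approximates the rate in spikes/ms
  expect_lt(abs(mean_euler - rate) / rate, 0.15)
})

test_that("magnesium block has the Jahr-Stevens form", {
  expect_equal(mg_block(0), 3.57 / 4.57, tolerance = 1e-12)
  expect_equal(mg_block(-65), 1 / (1 + (1 / 3.57) * exp(0.062 * 65)),
               tolerance = 1e-12)
  expect_lt(abs(mg_block(-65) - 0.0595), 0.002)
  v <- seq(-90, 40, by = 1)
  expect_true(all(diff(mg_block(v)) > 0))
  expect_true(all(mg_block(v) > 0 & mg_block(v) < 1))
  expect_equal(mg_block(1e4), 1, tolerance = 1e-6)
  expect_error(mg_block(0, Mg = 0))
})

test_that("receptor currents follow I = W h (E - V)", {
  gaba <- receptor_params("GABA")
  expect_equal(receptor_current(1, -50, gaba, W = 1), -10)
  ampa <- receptor_params("AMPA")
  expect_equal(receptor_current(0.5, -60, ampa, W = 2), 60)
  expect_equal(receptor_current(1, gaba$E_rev, gaba, W = 3), 0)
  nmda <- receptor_params("NMDA")
  expect_equal(receptor_current(1, -40, nmda, W = 2),
               2 * 1 * 40 * mg_block(-40))
})

test_that("dopamine scales the STN-GPe loop weights linearly", {
  expect_equal(da_scaled_weight(20, 0), 20)
  expect_equal(da_scaled_weight(20, 0.5), 19)
  expect_equal(da_scaled_weight(1, 0.9), 0.91)
  expect_true(da_scaled_weight(20, 0.9) < da_scaled_weight(20, 0.1))
})

test_that("striatal gains are sigmoidal with the published midpoints", {
  expect_equal(striatal_gain(0, "D2"), 3.75)
  expect_equal(striatal_gain(1, "D1"), 5)
  da <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(striatal_gain(da, "D1")) > 0))
  expect_true(all(diff(striatal_gain(da, "D2")) < 0))
  expect_gt(striatal_gain(0.9, "D1"), striatal_gain(0.1, "D1"))
  expect_lt(striatal_gain(0.9, "D2"), striatal_gain(0.1, "D2"))
})

test_that("lateral kernels have the Gaussian form and stencil sizes", {
  k <- build_lateral_kernel("STN", DA = 0.5)
  expect_equal(dim(k$weights), c(5L, 5L))
  expect_equal(k$weights[3, 3], 0)  # self term excluded
  expect_equal(k$weights[3, 4], k$A * exp(-1 / k$R^2))
  expect_equal(k$weights, k$weights[5:1, ])  # reflection symmetric
  expect_equal(k$weights, t(k$weights))
  g <- build_lateral_kernel("GPe", DA = 0.5)
  expect_equal(dim(g$weights), c(11L, 11L))
  expect_equal(g$A, 1)
  expect_equal(k$A, 0.2)
})

test_that("the default width mapping shrinks both kernels with dopamine", {
  expect_lt(lateral_radius("STN", 0.9), lateral_radius("STN", 0.1))
  expect_lt(lateral_radius("GPe", 0.9), lateral_radius("GPe", 0.1))
  s01 <- sum(build_lateral_kernel("STN", 0.1)$weights)
  s09 <- sum(build_lateral_kernel("STN", 0.9)$weights)
  expect_gt(s01, s09)
  # named alternative strategies stay available
  expect_equal(lateral_radius("STN", 0.5, mapping = "swap_cd21"),
               1 - 0.1 * 0.5)
  expect_equal(lateral_radius("GPe", 0.5, mapping = "as_printed"),
               0.5 * (1 - 0.05))
  expect_error(lateral_radius("STN", 0, mapping = "as_printed"),
               "non-positive")
})

test_that("lateral current equals the brute-force double sum", {
  set.seed(7)
  k <- build_lateral_kernel("GPe", DA = 0.3)
  h <- matrix(runif(49), 7, 7)
  V <- matrix(runif(49, -70, -40), 7, 7)
  gaba <- receptor_params("GABA")
  for (bnd in c("wrap", "clip")) {
    got <- lateral_current(k, h, V, gaba, boundary = bnd)
    want <- ref_lateral_sum(k$weights, h, boundary = bnd) * (gaba$E_rev - V)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # NMDA collaterals are magnesium-blocked, GABA are not
  nmda <- receptor_params("NMDA")
  ks <- build_lateral_kernel("STN", DA = 0.3)
  got_n <- lateral_current(ks, h, V, nmda)
  want_n <- ref_lateral_sum(ks$weights, h) * (0 - V) * mg_block(V)
  expect_equal(got_n, want_n, tolerance = 1e-12)
})

test_that("lateral current trivia: zero field and impulse response", {
  k <- build_lateral_kernel("STN", DA = 0.5)
  z <- matrix(0, 9, 9)
  V <- matrix(-60, 9, 9)
  ampa <- receptor_params("AMPA")
  expect_true(all(lateral_current(k, z, V, ampa) == 0))
  h <- z; h[5, 5] <- 1
  I <- lateral_current(k, h, V, ampa)
  expect_equal(I[3:7, 3:7] / 60, k$weights, tolerance = 1e-12)
  expect_equal(I[5, 5], 0)  # no self synapse
})

test_that("current assembly honors wiring, gains and the IP ablation", {
  cfg <- circuit_config(shape = 4, duration = 10, DA = 0.5)
  n <- 4
  z <- matrix(0, n, n)
  h <- list(strd1 = z, strd2 = z, stn_ampa = z, stn_nmda = z,
            stn_nmda_gpi = z, gpe_gaba = z)
  V <- matrix(-55, n, n)
  for (nuc in c("STN", "GPe", "GPi"))
    expect_true(all(assemble_currents(nuc, h, V, 0.5, cfg) == 0))
  # one-to-one wiring: a single active STN gating element affects only the
  # matching GPe position through the direct projection (laterals off)
  cfg0 <- circuit_config(shape = 4, duration = 10, DA = 0.5,
                         A_STN = 0, A_GPe = 0)
  h1 <- h; h1$stn_ampa[2, 3] <- 1; h1$stn_nmda[2, 3] <- 1
  I <- assemble_currents("GPe", h1, V, 0.5, cfg0)
  expect_true(I[2, 3] > 0)
  expect_equal(sum(I != 0), 1L)
  # IP removal leaves only the D1 striatal term on GPi
  h2 <- h; h2$stn_ampa[] <- 1; h2$stn_nmda_gpi[] <- 1; h2$strd1[1, 1] <- 1
  I_on <- assemble_currents("GPi", h2, V, 0.5, cfg)
  I_off <- assemble_currents("GPi", h2, V, 0.5, cfg, ip_removed = TRUE)
  expect_true(all(I_on[2:4, ] > 0))       # STN drive present
  expect_equal(sum(I_off != 0), 1L)       # only the D1 element remains
  expect_lt(I_off[1, 1], 0)               # and it is inhibitory
})
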