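test_that("config holds the published defaults and round-trips", {
  cfg <- circuit_config()
  expect_equal(cfg$w_sg, 1); expect_equal(cfg$w_gs, 20)
  expect_equal(cfg$w_stn_gpi, 1.15)
  expect_equal(cfg$w_strd1_gpi, 0.8); expect_equal(cfg$w_strd2_gpe, 1)
  expect_equal(cfg$A_D1, 10); expect_equal(cfg$A_D2, 7.5)
  expect_equal(cfg$lambda_str, 7.5); expect_equal(cfg$cd2, 0.1)
  expect_equal(cfg$r_s, 1); expect_equal(cfg$r_g, 0.5)
  expect_equal(cfg$cD21, 0.1)
  expect_equal(cfg$A_STN, 0.2); expect_equal(cfg$A_GPe, 1)
  expect_equal(cfg$nlat_STN, 5L); expect_equal(cfg$nlat_GPe, 11L)
  expect_equal(cfg$tau_NMDA_GPi, 67)
  expect_error(circuit_config(bogus_field = 1), "unknown")
  expect_error(circuit_config(DA = 0.95))
  p <- tempfile()
  cfg2 <- apply_stn_lesion(circuit_config(shape = 10, DA = 0.3), 4)
  write_circuit_config(cfg2, p)
  back <- read_circuit_config(p)
  expect_equal(back[order(names(back))], cfg2[order(names(cfg2))])
  unlink(p)
})

test_that("the engine reproduces the R reference circuit", {
  # exact spike-for-spike agreement over a horizon short enough that
  # floating-point rounding differences cannot be chaotically amplified,
  # plus tight agreement of the final membrane state
  lay <- binary_stimulus_layout(f1 = 200, f2 = 400, window = c(3, 9),
                                trial_ms = 10, shape = 4)
  for (da in c(0.2, 0.8)) {
    cfg <- circuit_config(shape = 4, duration = 10, DA = da, seed = 17,
                          delay_ms = 1)
    got <- run_circuit(cfg, lay[c("D1", "D2")])
    want <- ref_run_circuit(cfg, lay[c("D1", "D2")])
    expect_identical(got$str_d1$events, want$str_d1$events)
    expect_identical(got$str_d2$events, want$str_d2$events)
    for (nm in c("stn", "gpe", "gpi")) {
      expect_gt(nrow(got[[nm]]$events), 0)
      expect_equal(got[[nm]]$events$neuron, want[[nm]]$events$neuron)
      expect_equal(got[[nm]]$events$time_ms, want[[nm]]$events$time_ms,
                   tolerance = 1e-9)
    }
  }
})

test_that("the engine matches the reference under lesion and IP removal", {
  cfg <- circuit_config(shape = 4, duration = 10, DA = 0.5, seed = 23,
                        delay_ms = 2)
  cfg <- apply_stn_lesion(cfg, 2)
  cfg <- remove_indirect_pathway(cfg)
  got <- run_circuit(cfg)
  want <- ref_run_circuit(cfg)
  for (nm in c("stn", "gpe", "gpi"))
    expect_equal(got[[nm]]$events, want[[nm]]$events, tolerance = 1e-9)
  expect_lt(median(abs(got$state$v_gpi - want$v$gpi)), 1e-3)
  # lesioned neurons are silent over a longer run
  cfg$duration <- 200
  long <- run_circuit(cfg)
  dead <- which(!cfg$stn_alive)
  expect_false(any(long$stn$events$neuron %in% dead))
  expect_gt(nrow(long$stn$events), 0)
})

test_that("simulations are bitwise reproducible and zero-duration is empty", {
  cfg <- circuit_config(shape = 8, duration = 150, DA = 0.4, seed = 5)
  a <- run_circuit(cfg); b <- run_circuit(cfg)
  expect_identical(a$stn$events, b$stn$events)
  expect_identical(a$gpe$events, b$gpe$events)
  z <- run_circuit(circuit_config(shape = 8, duration = 0, DA = 0.4))
  expect_equal(nrow(z$stn$events), 0L)
})

test_that("with all synaptic weights zero each nucleus shows its f-I rate", {
  cfg <- circuit_config(shape = 6, duration = 1000, DA = 0.5, seed = 9,
                        w_sg = 0, w_gs = 0, w_stn_gpi = 0,
                        A_STN = 0, A_GPe = 0)
  sim <- run_circuit(cfg)
  iso_stn <- characterize_fi("STN", 30, duration = 1000)$rate_hz
  iso_gpe <- characterize_fi("GPe", 10, duration = 1000)$rate_hz
  expect_lt(abs(mean_firing_rate(sim$stn, c(100, 1000)) - iso_stn) / iso_stn,
            0.05)
  expect_lt(abs(mean_firing_rate(sim$gpe, c(100, 1000)) - iso_gpe) / iso_gpe,
            0.05)
})

test_that("lesion geometry and bounds are enforced", {
  cfg <- apply_stn_lesion(circuit_config(shape = 50), 20)
  alive <- matrix(cfg$stn_alive, 50, 50)
  expect_equal(sum(!alive), 400L)
  expect_false(any(alive[16:35, 16:35]))
  expect_true(all(alive[1:15, ]))
  expect_equal(apply_stn_lesion(circuit_config(shape = 10), 0)$stn_alive,
               NULL)
  expect_error(apply_stn_lesion(circuit_config(shape = 10), 12))
  # full lesion: STN silent, GPe loses its excitatory drive
  full <- apply_stn_lesion(circuit_config(shape = 6, duration = 300,
                                          DA = 0.5, seed = 2), 6)
  sim <- run_circuit(full)
  expect_equal(nrow(sim$stn$events), 0L)
  expect_gt(nrow(sim$gpe$events), 0L)
})

test_that("default parameter set stays finite over a one-second run", {
  sim <- run_circuit(circuit_config(shape = 10, duration = 1000, DA = 0.1,
                                    seed = 1))
  expect_true(all(is.finite(sim$state$v_stn)))
  expect_true(all(is.finite(sim$state$v_gpe)))
  expect_true(all(is.finite(sim$state$h)))
  expect_gt(nrow(sim$stn$events), 0)
})

test_that("state chaining resumes from the stored network state", {
  cfg <- circuit_config(shape = 6, duration = 100, DA = 0.5, seed = 4)
  s1 <- run_circuit(cfg)
  s2 <- run_circuit(cfg, state = s1$state)
  # resumed run starts at the attractor, a fresh one at rest: different
  expect_false(identical(s1$stn$events, s2$stn$events))
  expect_equal(length(s1$state$v_stn), 36L)
  expect_equal(dim(s1$state$h), c(36L, 6L))
})
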