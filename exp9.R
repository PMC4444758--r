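library(bgspike)
probe <- function(sig_s, sig_g, da = 0.5, seed = 3, dur = 1200, A_stn = 0.2,
                  shape = 20, dt = 1) {
  cfg <- circuit_config(shape = shape, duration = dur, DA = da, seed = seed,
                        dt = dt, A_STN = A_stn,
                        r_s = sig_s/(0.4+1.8*(1-da)), r_g = sig_g/(1.2+5*da))
  sim <- run_circuit(cfg)
  sm <- summary(sim)
  pk <- population_oscillation_frequency(sim$stn, window = c(100, dur))
  cat(sprintf("dt=%.1f ss=%4.2f sg=%4.2f As=%.2f | Rs %.2f Rg %.2f | STN %5.1f GPe %5.1f | pk %4.1fHz %s\n",
      dt, sig_s, sig_g, A_stn, sm$R_stn, sm$R_gpe,
      sm$rate_stn, sm$rate_gpe, pk$peak_frequency, pk$significant))
}
for (ss in c(0.5, 1.0, 1.5, 2.0)) probe(ss, 3.0)
for (sg in c(1.0, 2.0)) probe(1.0, sg)
probe(1.0, 3.0, dt = 0.5)
probe(1.0, 3.0, dt = 0.25)
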