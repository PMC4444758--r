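# Independent reference implementations used as oracles. These are written
# as plain, slow R loops on tiny problems and never share code with the
# compiled engine.

# scalar-loop Izhikevich integration of one neuron (forward Euler, reset
# after the integration substep); I_trace has one entry per step
ref_izhikevich <- function(params, I_trace, dt, v0 = params$c,
                           u0 = params$b * params$c) {
  v <- v0; u <- u0
  vs <- numeric(length(I_trace)); us <- numeric(length(I_trace))
  spikes <- logical(length(I_trace))
  for (t in seq_along(I_trace)) {
    vn <- v + dt * (0.04 * v^2 + 5 * v - u + 140 + I_trace[t])
    un <- u + dt * params$a * (params$b * v - u)
    if (vn >= params$v_peak) {
      spikes[t] <- TRUE
      vn <- params$c
      un <- un + params$d
    }
    v <- vn; u <- un
    vs[t] <- v; us[t] <- u
  }
  list(v = vs, u = us, spikes = spikes)
}

# event-driven solution of tau h' = -h + impulses: h jumps by `jump` at
# each spike time and decays exponentially in between
ref_gating_event <- function(spike_times, tau, jump, t_end, dt_grid) {
  ts <- seq(dt_grid, t_end, by = dt_grid)
  h <- numeric(length(ts))
  cur <- 0; t_prev <- 0; si <- 1
  spike_times <- sort(spike_times)
  for (i in seq_along(ts)) {
    t <- ts[i]
    while (si <= length(spike_times) && spike_times[si] <= t) {
      cur <- cur * exp(-(spike_times[si] - t_prev) / tau) + jump
      t_prev <- spike_times[si]
      si <- si + 1
    }
    h[i] <- cur * exp(-(t - t_prev) / tau)
  }
  h
}

# brute-force lateral sum: double loop over all source neurons
ref_lateral_sum <- function(weights, h_field, boundary = "wrap") {
  n <- nrow(h_field); m <- ncol(h_field)
  hw <- (nrow(weights) - 1L) %/% 2L
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (di in -hw:hw) for (dj in -hw:hw) {
      p <- i + di; q <- j + dj
      if (boundary == "wrap") {
        p <- 1L + (p - 1L) %% n; q <- 1L + (q - 1L) %% m
      } else if (p < 1 || p > n || q < 1 || q > m) next
      acc <- acc + weights[di + hw + 1L, dj + hw + 1L] * h_field[p, q]
    }
    out[i, j] <- acc
  }
  out
}

# full reference circuit: replicates the engine semantics step by step
# using the exported module operations (update_gating, assemble_currents,
# step_lattice). Only viable for tiny lattices and short runs.
ref_run_circuit <- function(cfg, pools = NULL) {
  n <- cfg$shape; N <- n * n
  dt <- cfg$dt
  n_steps <- round(cfg$duration / dt)
  D <- max(1L, as.integer(round(cfg$delay_ms / dt)))

  set.seed(cfg$seed)
  stn <- init_lattice("STN", n, jitter = cfg$jitter)
  gpe <- init_lattice("GPe", n, jitter = cfg$jitter)
  gpi <- init_lattice("GPi", n, jitter = cfg$jitter)
  if (!is.null(cfg$stn_alive))
    stn$alive_mask <- matrix(cfg$stn_alive, n, n)

  if (is.null(pools))
    pools <- list(D1 = bgspike:::silent_pool("D1", n),
                  D2 = bgspike:::silent_pool("D2", n))
  r_d1 <- generate_poisson(pools$D1, cfg$duration, dt)
  r_d2 <- generate_poisson(pools$D2, cfg$duration, dt)
  bucket <- function(r) {
    out <- vector("list", n_steps)
    if (nrow(r$events) == 0) return(out)
    stp <- 1L + as.integer(floor((r$events$time_ms - 1e-9) / dt))
    split(r$events$neuron, factor(stp, levels = seq_len(n_steps)))
  }
  b1 <- bucket(r_d1); b2 <- bucket(r_d2)

  kernels <- list(
    STN = build_lateral_kernel("STN", cfg$DA, A = cfg$A_STN,
                               nlat = cfg$nlat_STN,
                               mapping = cfg$lateral_mapping,
                               r_s = cfg$r_s, r_g = cfg$r_g,
                               cD21 = cfg$cD21),
    GPe = build_lateral_kernel("GPe", cfg$DA, A = cfg$A_GPe,
                               nlat = cfg$nlat_GPe,
                               mapping = cfg$lateral_mapping,
                               r_s = cfg$r_s, r_g = cfg$r_g,
                               cD21 = cfg$cD21))

  z <- matrix(0, n, n)
  h <- list(strd1 = z, strd2 = z, stn_ampa = z, stn_nmda = z,
            stn_nmda_gpi = z, gpe_gaba = z)
  sp_hist_stn <- vector("list", n_steps)   # spike masks per step
  sp_hist_gpe <- vector("list", n_steps)
  ev <- list(stn = list(), gpe = list(), gpi = list())
  amp <- cfg$spike_amplitude

  for (t in seq_len(n_steps)) {
    s_d1 <- z; s_d2 <- z
    if (!is.null(b1[[t]]) && length(b1[[t]])) s_d1[b1[[t]]] <- 1
    if (!is.null(b2[[t]]) && length(b2[[t]])) s_d2[b2[[t]]] <- 1
    del <- t - D
    s_stn <- if (del >= 1) sp_hist_stn[[del]] else z
    s_gpe <- if (del >= 1) sp_hist_gpe[[del]] else z

    h$strd1 <- update_gating(h$strd1, s_d1, cfg$tau_GABA, dt, amp)
    h$strd2 <- update_gating(h$strd2, s_d2, cfg$tau_GABA, dt, amp)
    h$stn_ampa <- update_gating(h$stn_ampa, s_stn, cfg$tau_AMPA, dt, amp)
    h$stn_nmda <- update_gating(h$stn_nmda, s_stn, cfg$tau_NMDA, dt, amp)
    h$stn_nmda_gpi <- update_gating(h$stn_nmda_gpi, s_stn,
                                    cfg$tau_NMDA_GPi, dt, amp)
    h$gpe_gaba <- update_gating(h$gpe_gaba, s_gpe, cfg$tau_GABA, dt, amp)

    I_gpe <- assemble_currents("GPe", h, gpe$v, cfg$DA, cfg, kernels)
    I_stn <- assemble_currents("STN", h, stn$v, cfg$DA, cfg, kernels)
    I_gpi <- assemble_currents("GPi", h, gpi$v, cfg$DA, cfg, kernels,
                               ip_removed = isTRUE(cfg$ip_removed))

    rg <- step_lattice(gpe, I_gpe, dt); gpe <- rg$lattice
    rs <- step_lattice(stn, I_stn, dt); stn <- rs$lattice
    ri <- step_lattice(gpi, I_gpi, dt); gpi <- ri$lattice

    sp_hist_stn[[t]] <- rs$spikes + 0
    sp_hist_gpe[[t]] <- rg$spikes + 0
    for (nm in c("stn", "gpe", "gpi")) {
      sp <- switch(nm, stn = rs$spikes, gpe = rg$spikes, gpi = ri$spikes)
      if (any(sp))
        ev[[nm]][[length(ev[[nm]]) + 1L]] <-
          data.frame(neuron = which(sp), time_ms = t * dt)
    }
  }
  mk <- function(l) spike_raster(
    if (length(l)) do.call(rbind, l) else
      data.frame(neuron = integer(0), time_ms = numeric(0)),
    duration = cfg$duration, n_neurons = N)
  list(stn = mk(ev$stn), gpe = mk(ev$gpe), gpi = mk(ev$gpi),
       str_d1 = r_d1, str_d2 = r_d2,
       v = list(stn = as.vector(stn$v), gpe = as.vector(gpe$v),
                gpi = as.vector(gpi$v)))
}
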