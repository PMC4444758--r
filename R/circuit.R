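#' Circuit configuration
#'
#' Collects every model and simulation parameter of the
#' striatum-STN-GPe-GPi circuit with its default value. The defaults are
#' the published parameter set of the model: neuron presets (see
#' [izhikevich_params()]), projection weights (`w_sg = 1`, `w_gs = 20`,
#' `w_stn_gpi = 1.15`, `w_strd1_gpi = 0.8`, `w_strd2_gpe = 1`), striatal
#' gain constants (`A_D1 = 10`, `A_D2 = 7.5`, `lambda_str = 7.5`),
#' receptor constants (see [receptor_params()]), lateral kernel
#' parameters (`A_STN = 0.2`, `A_GPe = 1`, `nlat` 5/11, `r_s = 1`,
#' `r_g = 0.5`, `cD21 = 0.1`) and the magnesium concentration `Mg = 1`.
#'
#' @param shape lattice side (default 50; all four populations share it).
#' @param dt integration step, ms.
#' @param duration run length, ms.
#' @param DA dopamine level in `[0.1, 0.9]`.
#' @param jitter initial membrane-potential jitter amplitude, mV.
#' @param burn_in interval (ms) excluded from summary metrics.
#' @param lateral_mapping dopamine-to-kernel-width strategy, see
#'   [lateral_radius()].
#' @param spike_amplitude gating impulse convention, see
#'   [update_gating()].
#' @param seed integer seed for initial jitter and striatal spike
#'   generation.
#' @param ... overrides for any other stored parameter (e.g. `w_gs = 15`,
#'   `A_STN = 0.1`, `ip_removed = TRUE`).
#' @return object of class `circuit_config`.
#' @examples
#' cfg <- circuit_config(shape = 10, duration = 200, DA = 0.5)
#' cfg
#' @export
circuit_config <- function(shape = 50, dt = 0.1, duration = 1000, DA = 0.5,
                           jitter = 5, burn_in = 100,
                           lateral_mapping = "default",
                           spike_amplitude = "density",
                           seed = 1L, ...) {
  cfg <- list(
    shape = if (length(shape) == 2L) shape[1] else shape,
    dt = dt, duration = duration, DA = DA,
    jitter = jitter, burn_in = burn_in,
    lateral_mapping = lateral_mapping,
    spike_amplitude = spike_amplitude,
    seed = as.integer(seed),
    # projection weights
    w_sg = 1, w_gs = 20, w_stn_gpi = 1.15,
    w_strd1_gpi = 0.8, w_strd2_gpe = 1,
    cd2 = 0.1,
    # striatal gains
    A_D1 = 10, A_D2 = 7.5, lambda_str = 7.5,
    # receptors
    Mg = 1, E_AMPA = 0, E_NMDA = 0, E_GABA = -60,
    tau_AMPA = 6, tau_NMDA = 160, tau_GABA = 4, tau_NMDA_GPi = 67,
    # synaptic transmission delay between neurons, ms
    delay_ms = 3.5,
    # lateral kernel boundary: "wrap" (toroidal) or "clip"
    boundary = "wrap",
    # lateral kernels
    r_s = 1, r_g = 0.5, cD21 = 0.1, A_STN = 0.2, A_GPe = 1,
    nlat_STN = 5L, nlat_GPe = 11L,
    # ablations
    ip_removed = FALSE, stn_alive = NULL)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown))
    stop("unknown circuit_config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(extra)] <- extra
  validate_circuit_config(structure(cfg, class = "circuit_config"))
}

validate_circuit_config <- function(cfg) {
  stopifnot(cfg$dt > 0, cfg$duration >= 0, cfg$shape >= 1,
            cfg$DA >= 0.1 - 1e-12, cfg$DA <= 0.9 + 1e-12)
  if (!is.null(cfg$stn_alive))
    stopifnot(length(cfg$stn_alive) == cfg$shape^2)
  cfg
}

#' @export
print.circuit_config <- function(x, ...) {
  cat(sprintf(paste0("<circuit_config> %dx%d lattices, dt = %g ms, ",
                     "%g ms, DA = %g\n"),
              x$shape, x$shape, x$dt, x$duration, x$DA))
  cat(sprintf("  mapping = %s, ip_removed = %s, lesioned STN = %d\n",
              x$lateral_mapping, x$ip_removed,
              if (is.null(x$stn_alive)) 0L else sum(!x$stn_alive)))
  invisible(x)
}

#' Serialize / restore a circuit configuration
#'
#' Round-trippable plain-text (`key<TAB>value`) representation used for
#' run provenance.
#'
#' @param cfg a `circuit_config`.
#' @param path file path.
#' @export
write_circuit_config <- function(cfg, path) {
  flat <- cfg
  flat$stn_alive <- if (is.null(cfg$stn_alive)) "" else
    paste(as.integer(cfg$stn_alive), collapse = ",")
  lines <- vapply(names(flat), function(k)
    sprintf("%s\t%s", k, as.character(flat[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_circuit_config
#' @export
read_circuit_config <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, col.names = c("k", "v"),
                          colClasses = "character")
  get <- function(k) kv$v[match(k, kv$k)]
  num <- function(k) as.numeric(get(k))
  alive <- get("stn_alive")
  circuit_config(
    shape = num("shape"), dt = num("dt"), duration = num("duration"),
    DA = num("DA"), jitter = num("jitter"), burn_in = num("burn_in"),
    lateral_mapping = get("lateral_mapping"),
    spike_amplitude = get("spike_amplitude"), seed = num("seed"),
    w_sg = num("w_sg"), w_gs = num("w_gs"), w_stn_gpi = num("w_stn_gpi"),
    w_strd1_gpi = num("w_strd1_gpi"), w_strd2_gpe = num("w_strd2_gpe"),
    cd2 = num("cd2"), A_D1 = num("A_D1"), A_D2 = num("A_D2"),
    lambda_str = num("lambda_str"), Mg = num("Mg"), delay_ms = num("delay_ms"),
    boundary = get("boundary"),
    r_s = num("r_s"), r_g = num("r_g"), cD21 = num("cD21"),
    A_STN = num("A_STN"), A_GPe = num("A_GPe"),
    nlat_STN = as.integer(num("nlat_STN")),
    nlat_GPe = as.integer(num("nlat_GPe")),
    ip_removed = as.logical(get("ip_removed")),
    stn_alive = if (is.na(alive) || !nzchar(alive)) NULL else
      as.logical(as.integer(strsplit(alive, ",")[[1]])))
}

#' Lesion a rectangular patch of the STN lattice
#'
#' Neurons inside the patch are removed from the dynamics and contribute
#' no spikes to any target (their gating stays at zero). The default is
#' the centered square patch used in the lesion experiments.
#'
#' @param config a [circuit_config()].
#' @param patch_side side of the square lesion patch (e.g. 20 on a 50x50
#'   lattice); 0 leaves the circuit intact.
#' @return the modified configuration.
#' @export
apply_stn_lesion <- function(config, patch_side = 20) {
  n <- config$shape
  stopifnot(patch_side >= 0, patch_side <= n)
  if (patch_side == 0) return(config)
  alive <- matrix(TRUE, n, n)
  lo <- floor((n - patch_side) / 2) + 1L
  hi <- lo + patch_side - 1L
  alive[lo:hi, lo:hi] <- FALSE
  config$stn_alive <- as.vector(alive)
  config
}

#' Remove the indirect pathway readout (STN projection onto GPi)
#'
#' GPi then receives the D1-striatal GABAergic current only; the STN-GPe
#' loop itself is untouched.
#'
#' @param config a [circuit_config()].
#' @export
remove_indirect_pathway <- function(config) {
  config$ip_removed <- TRUE
  config
}

#' Run the full circuit simulation
#'
#' Time-steps the STN, GPe and GPi lattices together with all synaptic
#' gating variables. Update order within a step: striatal spikes, gating
#' (driven by the previous step's neuronal spikes), synaptic currents,
#' forward-Euler lattice integration, spike detection and reset — giving
#' a uniform one-step causal delay on every projection. Deterministic for
#' a fixed `config$seed`.
#'
#' @param config a [circuit_config()].
#' @param pools optional list with striatal pools `D1` and `D2` (from
#'   [binary_stimulus_layout()] or [bandit_stimulus_layout()]); when
#'   omitted the striatum is silent, i.e. the free-running STN-GPe
#'   protocol.
#' @return object of class `bg_sim` with spike rasters `stn`, `gpe`,
#'   `gpi`, striatal rasters `str_d1`, `str_d2`, and the `config`
#'   snapshot.
#' @examples
#' \donttest{
#' sim <- run_circuit(circuit_config(shape = 10, duration = 300, DA = 0.1))
#' summary(sim)
#' }
#' @param state optional network state from a previous run (the `state`
#'   element of a `bg_sim`); membrane potentials, recovery variables and
#'   synaptic gating resume from it instead of fresh initialization, so
#'   consecutive runs chain into one continuous simulation (the short
#'   spike-transmission ring buffer restarts empty, a one-delay-long
#'   perturbation at the seam).
#' @export
run_circuit <- function(config, pools = NULL, state = NULL) {
  cfg <- validate_circuit_config(config)
  n <- cfg$shape; N <- n * n
  dt <- cfg$dt
  n_steps <- round(cfg$duration / dt)

  set.seed(cfg$seed)
  stn <- init_lattice("STN", n, jitter = cfg$jitter)
  gpe <- init_lattice("GPe", n, jitter = cfg$jitter)
  gpi <- init_lattice("GPi", n, jitter = cfg$jitter)
  h0 <- NULL
  if (!is.null(state)) {
    stopifnot(length(state$v_stn) == N)
    stn$v[] <- state$v_stn; stn$u[] <- state$u_stn
    gpe$v[] <- state$v_gpe; gpe$u[] <- state$u_gpe
    gpi$v[] <- state$v_gpi; gpi$u[] <- state$u_gpi
    h0 <- state$h
  }
  alive <- if (is.null(cfg$stn_alive)) rep(TRUE, N) else cfg$stn_alive

  if (is.null(pools))
    pools <- list(D1 = silent_pool("D1", n), D2 = silent_pool("D2", n))
  r_d1 <- generate_poisson(pools$D1, cfg$duration, dt)
  r_d2 <- generate_poisson(pools$D2, cfg$duration, dt)
  s_d1 <- raster_to_stream(r_d1, dt)
  s_d2 <- raster_to_stream(r_d2, dt)

  kern_stn <- build_lateral_kernel("STN", cfg$DA, A = cfg$A_STN,
                                   nlat = cfg$nlat_STN,
                                   mapping = cfg$lateral_mapping,
                                   r_s = cfg$r_s, r_g = cfg$r_g,
                                   cD21 = cfg$cD21)
  kern_gpe <- build_lateral_kernel("GPe", cfg$DA, A = cfg$A_GPe,
                                   nlat = cfg$nlat_GPe,
                                   mapping = cfg$lateral_mapping,
                                   r_s = cfg$r_s, r_g = cfg$r_g,
                                   cD21 = cfg$cD21)
  s_amp <- if (cfg$spike_amplitude == "density") 1 / dt else 1
  pars <- function(l) unlist(l$params[c("a", "b", "c", "d", "v_peak", "I_ext")])

  out <- cpp_run_circuit(
    n, n_steps, dt,
    pars(stn), pars(gpe), pars(gpi),
    cfg$E_AMPA, cfg$E_NMDA, cfg$E_GABA, cfg$Mg,
    cfg$tau_AMPA, cfg$tau_NMDA, cfg$tau_GABA, cfg$tau_NMDA_GPi,
    da_scaled_weight(cfg$w_sg, cfg$DA, cfg$cd2),
    da_scaled_weight(cfg$w_gs, cfg$DA, cfg$cd2),
    cfg$w_stn_gpi, cfg$w_strd1_gpi, cfg$w_strd2_gpe,
    striatal_gain(cfg$DA, "D1", A_D1 = cfg$A_D1, lambda_str = cfg$lambda_str),
    striatal_gain(cfg$DA, "D2", A_D2 = cfg$A_D2, lambda_str = cfg$lambda_str),
    kern_stn$g1d, kern_stn$hw, kern_stn$A,
    kern_gpe$g1d, kern_gpe$hw, kern_gpe$A,
    s_amp,
    s_d1$step, s_d1$id, s_d2$step, s_d2$id,
    as.vector(stn$v), as.vector(stn$u),
    as.vector(gpe$v), as.vector(gpe$u),
    as.vector(gpi$v), as.vector(gpi$u),
    alive, isTRUE(cfg$ip_removed),
    max(1L, as.integer(round(cfg$delay_ms / dt))),
    identical(cfg$boundary, "wrap"), h0)

  structure(list(
    stn = raster_from_engine(out$stn_id, out$stn_step, dt, cfg$duration, N),
    gpe = raster_from_engine(out$gpe_id, out$gpe_step, dt, cfg$duration, N),
    gpi = raster_from_engine(out$gpi_id, out$gpi_step, dt, cfg$duration, N),
    str_d1 = r_d1, str_d2 = r_d2,
    state = list(v_stn = out$v_stn, u_stn = out$u_stn,
                 v_gpe = out$v_gpe, u_gpe = out$u_gpe,
                 v_gpi = out$v_gpi, u_gpi = out$u_gpi,
                 h = out$h_final),
    config = cfg), class = "bg_sim")
}

#' @export
print.bg_sim <- function(x, ...) {
  cat(sprintf("<bg_sim> %dx%d, %g ms at DA = %g\n",
              x$config$shape, x$config$shape, x$config$duration,
              x$config$DA))
  for (nm in c("stn", "gpe", "gpi"))
    cat(sprintf("  %s: %d spikes (%.1f Hz)\n", toupper(nm),
                nrow(x[[nm]]$events), mean_firing_rate(x[[nm]])))
  invisible(x)
}

#' @export
summary.bg_sim <- function(object, ...) {
  cfg <- object$config
  win <- c(cfg$burn_in, cfg$duration)
  alive_stn <- if (is.null(cfg$stn_alive)) NULL else sum(cfg$stn_alive)
  qt <- seq(cfg$burn_in, cfg$duration, by = 1)
  res <- list(
    DA = cfg$DA,
    rate_stn = mean_firing_rate(object$stn, win, n_alive = alive_stn),
    rate_gpe = mean_firing_rate(object$gpe, win),
    rate_gpi = mean_firing_rate(object$gpi, win),
    R_stn = mean_r_sync(object$stn, qt),
    R_gpe = mean_r_sync(object$gpe, qt),
    R_joint = mean_r_sync(merge_rasters(object$stn, object$gpe), qt))
  class(res) <- "summary.bg_sim"
  res
}

#' @export
print.summary.bg_sim <- function(x, ...) {
  cat(sprintf("DA = %.2f | rates (Hz): STN %.1f, GPe %.1f, GPi %.1f\n",
              x$DA, x$rate_stn, x$rate_gpe, x$rate_gpi))
  cat(sprintf("R_sync: STN %.3f, GPe %.3f, joint %.3f\n",
              x$R_stn, x$R_gpe, x$R_joint))
  invisible(x)
}

#' @export
plot.bg_sim <- function(x, which = c("stn", "gpe", "gpi"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in which)
    plot(x[[nm]], main = toupper(nm), ...)
  invisible(x)
}

# internal: stack two rasters into one population (for the joint
# STN-union-GPe order parameter)
merge_rasters <- function(a, b) {
  ev <- rbind(a$events,
              data.frame(neuron = b$events$neuron + a$n_neurons,
                         time_ms = b$events$time_ms))
  spike_raster(ev, max(a$duration, b$duration), a$n_neurons + b$n_neurons)
}
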