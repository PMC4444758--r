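#' Receptor channel parameters
#'
#' Decay time constants and reversal potentials of the three receptor
#' channels used in the circuit. NMDA synapses onto GPi decay with
#' tau = 67 ms instead of the 160 ms used elsewhere.
#'
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA"`.
#' @param target optional target nucleus; `"GPi"` selects the faster NMDA
#'   decay constant.
#' @return list with `kind`, `tau` (ms) and `E_rev` (mV).
#' @export
receptor_params <- function(kind = c("AMPA", "NMDA", "GABA"), target = NULL) {
  kind <- match.arg(kind)
  tau <- switch(kind, AMPA = 6, GABA = 4,
                NMDA = if (identical(target, "GPi")) 67 else 160)
  E <- switch(kind, AMPA = 0, NMDA = 0, GABA = -60)
  list(kind = kind, tau = tau, E_rev = E)
}

#' Update a synaptic gating field
#'
#' Forward-Euler step of `tau * dh/dt = -h + S` where the presynaptic spike
#' train `S` enters as an impulse on the step it occurs. With the default
#' `"density"` convention the impulse amplitude is `1/dt`, so each spike
#' raises `h` by `1/tau` and the stationary mean of `h` equals the
#' presynaptic rate in spikes/ms, independently of `dt`. The alternative
#' `"unit"` convention (amplitude 1, increment `dt/tau` per spike) makes
#' the synaptic drive vanish as `dt -> 0` and is kept only for comparison.
#'
#' @param h gating field (matrix or vector), non-negative.
#' @param presyn_spikes binary field of the same shape (1 where the
#'   presynaptic neuron spiked on this step).
#' @param tau receptor decay constant, ms.
#' @param dt time step, ms.
#' @param amplitude `"density"` (default) or `"unit"`.
#' @return updated gating field.
#' @export
update_gating <- function(h, presyn_spikes, tau, dt,
                          amplitude = c("density", "unit")) {
  stopifnot(dt > 0, tau > 0)
  amplitude <- match.arg(amplitude)
  amp <- if (amplitude == "density") 1 / dt else 1
  h + dt * (-h + amp * presyn_spikes) / tau
}

#' Voltage-dependent magnesium block of NMDA channels
#'
#' `B(V) = 1 / (1 + (Mg / 3.57) * exp(-0.062 V))`, the standard
#' Jahr-Stevens form. Strictly increasing in `V`, with values in (0, 1).
#'
#' @param V membrane potential (mV), scalar or field.
#' @param Mg magnesium concentration (default 1).
#' @export
mg_block <- function(V, Mg = 1) {
  stopifnot(Mg > 0)
  1 / (1 + (Mg / 3.57) * exp(-0.062 * V))
}

#' Postsynaptic receptor current
#'
#' `I = gain * W * h * (E_rev - V)`; for NMDA receptors the magnesium
#' block [mg_block()] multiplies the current.
#'
#' @param h gating field.
#' @param V_post postsynaptic membrane potential field (mV).
#' @param receptor a list from [receptor_params()].
#' @param W scalar synaptic weight of the projection.
#' @param gain extra scalar gain (e.g. the dopamine-dependent striatal
#'   gains cD1/cD2).
#' @param Mg magnesium concentration used when `receptor$kind == "NMDA"`.
#' @export
receptor_current <- function(h, V_post, receptor, W = 1, gain = 1, Mg = 1) {
  I <- gain * W * h * (receptor$E_rev - V_post)
  if (receptor$kind == "NMDA") I <- I * mg_block(V_post, Mg)
  I
}

#' Dopamine-scaled projection weight for the STN-GPe loop
#'
#' The reciprocal STN to GPe and GPe to STN weights are linearly attenuated
#' by dopamine: `W = (1 - cd2 * DA) * w`.
#'
#' @param base_w base synaptic weight.
#' @param DA dopamine level in `[0.1, 0.9]` (0 is admitted as the identity
#'   limit).
#' @param cd2 attenuation coefficient (default 0.1).
#' @export
da_scaled_weight <- function(base_w, DA, cd2 = 0.1) {
  stopifnot(DA >= 0, DA <= 1)
  (1 - cd2 * DA) * base_w
}

#' Dopamine gains of the striatal projections
#'
#' Sigmoidal gains applied to the GABAergic currents from D1 striatum onto
#' GPi and D2 striatum onto GPe:
#' `cD1 = A_D1 / (1 + exp(-lambda * (DA - 1)))` (increasing in DA, direct
#' pathway facilitated by dopamine) and
#' `cD2 = A_D2 / (1 + exp(lambda * DA))` (decreasing in DA, indirect
#' pathway suppressed by dopamine).
#'
#' @param DA dopamine level.
#' @param branch `"D1"` or `"D2"`.
#' @param A_D1,A_D2 sigmoid amplitudes.
#' @param lambda_str sigmoid slope.
#' @export
striatal_gain <- function(DA, branch = c("D1", "D2"), A_D1 = 10, A_D2 = 7.5,
                          lambda_str = 7.5) {
  branch <- match.arg(branch)
  if (branch == "D1") A_D1 / (1 + exp(-lambda_str * (DA - 1)))
  else A_D2 / (1 + exp(lambda_str * DA))
}

#' Dopamine-dependent width of the lateral Gaussian kernels
#'
#' Maps the dopamine level to the width `R_m` of the within-nucleus
#' Gaussian stencil `w = A_m * exp(-d^2 / R_m^2)`. Three named strategies
#' are provided:
#'
#' * `"default"`: linear interpolation of the kernel width between
#'   calibrated endpoints, `R_s = r_s * (1.04375 - 0.4375 * DA)` (width
#'   1.0 at DA 0.1, 0.65 at DA 0.9) and `R_g = r_g * (6.475 - 4.75 * DA)`
#'   (width 3.0 at DA 0.1, 1.1 at DA 0.9). Both kernel widths shrink with
#'   dopamine: at low dopamine the wide, strong GPe lateral inhibition
#'   (together with the synaptic transmission delay) locks the GPe lattice
#'   into globally synchronized inhibition volleys that entrain STN, while
#'   at high dopamine the narrow kernels leave both lattices in a fast
#'   asynchronous state. The two endpoint widths (STN 1.0/0.6, GPe
#'   3.0/1.1 at DA 0.1/0.9) were calibrated once so that the free-running
#'   loop reproduces the reported dopamine dependence of synchrony and of
#'   the STN/GPe firing rates; see the methods vignette.
#' * `"swap_cd21"`: `R_s = r_s * (1 - cD21 * DA)`,
#'   `R_g = r_g * (cD21 * DA + floor)`. Same monotonic directions driven
#'   by the weak coupling constant `cD21`; the resulting modulation is
#'   too shallow to desynchronize the lattice but is kept as a named
#'   strategy.
#' * `"as_printed"`: `R_s = r_s * cD21 * DA`, `R_g = r_g * (1 - cD21 * DA)`
#'   (directions opposite to the observed dopamine-synchrony relation;
#'   kept for comparison).
#'
#' @param nucleus `"STN"` or `"GPe"`.
#' @param DA dopamine level in `[0.1, 0.9]`.
#' @param mapping strategy name.
#' @param r_s,r_g base radii of the STN and GPe Gaussians.
#' @param cD21 dopamine coupling constant of the printed mapping.
#' @param floor lower guard preventing a degenerate zero radius.
#' @return the kernel width `R_m` (> 0).
#' @export
lateral_radius <- function(nucleus = c("STN", "GPe"), DA,
                           mapping = c("default", "swap_cd21", "as_printed"),
                           r_s = 1, r_g = 0.5, cD21 = 0.1, floor = 0.05) {
  nucleus <- match.arg(nucleus)
  mapping <- match.arg(mapping)
  stopifnot(DA >= 0, DA <= 1)
  R <- switch(mapping,
    default = if (nucleus == "STN") r_s * (1.04375 - 0.4375 * DA)
              else r_g * (6.475 - 4.75 * DA),
    swap_cd21 = if (nucleus == "STN") r_s * (1 - cD21 * DA)
                else r_g * (cD21 * DA + floor),
    as_printed = if (nucleus == "STN") r_s * (cD21 * DA)
                 else r_g * (1 - cD21 * DA))
  if (R <= 0) stop("lateral kernel mapping produced a non-positive radius")
  R
}

#' Build a dopamine-modulated lateral kernel
#'
#' Gaussian weight stencil `w(d) = A_m * exp(-d^2 / R_m^2)` over a square
#' neighborhood (`nlat x nlat`, 5 for STN and 11 for GPe), with the self
#' term (d = 0) excluded. At the lattice edge the stencil is clipped (no
#' wraparound).
#'
#' @inheritParams lateral_radius
#' @param A amplitude of the lateral synapse (defaults: 0.2 for STN, 1 for
#'   GPe).
#' @param nlat stencil side length (odd; defaults: 5 for STN, 11 for GPe).
#' @param ... passed to [lateral_radius()].
#' @return list of class `lateral_kernel` with the stencil matrix
#'   `weights` (self term zero), the 1-D Gaussian factor `g1d`, half-width
#'   `hw`, amplitude `A`, radius `R` and `nucleus`.
#' @export
build_lateral_kernel <- function(nucleus = c("STN", "GPe"), DA,
                                 A = NULL, nlat = NULL, ...) {
  nucleus <- match.arg(nucleus)
  if (is.null(A)) A <- if (nucleus == "STN") 0.2 else 1
  if (is.null(nlat)) nlat <- if (nucleus == "STN") 5L else 11L
  stopifnot(nlat %% 2 == 1)
  R <- lateral_radius(nucleus, DA, ...)
  hw <- (nlat - 1L) %/% 2L
  d <- -hw:hw
  g1d <- exp(-d^2 / R^2)
  W <- A * outer(g1d, g1d)
  W[hw + 1L, hw + 1L] <- 0
  structure(list(nucleus = nucleus, weights = W, g1d = g1d, hw = hw,
                 A = A, R = R, DA = DA),
            class = "lateral_kernel")
}

#' @export
print.lateral_kernel <- function(x, ...) {
  cat(sprintf("<lateral_kernel> %s, %dx%d stencil, A = %g, R = %.3f, sum(w) = %.3f\n",
              x$nucleus, 2 * x$hw + 1, 2 * x$hw + 1, x$A, x$R,
              sum(x$weights)))
  invisible(x)
}

#' Lateral (collateral) synaptic current
#'
#' Convolves the presynaptic gating field with the kernel stencil and
#' multiplies by the postsynaptic driving force:
#' `I_ij = [B(V_ij)] * sum_pq w_(ij,pq) h_pq * (E - V_ij)`. The magnesium
#' block applies only to NMDA collaterals (STN); GABAergic collaterals
#' (GPe) are unblocked.
#'
#' @param kernel a `lateral_kernel`.
#' @param h_field presynaptic gating matrix (lattice-shaped).
#' @param V_field postsynaptic membrane potential matrix.
#' @param receptor list from [receptor_params()].
#' @param Mg magnesium concentration for the NMDA block.
#' @param boundary `"wrap"` (toroidal lattice, the default) or `"clip"`
#'   (stencils truncated at the edge).
#' @return current matrix.
#' @export
lateral_current <- function(kernel, h_field, V_field, receptor, Mg = 1,
                            boundary = c("wrap", "clip")) {
  stopifnot(inherits(kernel, "lateral_kernel"),
            identical(dim(h_field), dim(V_field)))
  boundary <- match.arg(boundary)
  n <- nrow(h_field); m <- ncol(h_field)
  hw <- kernel$hw
  acc <- matrix(0, n, m)
  for (di in -hw:hw) {
    for (dj in -hw:hw) {
      w <- kernel$weights[di + hw + 1L, dj + hw + 1L]
      if (w == 0) next
      if (boundary == "wrap") {
        si <- 1L + (seq_len(n) - 1L + di) %% n
        sj <- 1L + (seq_len(m) - 1L + dj) %% m
        acc <- acc + w * h_field[si, sj]
      } else {
        si <- max(1, 1 + di):min(n, n + di)    # source rows
        ti <- si - di                          # target rows
        sj <- max(1, 1 + dj):min(m, m + dj)
        tj <- sj - dj
        acc[ti, tj] <- acc[ti, tj] + w * h_field[si, sj]
      }
    }
  }
  I <- acc * (receptor$E_rev - V_field)
  if (receptor$kind == "NMDA") I <- I * mg_block(V_field, Mg)
  I
}

#' Assemble the total synaptic current of one nucleus
#'
#' Combines the projection and collateral currents received by a nucleus
#' for one integration step, mirroring the wiring of the circuit: GPe
#' receives its own GABAergic laterals, one-to-one AMPA+NMDA drive from
#' STN, and D2-striatal GABA scaled by the gain `cD2`; STN receives
#' one-to-one GABA from GPe and its own AMPA+NMDA collaterals; GPi
#' receives one-to-one AMPA+NMDA from STN (NMDA with tau = 67 ms) and
#' D1-striatal GABA scaled by `cD1`. With `ip_removed = TRUE` both STN
#' terms onto GPi are omitted, leaving the direct-pathway current only.
#'
#' All inter-nucleus projections are one-to-one by lattice index, so every
#' gating field has the lattice shape.
#'
#' @param nucleus `"STN"`, `"GPe"` or `"GPi"`.
#' @param h named list of gating fields: `stn_ampa`, `stn_nmda`
#'   (tau 160), `stn_nmda_gpi` (tau 67), `gpe_gaba`, `strd1`, `strd2`
#'   (present as required by the nucleus).
#' @param V postsynaptic membrane potential matrix.
#' @param DA dopamine level.
#' @param config a [circuit_config()] supplying weights and kernels.
#' @param kernels optional named list `list(STN = , GPe = )` of prebuilt
#'   lateral kernels (rebuilt from `config` when missing).
#' @param ip_removed omit the STN projection onto GPi.
#' @return current matrix for the nucleus.
#' @export
assemble_currents <- function(nucleus = c("STN", "GPe", "GPi"), h, V, DA,
                              config, kernels = NULL, ip_removed = FALSE) {
  nucleus <- match.arg(nucleus)
  cfg <- config
  Mg <- cfg$Mg
  bnd <- if (is.null(cfg$boundary)) "wrap" else cfg$boundary
  if (is.null(kernels))
    kernels <- list(
      STN = build_lateral_kernel("STN", DA, A = cfg$A_STN, nlat = cfg$nlat_STN,
                                 mapping = cfg$lateral_mapping,
                                 r_s = cfg$r_s, r_g = cfg$r_g, cD21 = cfg$cD21),
      GPe = build_lateral_kernel("GPe", DA, A = cfg$A_GPe, nlat = cfg$nlat_GPe,
                                 mapping = cfg$lateral_mapping,
                                 r_s = cfg$r_s, r_g = cfg$r_g, cD21 = cfg$cD21))
  ampa <- receptor_params("AMPA"); nmda <- receptor_params("NMDA")
  gaba <- receptor_params("GABA"); nmda_gpi <- receptor_params("NMDA", "GPi")
  switch(nucleus,
    GPe = {
      w_sg <- da_scaled_weight(cfg$w_sg, DA, cfg$cd2)
      lateral_current(kernels$GPe, h$gpe_gaba, V, gaba, Mg, bnd) +
        receptor_current(h$stn_ampa, V, ampa, W = w_sg, Mg = Mg) +
        receptor_current(h$stn_nmda, V, nmda, W = w_sg, Mg = Mg) +
        receptor_current(h$strd2, V, gaba, W = cfg$w_strd2_gpe,
                         gain = striatal_gain(DA, "D2", cfg$A_D2,
                                              lambda_str = cfg$lambda_str))
    },
    STN = {
      w_gs <- da_scaled_weight(cfg$w_gs, DA, cfg$cd2)
      receptor_current(h$gpe_gaba, V, gaba, W = w_gs, Mg = Mg) +
        lateral_current(kernels$STN, h$stn_ampa, V, ampa, Mg, bnd) +
        lateral_current(kernels$STN, h$stn_nmda, V, nmda, Mg, bnd)
    },
    GPi = {
      I <- receptor_current(h$strd1, V, gaba, W = cfg$w_strd1_gpi,
                            gain = striatal_gain(DA, "D1", A_D1 = cfg$A_D1,
                                                 lambda_str = cfg$lambda_str))
      if (!ip_removed)
        I <- I + receptor_current(h$stn_ampa, V, ampa, W = cfg$w_stn_gpi,
                                  Mg = Mg) +
             receptor_current(h$stn_nmda_gpi, V, nmda_gpi, W = cfg$w_stn_gpi,
                              Mg = Mg)
      I
    })
}
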