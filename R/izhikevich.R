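#' Izhikevich parameter presets for the basal ganglia nuclei
#'
#' Returns the two-variable Izhikevich model parameters used for the three
#' modeled nuclei. STN is a slowly-recovering, rebound-capable cell
#' (a = 0.005, b = 0.265); GPe and GPi are tonically spiking cells
#' (a = 0.1, b = 0.2). The constant external drive `I_ext` sets the
#' autonomous firing rate of each nucleus (STN 30, GPe/GPi 10, in the
#' dimensionless current convention of the Izhikevich model).
#'
#' @param preset one of `"STN"`, `"GPe"`, `"GPi"`.
#' @return A list with fields `a`, `b`, `c`, `d`, `v_peak`, `I_ext`.
#' @examples
#' izhikevich_params("STN")
#' @export
izhikevich_params <- function(preset = c("STN", "GPe", "GPi")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    STN = list(a = 0.005, b = 0.265, c = -65, d = 1.5, I_ext = 30),
    GPe = list(a = 0.1,   b = 0.2,   c = -65, d = 2,   I_ext = 10),
    GPi = list(a = 0.1,   b = 0.2,   c = -65, d = 2,   I_ext = 10))
  p$v_peak <- 30
  p$preset <- preset
  p[c("a", "b", "c", "d", "v_peak", "I_ext", "preset")]
}

#' Initialize a 2D lattice of Izhikevich neurons
#'
#' Membrane potentials start at the reset value `c` plus a small uniform
#' jitter `U(0, jitter)` mV that breaks the symmetry of the otherwise
#' identical neurons; the recovery variable starts on its nullcline,
#' `u = b * v`. With zero jitter all neurons are identical and, under
#' identical input, spike in perfect unison forever.
#'
#' @param preset nucleus name passed to [izhikevich_params()].
#' @param shape integer lattice side `n` (the lattice is `n x n`) or a
#'   length-2 vector `c(nrow, ncol)` with `nrow == ncol`.
#' @param seed optional integer seed; when given, initialization is
#'   deterministic.
#' @param jitter amplitude (mV) of the uniform initial-condition jitter.
#' @return A list of class `neuron_lattice` with fields `shape`, `v`, `u`
#'   (matrices), `params`, `alive_mask`.
#' @export
init_lattice <- function(preset, shape = 50, seed = NULL, jitter = 5) {
  params <- izhikevich_params(preset)
  if (length(shape) == 2L) {
    stopifnot(shape[1] == shape[2])
    shape <- shape[1]
  }
  n <- as.integer(shape)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(params$c + stats::runif(n * n, 0, jitter), n, n)
  u <- params$b * v
  structure(list(shape = c(n, n), v = v, u = u, params = params,
                 alive_mask = matrix(TRUE, n, n)),
            class = "neuron_lattice")
}

#' @export
print.neuron_lattice <- function(x, ...) {
  cat(sprintf("<neuron_lattice> %dx%d %s neurons (%d lesioned)\n",
              x$shape[1], x$shape[2], x$params$preset, sum(!x$alive_mask)))
  invisible(x)
}

#' Advance an Izhikevich lattice by one forward-Euler step
#'
#' Integrates `dv/dt = 0.04 v^2 + 5 v - u + 140 + I_ext + I_syn` and
#' `du/dt = a (b v - u)` for every live neuron, then applies the spike
#' rule: neurons whose updated `v` reaches `v_peak` are recorded as
#' spiking and reset (`v <- c`, `u <- u + d`). Lesioned neurons (where
#' `alive_mask` is `FALSE`) are untouched and never spike.
#'
#' @param lattice a `neuron_lattice`.
#' @param I_syn synaptic current, a matrix matching the lattice shape (or a
#'   scalar).
#' @param dt time step in ms.
#' @return A list with the updated `lattice` and a logical matrix `spikes`.
#' @examples
#' lat <- init_lattice("GPe", shape = 1, jitter = 0)
#' step_lattice(lat, I_syn = 0, dt = 1)$lattice$v  # -65 -> -58
#' @export
step_lattice <- function(lattice, I_syn, dt) {
  stopifnot(inherits(lattice, "neuron_lattice"), dt > 0)
  p <- lattice$params
  v <- lattice$v; u <- lattice$u
  if (length(I_syn) == 1L) I_syn <- matrix(I_syn, nrow(v), ncol(v))
  stopifnot(identical(dim(I_syn), dim(v)))
  alive <- lattice$alive_mask
  vn <- v + dt * (0.04 * v^2 + 5 * v - u + 140 + p$I_ext + I_syn)
  un <- u + dt * p$a * (p$b * v - u)
  spikes <- alive & (vn >= p$v_peak)
  vn[spikes] <- p$c
  un[spikes] <- un[spikes] + p$d
  vn[!alive] <- v[!alive]
  un[!alive] <- u[!alive]
  if (any(!is.finite(vn[alive])) || any(!is.finite(un[alive])))
    stop(sprintf("numerical blow-up in lattice update at dt = %g ms", dt))
  lattice$v <- vn; lattice$u <- un
  list(lattice = lattice, spikes = spikes)
}

#' Firing rate versus injected current for a neuron preset
#'
#' Runs one isolated neuron per current value (no synaptic input, no
#' lateral coupling) and reports the mean firing rate over the run. The
#' rate is non-decreasing in the injected current over the physiological
#' range for all three presets.
#'
#' @param preset nucleus name.
#' @param I_values numeric vector of total injected currents (replacing the
#'   preset's `I_ext`).
#' @param duration run length in ms (>= 500 recommended).
#' @param dt integration step, ms.
#' @param burn_in initial interval (ms) excluded from the rate.
#' @return data frame with columns `I` and `rate_hz`.
#' @export
characterize_fi <- function(preset, I_values, duration = 1000, dt = 0.1,
                            burn_in = 100) {
  stopifnot(duration >= 500)
  params <- izhikevich_params(preset)
  rates <- vapply(I_values, function(I) {
    v <- params$c; u <- params$b * v
    n_steps <- round(duration / dt)
    count <- 0L
    for (t in seq_len(n_steps)) {
      vn <- v + dt * (0.04 * v^2 + 5 * v - u + 140 + I)
      un <- u + dt * params$a * (params$b * v - u)
      if (vn >= params$v_peak) {
        if (t * dt > burn_in) count <- count + 1L
        vn <- params$c; un <- un + params$d
      }
      v <- vn; u <- un
    }
    count / ((duration - burn_in) / 1000)
  }, numeric(1))
  data.frame(I = I_values, rate_hz = rates)
}

# internal: simulate one neuron with an arbitrary current trace, returning
# spike times in ms; used for rebound and reference checks
simulate_neuron <- function(params, I_trace, dt) {
  v <- params$c; u <- params$b * v
  times <- numeric(0)
  for (t in seq_along(I_trace)) {
    vn <- v + dt * (0.04 * v^2 + 5 * v - u + 140 + I_trace[t])
    un <- u + dt * params$a * (params$b * v - u)
    if (vn >= params$v_peak) {
      times <- c(times, t * dt)
      vn <- params$c; un <- un + params$d
    }
    v <- vn; u <- un
  }
  times
}
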