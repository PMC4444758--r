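#' Striatal Poisson spike pools
#'
#' The striatum is not modeled at the membrane level: each of the D1 and
#' D2 populations is a pool of Poisson spike sources on the same lattice
#' as the target nucleus (D1 projects one-to-one onto GPi, D2 onto GPe).
#' A pool is described by a sequence of epochs; within an epoch the
#' neurons are partitioned into correlation groups, each group sharing a
#' single Poisson train at its own rate (a singleton group is an
#' independent, uncorrelated train).
#'
#' @param branch `"D1"` or `"D2"`.
#' @param shape lattice side `n` (pool has `n^2` neurons).
#' @param epochs list of epochs, each a list with numeric `from`, `to`
#'   (ms), `groups` (list of integer vectors partitioning `1:n^2`) and
#'   `rates` (Hz, one per group). `groups = NULL` means all-singleton
#'   (uncorrelated) with a single shared rate.
#' @return object of class `striatal_pool`.
#' @export
striatal_pool <- function(branch = c("D1", "D2"), shape = 50, epochs) {
  branch <- match.arg(branch)
  n <- as.integer(if (length(shape) == 2L) shape[1] else shape)
  structure(list(branch = branch, shape = c(n, n), n_neurons = n * n,
                 epochs = epochs),
            class = "striatal_pool")
}

#' @export
print.striatal_pool <- function(x, ...) {
  cat(sprintf("<striatal_pool> %s, %d neurons, %d epochs\n",
              x$branch, x$n_neurons, length(x$epochs)))
  invisible(x)
}

#' Generate Poisson spikes from a striatal pool
#'
#' Spikes are drawn per integration step as Bernoulli events with
#' probability `rate * dt` (requiring `rate * dt < 0.1` for thinning
#' validity); all members of a correlation group receive copies of the
#' same train. Uses the current R random number stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param pool a [striatal_pool()].
#' @param duration total duration, ms.
#' @param dt time step, ms.
#' @return a [spike_raster()].
#' @export
generate_poisson <- function(pool, duration, dt) {
  stopifnot(inherits(pool, "striatal_pool"), dt > 0)
  n_steps <- round(duration / dt)
  neuron <- integer(0); step <- integer(0)
  for (ep in pool$epochs) {
    s0 <- round(ep$from / dt); s1 <- min(round(ep$to / dt), n_steps)
    if (s1 <= s0) next
    len <- s1 - s0
    groups <- ep$groups
    rates <- ep$rates
    if (is.null(groups)) {          # uncorrelated: singleton per neuron
      p <- rates[1] * dt / 1000
      if (p >= 0.1) stop("rate * dt too large for Bernoulli thinning")
      counts <- stats::rbinom(pool$n_neurons, len, p)
      tot <- sum(counts)
      if (tot > 0) {
        neuron <- c(neuron, rep.int(seq_len(pool$n_neurons), counts))
        step <- c(step, s0 + unlist(lapply(counts[counts > 0], function(k)
          sort(sample.int(len, k))), use.names = FALSE))
      }
    } else {
      stopifnot(length(groups) == length(rates))
      for (g in seq_along(groups)) {
        p <- rates[g] * dt / 1000
        if (p >= 0.1) stop("rate * dt too large for Bernoulli thinning")
        k <- stats::rbinom(1, len, p)
        if (k == 0) next
        st <- s0 + sort(sample.int(len, k))
        members <- groups[[g]]
        neuron <- c(neuron, rep(members, each = k))
        step <- c(step, rep(st, times = length(members)))
      }
    }
  }
  spike_raster(data.frame(neuron = neuron, time_ms = (step - 0.5) * dt),
               duration = duration, n_neurons = pool$n_neurons)
}

#' Partition a lattice into competing pools
#'
#' For two stimuli the lattice is split into halves by flattened index
#' (columns 1..n/2 versus the rest in column-major order); for four, into
#' spatial quadrants. The same partition is applied to the striatal input
#' pools and to the GPi readout pools of the race model.
#'
#' @param n lattice side.
#' @param k number of pools (2 or 4).
#' @return list of `k` integer vectors partitioning `1:n^2`.
#' @export
lattice_pools <- function(n, k) {
  N <- n * n
  idx <- matrix(seq_len(N), n, n)
  if (k == 2L) {
    half <- n %/% 2
    list(as.vector(idx[, 1:half]), as.vector(idx[, (half + 1):n]))
  } else if (k == 4L) {
    h <- n %/% 2
    list(as.vector(idx[1:h, 1:h]), as.vector(idx[(h + 1):n, 1:h]),
         as.vector(idx[1:h, (h + 1):n]), as.vector(idx[(h + 1):n, (h + 1):n]))
  } else stop("k must be 2 or 4")
}

#' Striatal input layout for the binary action selection task
#'
#' Outside the stimulus window every striatal neuron fires an uncorrelated
#' background train (1 Hz). During the window the first half of the
#' lattice carries stimulus #1 and the second half stimulus #2, each half
#' being one fully correlated group at its stimulus rate. The D1 and D2
#' pools are independent Poisson realizations of the same layout.
#'
#' @param f1,f2 stimulus rates in Hz (stimulus #2 is the more salient by
#'   default).
#' @param window stimulus interval `c(on, off)` in ms.
#' @param background background rate, Hz.
#' @param trial_ms trial duration, ms.
#' @param shape lattice side.
#' @return list with pools `D1`, `D2` and the `saliences` vector
#'   `c(f1, f2)`.
#' @export
binary_stimulus_layout <- function(f1 = 4, f2 = 8, window = c(100, 200),
                                   background = 1, trial_ms = 250,
                                   shape = 50) {
  stopifnot(window[1] >= 0, window[2] <= trial_ms, f1 != f2)
  n <- if (length(shape) == 2L) shape[1] else shape
  pools <- lattice_pools(n, 2L)
  epochs <- list(
    list(from = 0, to = window[1], groups = NULL, rates = background),
    list(from = window[1], to = window[2], groups = pools,
         rates = c(f1, f2)),
    list(from = window[2], to = trial_ms, groups = NULL, rates = background))
  list(D1 = striatal_pool("D1", n, epochs),
       D2 = striatal_pool("D2", n, epochs),
       saliences = c(f1, f2))
}

#' Striatal input layout for the n-armed bandit task
#'
#' Each lattice quadrant carries one arm; during the stimulus window the
#' quadrant fires as one fully correlated group at a rate given by the
#' cortico-striatal weight through `rate_map` (default `w / 10` Hz, which
#' keeps initial weights of 50 at a physiological 5 Hz). Weights outside
#' `[0, 100]` are clipped with a warning.
#'
#' @param w_d1,w_d2 length-4 cortico-striatal weight vectors.
#' @param rate_map function mapping a weight to a striatal rate in Hz.
#' @param window stimulus interval, ms.
#' @param background background rate, Hz.
#' @param trial_ms trial duration, ms.
#' @param shape lattice side.
#' @return list with pools `D1`, `D2`, the quadrant partition `pools` and
#'   the rate vectors `rates_d1`, `rates_d2`.
#' @export
bandit_stimulus_layout <- function(w_d1, w_d2, rate_map = function(w) w / 10,
                                   window = c(100, 200), background = 1,
                                   trial_ms = 250, shape = 50) {
  stopifnot(length(w_d1) == 4L, length(w_d2) == 4L)
  clip <- function(w) {
    if (any(w < 0 | w > 100)) {
      warning("cortico-striatal weight outside [0, 100]; clipped")
      w <- pmin(pmax(w, 0), 100)
    }
    w
  }
  w_d1 <- clip(w_d1); w_d2 <- clip(w_d2)
  n <- if (length(shape) == 2L) shape[1] else shape
  pools <- lattice_pools(n, 4L)
  mk <- function(w) list(
    list(from = 0, to = window[1], groups = NULL, rates = background),
    list(from = window[1], to = window[2], groups = pools,
         rates = vapply(w, rate_map, numeric(1))),
    list(from = window[2], to = trial_ms, groups = NULL, rates = background))
  list(D1 = striatal_pool("D1", n, mk(w_d1)),
       D2 = striatal_pool("D2", n, mk(w_d2)),
       pools = pools,
       rates_d1 = vapply(w_d1, rate_map, numeric(1)),
       rates_d2 = vapply(w_d2, rate_map, numeric(1)))
}

# internal: silent pool (no striatal drive at all)
silent_pool <- function(branch, shape)
  striatal_pool(branch, shape, epochs = list())

# internal: raster -> (0-based step, 0-based id) streams ordered by step
raster_to_stream <- function(raster, dt) {
  if (nrow(raster$events) == 0L)
    return(list(step = integer(0), id = integer(0)))
  stp <- as.integer(floor((raster$events$time_ms - 1e-9) / dt))
  o <- order(stp)
  list(step = stp[o], id = raster$events$neuron[o] - 1L)
}
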