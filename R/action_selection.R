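#' Pooled, normalized and reversed GPi rate series
#'
#' Partitions the GPi lattice into the competing pools, computes each
#' pool's mean spike rate per integration step smoothed over a trailing
#' window, and maps it through `f = (f_max - f') / f_max`, where `f_max`
#' is the largest smoothed pool rate at that time. Low GPi activity
#' (disinhibition) therefore yields a high drive `f`; the pool at the
#' maximum gets `f = 0`, a silent pool gets `f = 1`. When every pool is
#' silent in the window all drives are 0 (no evidence either way).
#'
#' @param gpi_raster GPi [spike_raster()].
#' @param pools list of integer vectors partitioning the lattice (see
#'   [lattice_pools()]).
#' @param dt integration step of the underlying simulation, ms.
#' @param window_ms trailing smoothing window, ms.
#' @return list with matrices `f` and `f_raw` (steps x k; `f_raw` in
#'   spikes per neuron per ms), and `times` (ms).
#' @export
gpi_pool_rates <- function(gpi_raster, pools, dt, window_ms = 10) {
  k <- length(pools)
  n_steps <- round(gpi_raster$duration / dt)
  stopifnot(sort(unlist(pools)) == seq_len(gpi_raster$n_neurons))
  pool_of <- integer(gpi_raster$n_neurons)
  for (i in seq_len(k)) pool_of[pools[[i]]] <- i
  ev <- gpi_raster$events
  stp <- pmin(n_steps, 1L + as.integer(floor((ev$time_ms - 1e-9) / dt)))
  raw <- matrix(0, n_steps, k)
  if (nrow(ev))
    for (i in seq_len(k)) {
      sel <- pool_of[ev$neuron] == i
      raw[, i] <- tabulate(stp[sel], n_steps) / length(pools[[i]]) / dt
    }
  w <- max(1L, round(window_ms / dt))
  sm <- apply(raw, 2, function(x) {
    cs <- cumsum(x)
    (cs - c(rep(0, w), utils::head(cs, -w))) / pmin(seq_along(x), w)
  })
  fmax <- apply(sm, 1, max)
  f <- (fmax - sm) / ifelse(fmax > 0, fmax, 1)
  list(f = f, f_raw = sm, times = seq_len(n_steps) * dt)
}

#' Race-model action selection
#'
#' Each competing stimulus accumulates evidence through a leaky
#' integrator `tau * dz/dt = -z + f(t)` starting at `z = 0`; the first
#' integrator to cross the threshold wins. No crossing by the end of the
#' input means no action (a No-Go). For constant `f` the closed form is
#' `z(t) = f * (1 - exp(-t / tau))`, so a unit input crosses the 0.15
#' threshold at `t = -tau * log(0.85)`.
#'
#' @param rate_series matrix (steps x k) of pool drives `f`, or a vector
#'   for a single accumulator.
#' @param dt step, ms.
#' @param tau integrator time constant, ms.
#' @param threshold decision threshold.
#' @return list with `winner` (pool index or `NA`), `t_cross` (ms or
#'   `NA`) and the integrator trace matrix `z`.
#' @export
race_integrate <- function(rate_series, dt, tau = 1, threshold = 0.15) {
  stopifnot(threshold > 0, dt > 0, tau > 0)
  f <- if (is.matrix(rate_series)) rate_series else cbind(rate_series)
  k <- ncol(f)
  z <- numeric(k)
  ztrace <- matrix(NA_real_, nrow(f), k)
  for (t in seq_len(nrow(f))) {
    z <- unname(z + dt * (-z + f[t, ]) / tau)
    ztrace[t, ] <- z
    if (any(z >= threshold)) {
      # exact ties (e.g. two simultaneously silent pools) break at random
      cand <- which(z >= max(z) - 1e-12)
      w <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
      return(list(winner = as.integer(w), t_cross = t * dt,
                  z = ztrace[seq_len(t), , drop = FALSE]))
    }
  }
  list(winner = NA_integer_, t_cross = NA_real_, z = ztrace)
}

#' Classify a race outcome
#'
#' Binary task: `"Go"` when the more salient stimulus wins, `"Explore"`
#' when the less salient one wins, `"NoGo"` when no accumulator crossed.
#' Bandit task (`true_means` given): `"exploit"` when the winning arm has
#' the highest current mean payoff, else `"explore"` (`"NoGo"` when
#' nothing crossed).
#'
#' @param winner pool index or `NA`.
#' @param saliences stimulus salience vector (must be distinct).
#' @param true_means optional true arm means for the bandit labeling.
#' @return character label.
#' @export
classify_outcome <- function(winner, saliences = NULL, true_means = NULL) {
  if (is.null(true_means)) {
    stopifnot(!is.null(saliences))
    if (anyDuplicated(saliences)) stop("saliences must be distinct")
    if (is.na(winner)) return("NoGo")
    if (winner == which.max(saliences)) "Go" else "Explore"
  } else {
    if (is.na(winner)) return("NoGo")
    if (winner == which.max(true_means)) "exploit" else "explore"
  }
}

#' Run one binary action selection trial
#'
#' A 250 ms trial with the two-stimulus striatal layout (stimulus #1 at
#' `f1` Hz to the first lattice half, stimulus #2 at `f2` Hz to the
#' second, both inside the 100-200 ms window, 1 Hz background
#' elsewhere). The race integrates the GPi half-pool drives from
#' stimulus onset to the end of the trial.
#'
#' @param config a [circuit_config()]; `duration` is forced to
#'   `trial_ms`.
#' @param f1,f2 stimulus saliences (Hz).
#' @param window stimulus window, ms.
#' @param trial_ms trial length, ms.
#' @param race_window_ms smoothing window of the GPi pool rates.
#' @param threshold race threshold.
#' @param tau race integrator time constant, ms.
#' @return list with `label`, `winner`, `t_cross`, the simulation
#'   object `sim` and the pool-rate object `rates`.
#' @export
run_binary_trial <- function(config, f1 = 4, f2 = 8, window = c(100, 200),
                             trial_ms = 250, race_window_ms = 10,
                             threshold = 0.15, tau = 1) {
  cfg <- config
  cfg$duration <- trial_ms
  lay <- binary_stimulus_layout(f1, f2, window, trial_ms = trial_ms,
                                shape = cfg$shape)
  sim <- run_circuit(cfg, lay[c("D1", "D2")])
  pools <- lattice_pools(cfg$shape, 2L)
  pr <- gpi_pool_rates(sim$gpi, pools, dt = cfg$dt,
                       window_ms = race_window_ms)
  steps <- pr$times > window[1]
  race <- race_integrate(pr$f[steps, , drop = FALSE], dt = cfg$dt,
                         tau = tau, threshold = threshold)
  t_cross <- if (is.na(race$t_cross)) NA_real_ else window[1] + race$t_cross
  list(label = classify_outcome(race$winner, saliences = c(f1, f2)),
       winner = race$winner, t_cross = t_cross, sim = sim, rates = pr)
}

#' Binary action selection task over dopamine levels
#'
#' Repeats independent binary trials (network state re-initialized each
#' trial) at each dopamine level and tabulates the fraction of Go,
#' Explore and No-Go outcomes. Increasing dopamine moves the circuit
#' from a No-Go-dominated regime through an exploratory regime (peaked
#' at intermediate dopamine, carried by alternating GPi pool bursts) to
#' a Go-dominated regime.
#'
#' @param config a [circuit_config()].
#' @param da_levels dopamine levels to test.
#' @param n_trials trials per level.
#' @param seed base seed; trial `i` at level `j` uses
#'   `seed + 1000 * j + i`.
#' @param ... passed to [run_binary_trial()].
#' @return list with `summary` (data frame: DA, go, explore, nogo
#'   fractions) and `records` (one row per trial).
#' @export
binary_task <- function(config, da_levels = seq(0.1, 0.9, by = 0.1),
                        n_trials = 100, seed = 1L, ...) {
  rec <- list()
  for (j in seq_along(da_levels)) {
    for (i in seq_len(n_trials)) {
      cfg <- config
      cfg$DA <- da_levels[j]
      cfg$seed <- as.integer(seed + 1000L * j + i)
      tr <- run_binary_trial(cfg, ...)
      rec[[length(rec) + 1L]] <-
        data.frame(DA = da_levels[j], trial = i, label = tr$label,
                   winner = ifelse(is.na(tr$winner), NA_integer_, tr$winner),
                   t_cross = tr$t_cross)
    }
  }
  records <- do.call(rbind, rec)
  agg <- do.call(rbind, lapply(split(records, records$DA), function(d)
    data.frame(DA = d$DA[1],
               go = mean(d$label == "Go"),
               explore = mean(d$label == "Explore"),
               nogo = mean(d$label == "NoGo"))))
  rownames(agg) <- NULL
  list(summary = agg, records = records)
}
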