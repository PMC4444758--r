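#' Spike phases by linear interpolation between spikes
#'
#' The phase of neuron `j` at query time `t` is
#' `2 * pi * (t - t_jk) / (t_jk+1 - t_jk)` where `t_jk` and `t_jk+1` are
#' the spikes bracketing `t`. A neuron is valid at `t` only when such a
#' bracketing pair exists (at least two spikes, with `t` inside the
#' interspike interval); silent or single-spike neurons are masked out
#' rather than assigned a phase.
#'
#' @param raster a [spike_raster()].
#' @param query_times numeric vector of times (ms) within the raster
#'   duration.
#' @return list with `phase` (n_neurons x n_times matrix, radians in
#'   `[0, 2*pi)`), `valid` (logical matrix) and `times`.
#' @export
spike_phases <- function(raster, query_times) {
  stopifnot(inherits(raster, "spike_raster"),
            all(query_times >= 0), all(query_times <= raster$duration))
  nt <- length(query_times)
  phase <- matrix(NA_real_, raster$n_neurons, nt)
  valid <- matrix(FALSE, raster$n_neurons, nt)
  ev <- raster$events
  spl <- split(ev$time_ms, ev$neuron)
  for (nm in names(spl)) {
    st <- spl[[nm]]
    if (length(st) < 2L) next
    j <- as.integer(nm)
    k <- findInterval(query_times, st)
    ok <- k >= 1L & k < length(st)
    if (!any(ok)) next
    t0 <- st[k[ok]]; t1 <- st[k[ok] + 1L]
    phase[j, ok] <- 2 * pi * (query_times[ok] - t0) / (t1 - t0)
    valid[j, ok] <- TRUE
  }
  list(phase = phase, valid = valid, times = query_times)
}

#' Kuramoto order parameter of spike phases
#'
#' `R(t) * exp(i * theta(t)) = mean_j exp(i * phase_j(t))` over the
#' neurons valid at `t`. `R = 1` for perfect synchrony; for `N` neurons
#' with independent uniform phases `E[R]` is approximately `1/sqrt(N)`.
#' Times with no valid neuron yield `NA` (flagged, not silently zero).
#'
#' @param phases result of [spike_phases()].
#' @return data frame with columns `time`, `R`, `theta`, `n_valid`.
#' @export
sync_order_parameter <- function(phases) {
  nt <- length(phases$times)
  R <- theta <- rep(NA_real_, nt)
  nv <- integer(nt)
  for (t in seq_len(nt)) {
    ph <- phases$phase[phases$valid[, t], t]
    nv[t] <- length(ph)
    if (nv[t] >= 1L) {
      z <- mean(exp(1i * ph))
      R[t] <- Mod(z); theta[t] <- Arg(z)
    }
  }
  data.frame(time = phases$times, R = R, theta = theta, n_valid = nv)
}

# internal: time-averaged R over a query grid (NA times dropped)
mean_r_sync <- function(raster, query_times) {
  s <- sync_order_parameter(spike_phases(raster, query_times))
  mean(s$R, na.rm = TRUE)
}

#' Population mean firing rate
#'
#' Total spike count in the window divided by the number of (live)
#' neurons and the window length: additive over disjoint windows.
#'
#' @param raster a [spike_raster()].
#' @param window `c(from, to)` in ms; defaults to the full duration.
#' @param n_alive number of live neurons (defaults to all; pass the
#'   unlesioned count when part of the population is silenced).
#' @return rate in Hz.
#' @export
mean_firing_rate <- function(raster, window = NULL, n_alive = NULL) {
  if (is.null(window)) window <- c(0, raster$duration)
  stopifnot(window[2] > window[1])
  if (is.null(n_alive)) n_alive <- raster$n_neurons
  k <- sum(raster$events$time_ms > window[1] &
             raster$events$time_ms <= window[2])
  k / n_alive / ((window[2] - window[1]) / 1000)
}

#' Dominant population oscillation frequency
#'
#' Bins the population spike count (1 ms bins), subtracts the mean, and
#' takes a modified-Daniell-smoothed periodogram (a raw periodogram's
#' in-band maximum exceeds any fixed multiple of the median even for
#' white noise, so smoothing is what makes a peak criterion meaningful).
#' Returns the frequency of the largest spectral peak within the band,
#' provided it exceeds 3x the median in-band spectral power (otherwise the peak
#' frequency is `NA`: no significant rhythm).
#'
#' @param raster a [spike_raster()] of duration >= 1000 ms.
#' @param band frequency band searched, Hz.
#' @param bin_ms bin width, ms.
#' @param window optional `c(from, to)` ms analysis window.
#' @return list with `frequency` (Hz or `NA`), `peak_power`,
#'   `median_power`, `significant`, and the `spectrum` data frame.
#' @export
population_oscillation_frequency <- function(raster, band = c(2, 30),
                                             bin_ms = 1, window = NULL) {
  if (is.null(window)) window <- c(0, raster$duration)
  stopifnot(diff(window) >= 1000)
  tm <- raster$events$time_ms
  tm <- tm[tm > window[1] & tm <= window[2]]
  nb <- floor(diff(window) / bin_ms)
  counts <- tabulate(pmin(nb, 1L + floor((tm - window[1]) / bin_ms)), nb)
  x <- counts - mean(counts)
  spec <- stats::spec.pgram(stats::ts(x, frequency = 1000 / bin_ms),
                            spans = c(9, 9), taper = 0, plot = FALSE,
                            detrend = FALSE)
  df <- data.frame(freq = spec$freq, power = spec$spec)
  inband <- df[df$freq >= band[1] & df$freq <= band[2], ]
  med <- stats::median(inband$power)
  if (nrow(inband) == 0L)
    return(list(frequency = NA_real_, peak_power = NA_real_,
                median_power = med, significant = FALSE, spectrum = df))
  i <- which.max(inband$power)
  sig <- inband$power[i] > 3 * med
  list(frequency = if (sig) inband$freq[i] else NA_real_,
       peak_frequency = inband$freq[i],
       peak_power = inband$power[i], median_power = med,
       significant = sig, spectrum = df)
}

#' Two-sample comparison of synchrony values
#'
#' Pooled-variance (classical independent two-sample) t-test between two
#' groups of per-trial mean synchrony values, as used to contrast
#' explore- versus exploit-trial synchrony.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @return list with group means and SDs, `t`, `df`, `p`, and a
#'   `degenerate` flag set when both groups have zero variance.
#' @export
compare_sync_groups <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
    res <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  c(list(mean_a = mean(a), mean_b = mean(b),
         sd_a = stats::sd(a), sd_b = stats::sd(b)),
    res, list(degenerate = degenerate))
}

#' Sweep dopamine and summarize circuit dynamics
#'
#' Runs the free-running STN-GPe protocol at each dopamine level and
#' tabulates post-burn-in synchrony (within STN, within GPe, and over the
#' pooled STN+GPe population), mean firing rates, and the dominant STN
#' population frequency.
#'
#' @param config a [circuit_config()] (its `DA` field is overridden).
#' @param da_values dopamine levels.
#' @param pools optional striatal pools (default silent).
#' @param seeds one or more seeds; metrics are averaged over them.
#' @return data frame, one row per dopamine level.
#' @export
sweep_da <- function(config, da_values = seq(0.1, 0.9, by = 0.1),
                     pools = NULL, seeds = config$seed) {
  rows <- lapply(da_values, function(da) {
    per_seed <- lapply(seeds, function(s) {
      cfg <- config; cfg$DA <- da; cfg$seed <- as.integer(s)
      sim <- run_circuit(cfg, pools)
      sm <- summary(sim)
      pk <- if (cfg$duration - cfg$burn_in >= 1000)
        population_oscillation_frequency(
          sim$stn, window = c(cfg$burn_in, cfg$duration))$peak_frequency
      else NA_real_
      c(R_STN = sm$R_stn, R_GPe = sm$R_gpe, R_joint = sm$R_joint,
        rate_STN = sm$rate_stn, rate_GPe = sm$rate_gpe,
        stn_peak_hz = pk)
    })
    c(DA = da, colMeans(do.call(rbind, per_seed)))
  })
  as.data.frame(do.call(rbind, rows))
}
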