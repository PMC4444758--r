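#' Restless bandit payoff walk
#'
#' The mean payoff of each arm follows a decaying Gaussian random walk
#' `mu[k+1] = lambda * mu[k] + (1 - lambda) * theta + e`,
#' `e ~ N(0, sd_d^2)`; the payoff delivered on a trial is
#' `round(N(mu, sd_0^2))` clipped to `[0, 100]`. Walk parameters default
#' to the restless four-armed bandit convention of the human
#' decision-making literature (`lambda = 0.9836`, `theta = 50`,
#' `sd_d = 2.8`, `sd_0 = 4`); they are external defaults, not values
#' fixed by the circuit model, and are fully configurable.
#'
#' @param n_arms number of arms.
#' @param lambda decay of the mean toward `theta`.
#' @param theta attractor of the walk.
#' @param sd_d diffusion SD of the mean.
#' @param sd_0 payoff sampling SD.
#' @param mu0 initial mean payoff of every arm.
#' @return object of class `payoff_walk`.
#' @export
payoff_walk <- function(n_arms = 4, lambda = 0.9836, theta = 50,
                        sd_d = 2.8, sd_0 = 4, mu0 = 50) {
  structure(list(n_arms = n_arms, lambda = lambda, theta = theta,
                 sd_d = sd_d, sd_0 = sd_0, mu = rep(mu0, n_arms)),
            class = "payoff_walk")
}

#' @rdname payoff_walk
#' @param walk a `payoff_walk`.
#' @return `step_payoff_walk`: the walk with its means diffused by one
#'   trial (uses the current R random stream).
#' @export
step_payoff_walk <- function(walk) {
  walk$mu <- walk$lambda * walk$mu + (1 - walk$lambda) * walk$theta +
    stats::rnorm(walk$n_arms, 0, walk$sd_d)
  walk
}

#' @rdname payoff_walk
#' @param arm selected arm index.
#' @return `draw_payoff`: integer payoff in `[0, 100]`.
#' @export
draw_payoff <- function(walk, arm) {
  r <- round(stats::rnorm(1, walk$mu[arm], walk$sd_0))
  min(max(r, 0), 100)
}

#' Reward-prediction-error update of cortico-striatal weights
#'
#' For the selected arm `x`: expected value `V = w_D1[x]`, error
#' `delta = reward - V`, weight updates `w_D1[x] += eta * delta` and
#' `w_D2[x] -= eta * delta` (opposite signs for the two striatal
#' branches), and dopamine for the next trial
#' `DA = 1 / (1 + exp(-lambda_da * delta))` clipped into the working
#' range `[0.1, 0.9]`. `clamp_delta` substitutes a fixed error before
#' the dopamine mapping (e.g. -20 to pin dopamine at its Parkinsonian
#' floor) without affecting the weight update's bookkeeping use of the
#' true delta; pass `clamp_weights = TRUE` to clamp the plasticity too.
#'
#' @param w_d1,w_d2 length-4 weight vectors.
#' @param arm selected arm (1..4).
#' @param reward received payoff.
#' @param eta learning rate.
#' @param lambda_da sigmoid slope of the delta-to-dopamine mapping.
#' @param da_range working dopamine range.
#' @param clamp_delta optional fixed delta for the dopamine mapping.
#' @return list with `w_d1`, `w_d2`, `V`, `delta`, `DA`.
#' @export
rl_update <- function(w_d1, w_d2, arm, reward, eta = 0.3, lambda_da = 0.2,
                      da_range = c(0.1, 0.9), clamp_delta = NULL) {
  V <- w_d1[arm]
  delta <- reward - V
  w_d1[arm] <- w_d1[arm] + eta * delta
  w_d2[arm] <- w_d2[arm] - eta * delta
  d_eff <- if (is.null(clamp_delta)) delta else clamp_delta
  DA <- 1 / (1 + exp(-lambda_da * d_eff))
  DA <- min(max(DA, da_range[1]), da_range[2])
  list(w_d1 = w_d1, w_d2 = w_d2, V = V, delta = delta, DA = DA)
}

#' Run a spiking-network bandit session
#'
#' Each trial presents the four arms as striatal quadrant rates derived
#' from the cortico-striatal weights, runs the circuit at the current
#' dopamine level, selects an arm with the race model over the GPi
#' quadrant pools, draws the payoff, applies the reward-prediction-error
#' update, and carries the resulting dopamine into the next trial. The
#' network state is re-initialized each trial; the walk advances every
#' trial. No-Go trials deliver no reward and no update. A trial is
#' labeled `"exploit"` when the selected arm is the one with the highest
#' current true mean payoff.
#'
#' @param config a [circuit_config()]; `shape` is typically reduced
#'   (e.g. 20) for session-scale runs.
#' @param walk a [payoff_walk()].
#' @param n_trials trials in the session.
#' @param seed session seed (drives walk, striatal spikes and jitter).
#' @param eta learning rate.
#' @param lambda_da delta-to-dopamine slope.
#' @param clamp_delta optional fixed delta for the dopamine mapping (the
#'   Parkinsonian condition uses -20).
#' @param DA0 dopamine on the first trial.
#' @param rate_map weight-to-rate map, see [bandit_stimulus_layout()].
#' @param window stimulus window, ms.
#' @param trial_ms trial length, ms.
#' @param race_window_ms GPi pool-rate smoothing window, ms.
#' @param threshold,tau race parameters.
#' @return data frame of trial records: arm, label, reward, `V`,
#'   `delta`, `DA` used, mean STN synchrony in the stimulus window, and
#'   the true means.
#' @export
run_bandit_session <- function(config, walk = payoff_walk(), n_trials = 300,
                               seed = 1L, eta = 0.3, lambda_da = 0.2,
                               clamp_delta = NULL, DA0 = 0.5,
                               rate_map = function(w) w / 10,
                               window = c(100, 200), trial_ms = 250,
                               race_window_ms = 5, threshold = 0.15,
                               tau = 1) {
  w_d1 <- rep(50, walk$n_arms)
  w_d2 <- rep(50, walk$n_arms)
  DA <- DA0
  pools <- lattice_pools(config$shape, 4L)
  rec <- vector("list", n_trials)
  net_state <- NULL   # network state persists across trials
  for (k in seq_len(n_trials)) {
    set.seed(as.integer(seed * 10000L + k))
    walk <- step_payoff_walk(walk)
    lay <- bandit_stimulus_layout(w_d1, w_d2, rate_map, window,
                                  trial_ms = trial_ms, shape = config$shape)
    cfg <- config
    cfg$DA <- DA
    cfg$duration <- trial_ms
    cfg$seed <- as.integer(seed * 10000L + k)
    sim <- run_circuit(cfg, lay[c("D1", "D2")], state = net_state)
    net_state <- sim$state
    pr <- gpi_pool_rates(sim$gpi, pools, dt = cfg$dt,
                         window_ms = race_window_ms)
    race <- race_integrate(pr$f[pr$times > window[1], , drop = FALSE],
                           dt = cfg$dt, tau = tau, threshold = threshold)
    qt <- seq(window[1], window[2], by = 1)
    r_stn <- mean_r_sync(sim$stn, qt)
    arm <- race$winner
    if (!is.na(arm)) {
      reward <- draw_payoff(walk, arm)
      up <- rl_update(w_d1, w_d2, arm, reward, eta, lambda_da,
                      clamp_delta = clamp_delta)
      w_d1 <- up$w_d1; w_d2 <- up$w_d2
      DA <- up$DA
      rec[[k]] <- data.frame(
        trial = k, arm = arm,
        label = classify_outcome(arm, true_means = walk$mu),
        reward = reward, V = up$V, delta = up$delta, DA_used = cfg$DA,
        DA_next = DA, R_sync_stn = r_stn,
        mu_best = max(walk$mu), best_arm = which.max(walk$mu))
    } else {
      rec[[k]] <- data.frame(
        trial = k, arm = NA_integer_, label = "NoGo",
        reward = NA_real_, V = NA_real_, delta = NA_real_,
        DA_used = cfg$DA, DA_next = DA, R_sync_stn = r_stn,
        mu_best = max(walk$mu), best_arm = which.max(walk$mu))
    }
  }
  if (n_trials == 0L) return(data.frame())
  do.call(rbind, rec)
}

#' Soft-max behavioral reference session
#'
#' The abstract agent the network is compared against: delta-rule value
#' estimates per arm (initialized at the walk's starting mean) and
#' soft-max action selection `P(i) proportional to exp(beta * Q_i)`.
#' `beta -> 0` gives uniform random choice (25% exploitation in
#' expectation on four arms); large `beta` approaches greedy selection.
#'
#' @param walk a [payoff_walk()].
#' @param beta soft-max temperature parameter (exploitation increases
#'   with `beta`).
#' @param eta learning rate of the value update.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return data frame of trial records matching [run_bandit_session()]'s
#'   columns where applicable.
#' @export
behavioral_session <- function(walk = payoff_walk(), beta = 0.2, eta = 0.3,
                               n_trials = 300, seed = 1L) {
  stopifnot(beta >= 0)
  Q <- rep(walk$theta, walk$n_arms)
  rec <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(as.integer(seed * 10000L + k))
    walk <- step_payoff_walk(walk)
    p <- exp(beta * (Q - max(Q)))
    p <- p / sum(p)
    arm <- sample.int(walk$n_arms, 1, prob = p)
    reward <- draw_payoff(walk, arm)
    V <- Q[arm]
    delta <- reward - V
    Q[arm] <- Q[arm] + eta * delta
    rec[[k]] <- data.frame(
      trial = k, arm = arm,
      label = classify_outcome(arm, true_means = walk$mu),
      reward = reward, V = V, delta = delta,
      mu_best = max(walk$mu), best_arm = which.max(walk$mu))
  }
  do.call(rbind, rec)
}

#' Session-level bandit metrics
#'
#' Percent exploitation (share of all trials on which the arm with the
#' highest current true mean was selected), mean absolute
#' reward-prediction error, mean STN synchrony split by explore/exploit
#' label, and — when a matched behavioral session on the same walk is
#' supplied — the per-trial cross-model expected-value error
#' `e_bebg = V_bg - V_be`.
#'
#' @param records data frame from [run_bandit_session()] (or a
#'   row-bound set of sessions).
#' @param behavioral optional matched records from
#'   [behavioral_session()].
#' @return list of summary statistics.
#' @export
session_metrics <- function(records, behavioral = NULL) {
  stopifnot(nrow(records) > 0)
  out <- list(
    pct_exploitation = 100 * mean(records$label == "exploit"),
    mean_abs_delta = mean(abs(records$delta), na.rm = TRUE),
    n_nogo = sum(records$label == "NoGo"))
  if ("R_sync_stn" %in% names(records)) {
    out$mean_R_exploit <- mean(records$R_sync_stn[records$label == "exploit"],
                               na.rm = TRUE)
    out$mean_R_explore <- mean(records$R_sync_stn[records$label == "explore"],
                               na.rm = TRUE)
  }
  if (!is.null(behavioral)) {
    m <- min(nrow(records), nrow(behavioral))
    out$e_bebg <- records$V[seq_len(m)] - behavioral$V[seq_len(m)]
    out$mean_abs_e_bebg <- mean(abs(out$e_bebg), na.rm = TRUE)
  }
  out
}

#' Exploitation versus pathway weight
#'
#' Reruns bandit sessions while sweeping either the direct-pathway
#' weight (`w_strd1_gpi`, striatum D1 to GPi) or the indirect-pathway
#' readout weight (`w_stn_gpi`, STN to GPi), holding the other fixed.
#' Exploitation grows with the direct pathway and falls as the
#' indirect-pathway readout strengthens.
#'
#' @param config a [circuit_config()].
#' @param axis `"w_strd1_gpi"` or `"w_stn_gpi"`.
#' @param values weight values to test.
#' @param fixed named list of weights held fixed (e.g.
#'   `list(w_stn_gpi = 0.75)`).
#' @param n_sessions sessions per value.
#' @param n_trials trials per session.
#' @param seed base seed.
#' @param ... passed to [run_bandit_session()].
#' @return data frame with one row per weight value.
#' @export
sweep_pathway_weights <- function(config, axis = c("w_strd1_gpi", "w_stn_gpi"),
                                  values, fixed = list(), n_sessions = 3,
                                  n_trials = 300, seed = 1L, ...) {
  axis <- match.arg(axis)
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg[[axis]] <- v
    for (nm in names(fixed)) cfg[[nm]] <- fixed[[nm]]
    pct <- vapply(seq_len(n_sessions), function(s) {
      rec <- run_bandit_session(cfg, payoff_walk(), n_trials = n_trials,
                                seed = seed + 97L * s, ...)
      session_metrics(rec)$pct_exploitation
    }, numeric(1))
    data.frame(value = v, pct_exploitation = mean(pct))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- axis
  out
}
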