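test_that("payoff walk matches its AR(1) closed forms", {
  set.seed(12)
  w <- payoff_walk()
  mus <- matrix(NA_real_, 4000, 4)
  for (k in 1:4000) { w <- step_payoff_walk(w); mus[k, ] <- w$mu }
  tail_mu <- mus[1001:4000, ]
  expect_lt(abs(mean(tail_mu) - w$theta), 2)
  var_inf <- w$sd_d^2 / (1 - w$lambda^2)
  expect_lt(abs(var(as.vector(tail_mu)) / var_inf - 1), 0.25)
  # degenerate walk stays put and pays exactly its mean
  d <- payoff_walk(lambda = 1, sd_d = 0, sd_0 = 0)
  d <- step_payoff_walk(d)
  expect_equal(d$mu, rep(50, 4))
  expect_equal(draw_payoff(d, 2), 50)
})

test_that("payoffs are integers clipped to [0, 100]", {
  set.seed(13)
  w <- payoff_walk(sd_0 = 80)
  pays <- replicate(2000, draw_payoff(w, 1))
  expect_true(all(pays >= 0 & pays <= 100))
  expect_true(all(pays == round(pays)))
  expect_gt(sum(pays %in% c(0, 100)), 0)  # clipping actually engaged
})

test_that("the reward-prediction-error update follows the published rule", {
  up <- rl_update(rep(50, 4), rep(50, 4), arm = 2, reward = 70, eta = 0.3)
  expect_equal(up$V, 50)
  expect_equal(up$delta, 20)
  expect_equal(up$w_d1[2], 56)
  expect_equal(up$w_d2[2], 44)
  expect_equal(up$w_d1[-2], rep(50, 3))
  # delta = 0: dopamine at the sigmoid midpoint, no weight change
  z <- rl_update(rep(50, 4), rep(50, 4), 1, 50)
  expect_equal(z$DA, 0.5)
  expect_equal(z$w_d1, rep(50, 4))
  # strongly negative delta clips to the dopamine floor (PD clamp)
  neg <- rl_update(rep(50, 4), rep(50, 4), 1, 50, clamp_delta = -20)
  expect_equal(1 / (1 + exp(0.2 * 20)), 0.0180, tolerance = 1e-3)
  expect_equal(neg$DA, 0.1)
  pos <- rl_update(rep(50, 4), rep(50, 4), 1, 100)
  expect_equal(pos$DA, 0.9)  # ceiling
})

test_that("weights conserve w_D1 + w_D2 = 100 and delta bookkeeping holds", {
  set.seed(14)
  w1 <- rep(50, 4); w2 <- rep(50, 4)
  walk <- payoff_walk()
  for (k in 1:200) {
    walk <- step_payoff_walk(walk)
    arm <- sample.int(4, 1)
    r <- draw_payoff(walk, arm)
    up <- rl_update(w1, w2, arm, r)
    expect_equal(up$delta, r - up$V)
    w1 <- up$w_d1; w2 <- up$w_d2
    expect_equal(w1 + w2, rep(100, 4))
  }
})

test_that("behavioral soft-max agent spans random to greedy with beta", {
  pct <- sapply(c(0.001, 0.3, 3), function(beta) {
    mean(sapply(1:6, function(s) {
      rec <- behavioral_session(payoff_walk(), beta = beta, n_trials = 150,
                                seed = s)
      mean(rec$label == "exploit")
    }))
  })
  expect_lt(abs(pct[1] - 0.25), 0.07)   # beta -> 0: uniform on 4 arms
  expect_gt(pct[2], pct[1] + 0.1)       # exploitation grows with beta
  expect_gt(pct[3], pct[2] - 0.05)      # and saturates near the greedy limit
  expect_gt(pct[3], 0.4)
})

test_that("session metrics summarize records correctly", {
  rec <- data.frame(label = c("exploit", "explore", "exploit", "NoGo"),
                    delta = c(5, -3, 2, NA),
                    V = c(50, 52, 51, NA),
                    R_sync_stn = c(0.2, 0.5, 0.3, 0.4))
  m <- session_metrics(rec)
  expect_equal(m$pct_exploitation, 50)
  expect_equal(m$mean_abs_delta, mean(c(5, 3, 2)))
  expect_equal(m$n_nogo, 1L)
  expect_equal(m$mean_R_exploit, 0.25)
  expect_equal(m$mean_R_explore, 0.5)
  all_ex <- data.frame(label = rep("exploit", 4), delta = 1:4, V = 1:4)
  expect_equal(session_metrics(all_ex)$pct_exploitation, 100)
  alt <- data.frame(label = rep(c("exploit", "explore"), 5),
                    delta = 0, V = 0)
  expect_equal(session_metrics(alt)$pct_exploitation, 50)
  # cross-model error against a matched behavioral record
  beh <- data.frame(V = c(49, 50, 53, 50))
  m2 <- session_metrics(rec, beh)
  expect_equal(m2$e_bebg, c(1, 2, -2, NA))
})

test_that("a short network bandit session runs and learns on a rigged walk", {
  # one arm always pays 100, the rest 0: the selection machinery must keep
  # choosing, the value estimate of the rigged arm must converge to its
  # payoff, and the bookkeeping must stay exact
  cfg <- circuit_config(shape = 20, duration = 250, DA = 0.5)
  walk <- payoff_walk(lambda = 1, sd_d = 0, sd_0 = 0)
  walk$mu <- c(0, 0, 100, 0)
  rec <- run_bandit_session(cfg, walk, n_trials = 60, seed = 3)
  expect_equal(nrow(rec), 60)
  sel <- rec$label != "NoGo"
  expect_gt(mean(sel), 0.5)
  expect_gte(mean(rec$label == "exploit"), 0.15)
  expect_gt(max(rec$V[!is.na(rec$arm) & rec$arm == 3]), 90)  # learned value
  # delta bookkeeping holds in the records
  ok <- !is.na(rec$delta)
  expect_equal(rec$delta[ok], rec$reward[ok] - rec$V[ok])
  # zero-trial session
  expect_equal(nrow(run_bandit_session(cfg, walk, n_trials = 0, seed = 1)),
               0L)
})
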