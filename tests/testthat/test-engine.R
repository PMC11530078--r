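make_m1_config <- function(Sigma_y = 0, Sigma_x = 0, lambda1 = 1e-12, A = 1,
                           mu = c(0, 0)) {
  spec <- player_game_spec("s", 2L, 2L, Q_own = diag(2) * 2,
                           Q_cross = diag(2) * 0.5, r_own = c(1, -1))
  p <- player_params(Sigma_y = Sigma_y, mu = mu, P0 = 1e-9, A = A,
                     Sigma_x = Sigma_x, lambda1 = lambda1, a = 1, dim = 2L)
  list(game = joint_game(spec, spec), params = list(p, p))
}

test_that("a dyad at a Nash equilibrium with perfect sensing stays there", {
  cfg <- make_m1_config()
  ne <- nash_equilibrium(cfg$game)
  beliefs <- list(partner_belief(ne$u2, 0 * diag(2)),
                  partner_belief(ne$u1, 0 * diag(2)))
  policies <- list(policy_state(1e-12), policy_state(1e-12))
  step <- run_trial(cfg$game, cfg$params, beliefs, policies)
  expect_equal(step$record$players[[1]]$u, ne$u1, tolerance = 1e-9)
  expect_equal(step$record$players[[2]]$u, ne$u2, tolerance = 1e-9)
  expect_equal(step$beliefs[[1]]$x, ne$u2, tolerance = 1e-9)
  expect_equal(step$beliefs[[2]]$x, ne$u1, tolerance = 1e-9)
})

test_that("one stochastic trial equals a hand-stepped chain at the same RNG state", {
  cfg <- make_m1_config(Sigma_y = 0.5, Sigma_x = 0.1, lambda1 = 0.3, A = 0.9)
  beliefs <- lapply(cfg$params, initial_belief)
  policies <- list(policy_state(0.3), policy_state(0.3))
  set.seed(777)
  step <- run_trial(cfg$game, cfg$params, beliefs, policies)
  # manual chain, drawing from the same single RNG stream in event order
  set.seed(777)
  a1 <- sample_action(cfg$game$specs[[1]], beliefs[[1]]$x, beliefs[[1]]$P, 0.3)
  a2 <- sample_action(cfg$game$specs[[2]], beliefs[[2]]$x, beliefs[[2]]$P, 0.3)
  y1 <- observe(a2$u, cfg$params[[1]]$H, cfg$params[[1]]$Sigma_y)
  b1 <- kalman_step(beliefs[[1]], y1, cfg$params[[1]])
  y2 <- observe(a1$u, cfg$params[[2]]$H, cfg$params[[2]]$Sigma_y)
  b2 <- kalman_step(beliefs[[2]], y2, cfg$params[[2]])
  expect_equal(step$record$players[[1]]$u, a1$u)
  expect_equal(step$record$players[[2]]$u, a2$u)
  expect_equal(step$record$players[[1]]$y, y1)
  expect_equal(step$beliefs[[1]]$x, b1$x)
  expect_equal(step$beliefs[[2]]$P, b2$P)
  expect_equal(step$record$players[[1]]$cost,
               deterministic_cost(cfg$game$specs[[1]], a1$u, a2$u))
})

test_that("with one strategy and zero temperature the loop is filtered fictitious play", {
  cfg <- make_m1_config(mu = c(1, 1), A = 1)
  series <- run_session(cfg, 30, seed = 5)
  # oracle: deterministic recursion of conditional optima through the filter
  spec <- cfg$game$specs[[1]]
  x1 <- c(1, 1); x2 <- c(1, 1); P <- 1e-9 * diag(2)
  for (t in 1:30) {
    u1 <- expected_cost(spec, x1, P)$u_star
    u2 <- expected_cost(spec, x2, P)$u_star
    expect_equal(series$players[[1]]$u[t, ], u1, tolerance = 1e-6)
    expect_equal(series$players[[2]]$u[t, ], u2, tolerance = 1e-6)
    K <- diag(2)                       # noiseless sensing: full correction
    x1 <- u2; x2 <- u1
  }
  # and it converges to the equilibrium
  ne <- nash_equilibrium(cfg$game)
  expect_equal(series$players[[1]]$u[30, ], ne$u1, tolerance = 1e-4)
})

test_that("sessions are bit-reproducible from (config, seed) and respect n_trials", {
  cfg <- stag_hunt_session_config(Sigma_y = 1, Sigma_x = 1)
  s1 <- run_session(cfg, 60, seed = 9)
  s2 <- run_session(cfg, 60, seed = 9)
  s3 <- run_session(cfg, 60, seed = 10)
  expect_identical(s1$players[[1]]$u, s2$players[[1]]$u)
  expect_identical(s1$players[[2]]$s, s2$players[[2]]$s)
  expect_false(identical(s1$players[[1]]$u, s3$players[[1]]$u))
  expect_identical(run_session(cfg, 1, seed = 1)$n_trials, 1L)
  expect_error(run_session(list(game = cfg$game), 10, 1), "params")
  expect_error(run_session(cfg, 0, 1), "n_trials")
})

test_that("player 1's draws do not depend on player 2's parameters", {
  cfg <- stag_hunt_session_config(Sigma_y = 1, Sigma_x = 1)
  cfg2 <- cfg
  cfg2$params[[2]] <- player_params(Sigma_y = 5, mu = 0.3, P0 = 1e-3, A = 0.5,
                                    Sigma_x = 3, lambda1 = 0.4, a = 0.99, dim = 1L)
  s1 <- run_session(cfg, 40, seed = 33)
  s2 <- run_session(cfg2, 40, seed = 33)
  # identical until player 2's different behavior feeds back through sensing:
  # at least the first trial's player-1 action must coincide exactly
  expect_identical(s1$players[[1]]$u[1, ], s2$players[[1]]$u[1, ])
})

test_that("epoch strategy proportions count correctly and sum to one", {
  cfg <- stag_hunt_session_config()
  series <- run_session(cfg, 80, seed = 2)
  # overwrite with hand-built labels: epoch 1 all SS; epoch 2 has 10 SS
  series$players[[1]]$s <- c(rep("stag", 40), rep(c("stag", "rabbit"), c(10, 30)))
  series$players[[2]]$s <- c(rep("stag", 40), rep("stag", 40))
  ep <- epoch_strategy_probabilities(series, 40)
  expect_equal(unname(ep[1, "stag-stag"]), 1)
  expect_equal(unname(ep[2, "stag-stag"]), 0.25)
  expect_equal(unname(rowSums(ep)), c(1, 1))
  # uniform independent labels hover at the 0.25 chance level
  set.seed(303)
  series$players[[1]]$s <- sample(c("stag", "rabbit"), 80, TRUE)
  series$players[[2]]$s <- sample(c("stag", "rabbit"), 80, TRUE)
  ep2 <- epoch_strategy_probabilities(series, 80)
  expect_lt(max(abs(ep2 - 0.25)), 3 * sqrt(0.25 * 0.75 / 80))
})

test_that("population jitter stays within +-10% and respects parameter bounds", {
  set.seed(404)
  base <- stag_hunt_params(Sigma_y = 10, Sigma_x = 0.1)
  for (k in 1:50) {
    j <- jitter_params(base, 0.1)
    expect_true(abs(as.numeric(j$Sigma_y) / 10 - 1) <= 0.1 + 1e-12)
    expect_true(abs(as.numeric(j$Sigma_x) / 0.1 - 1) <= 0.1 + 1e-12)
    # rates jitter on the (1 - rate) scale: time constants move by <= 10%
    expect_true(abs((1 - j$a) / (1 - 0.999) - 1) <= 0.1 + 1e-9)
    expect_true(abs((1 - as.numeric(j$A)) / (1 - 0.99) - 1) <= 0.1 + 1e-9)
    expect_true(j$a <= 1 && as.numeric(j$A) <= 1)
    expect_identical(j$mu, base$mu)      # zero prior mean stays zero
  }
  runs <- simulate_dyads(stag_hunt_session_config(), 3, 10, seed = 1)
  expect_length(runs, 3L)
  expect_false(identical(runs[[1]]$players[[1]]$u, runs[[2]]$players[[1]]$u))
})
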