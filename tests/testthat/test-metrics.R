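test_that("Savitzky-Golay smoothing reproduces low-order polynomials with derivatives", {
  fs <- 100; t <- seq(0, 2, by = 1 / fs)
  x <- 2 + 3 * t - 1.5 * t^2 + 0.5 * t^3
  sm <- sg_smooth(x, fs = fs)
  interior <- 30:(length(t) - 30)
  expect_lt(max(abs(sm$pos[interior] - x[interior])), 1e-8)
  expect_lt(max(abs(sm$vel[interior] - (3 - 3 * t[interior] + 1.5 * t[interior]^2))), 1e-6)
  expect_lt(max(abs(sm$acc[interior] - (-3 + 3 * t[interior]))), 1e-4)
  # constant input: zero velocity
  smc <- sg_smooth(rep(1.2, 201), fs = fs)
  expect_lt(max(abs(smc$vel)), 1e-10)
  # white noise: variance reduced
  set.seed(601)
  noise <- rnorm(500)
  expect_lt(var(sg_smooth(noise, fs = fs)$pos), var(noise))
  expect_error(sg_smooth(rnorm(10), fs = fs), "shorter")
})

test_that("minimum via-point distance agrees with an exhaustive scan", {
  set.seed(611)
  traj <- data.frame(t = seq(0, 1, length.out = 100),
                     x = cumsum(rnorm(100, 0, 0.01)),
                     y = cumsum(rnorm(100, 0, 0.01)))
  vp <- c(0.05, -0.05)
  res <- min_vp_distance(traj, vp)
  dists <- sqrt((traj$x - vp[1])^2 + (traj$y - vp[2])^2)
  best <- Inf; best_t <- NA
  for (i in seq_len(nrow(traj))) if (dists[i] < best) { best <- dists[i]; best_t <- traj$t[i] }
  expect_equal(res$MD, best)
  expect_equal(res$TC, best_t)
  # path through the via-point and a constant path
  traj2 <- data.frame(t = 1:3 / 10, x = c(0, 0.05, 0.1), y = c(0, -0.05, 0))
  expect_equal(min_vp_distance(traj2, vp)$MD, 0)
  traj3 <- data.frame(t = 1:5, x = rep(0.05, 5), y = rep(0.05, 5))
  expect_equal(min_vp_distance(traj3, vp), list(MD = 0.1, TC = 1))
})

test_that("strategy classification implements the threshold rule with an invalid case", {
  expect_identical(classify_strategy(0.001, 0.001, 0.3, 0.7), "E")
  expect_identical(classify_strategy(0.001, 0.001, 0.7, 0.3), "L")
  expect_identical(classify_strategy(0.001, 0.05, 0.3, 0.7), "M")
  expect_identical(classify_strategy(0.05, 0.001, 0.3, 0.7), "invalid")
  # thresholds are strict
  expect_identical(classify_strategy(0.02, 0.001, 0.3, 0.7), "invalid")
  expect_identical(classify_strategy(0.001, 0.02, 0.3, 0.7), "M")
})

test_that("dyad classification distinguishes collaboration, cycling and neither", {
  expect_identical(classify_dyad("E", "L"), "collaborative")
  expect_identical(classify_dyad("L", "E"), "collaborative")
  expect_identical(classify_dyad("E", "E"), "cyclic")
  expect_identical(classify_dyad("L", "L"), "cyclic")
  expect_identical(classify_dyad("M", "E"), "non-collaborative")
  expect_identical(classify_dyad("invalid", "L"), "non-collaborative")
})

test_that("leadership index averages interaction power over the pre-crossing window", {
  t <- seq(0, 1, by = 0.01)
  n <- length(t)
  Fm <- cbind(rep(0.5, n), rep(-0.2, n))
  v <- cbind(rep(0.1, n), rep(0.3, n))
  TC <- 0.5
  li <- leadership_index(Fm, v, t, TC)
  # explicit sample-loop oracle
  acc <- c()
  for (i in seq_len(n)) if (t[i] >= TC - 0.3 && t[i] < TC)
    acc <- c(acc, Fm[i, 1] * v[i, 1] + Fm[i, 2] * v[i, 2])
  expect_equal(li, mean(acc))
  # zero force gives zero; force parallel to velocity marks a follower
  expect_equal(leadership_index(0 * Fm, v, t, TC), 0)
  expect_gt(leadership_index(cbind(v[, 1], v[, 2]), v, t, TC), 0)
  # moving against the force marks a leader
  expect_lt(leadership_index(-v, v, t, TC), 0)
})

test_that("learner flag uses the final epoch with a strict threshold", {
  expect_true(learner_flag(rep(0, 24)))
  expect_false(learner_flag(rep(0.05, 24)))
  expect_false(learner_flag(rep(0.02, 24)))            # boundary: not below
  expect_true(learner_flag(c(rep(0.5, 12), rep(0.001, 12))))
  expect_false(learner_flag(c(rep(0.001, 12), rep(0.5, 12))))
  expect_error(learner_flag(rep(0, 5)), "epoch")
})

test_that("collaboration probabilities count per epoch and sum to one", {
  s1 <- rep("E", 12); s2 <- rep("L", 12)
  expect_equal(unname(collaboration_probability(s1, s2)[1, ]), c(1, 0, 0))
  s1 <- rep(c("E", "E"), 6); s2 <- rep(c("L", "E"), 6)
  cp <- collaboration_probability(s1, s2)
  expect_equal(unname(cp[1, ]), c(0.5, 0.5, 0))
  # trial-loop oracle on a random labeling
  set.seed(621)
  s1 <- sample(c("E", "L", "M"), 36, TRUE); s2 <- sample(c("E", "L", "M"), 36, TRUE)
  cp <- collaboration_probability(s1, s2, 12)
  for (e in 1:3) {
    idx <- (e - 1) * 12 + 1:12
    lab <- mapply(classify_dyad, s1[idx], s2[idx])
    expect_equal(unname(cp[e, "collaborative"]), mean(lab == "collaborative"))
    expect_equal(unname(cp[e, "cyclic"]), mean(lab == "cyclic"))
  }
  expect_equal(unname(rowSums(cp)), rep(1, 3))
})

test_that("the metric pipeline is label-symmetric under a player/via-point swap", {
  basis <- viapoint_basis()
  cfg <- viapoint_config("symmetric")
  sess <- viapoint_session_config(cfg, basis, Sigma_y = 1e-4)
  series <- run_session(sess, 12, seed = 77)
  rec <- viapoint_recordings(series)
  met <- coordination_metrics(rec, cfg$VP1, cfg$VP2)
  # swap players and via-points
  rec_sw <- rec; rec_sw$player <- 3L - rec$player
  met_sw <- coordination_metrics(rec_sw, cfg$VP2, cfg$VP1)
  m1 <- met[met$player == 1, ]; m2s <- met_sw[met_sw$player == 2, ]
  expect_equal(m1$MD_own, m2s$MD_own, tolerance = 1e-12)
  expect_equal(m1$MD_other, m2s$MD_other, tolerance = 1e-12)
  expect_identical(m1$s, m2s$s)
  expect_identical(met$dyad, met_sw$dyad)
})

test_that("simulated dyads with reliable partner sensing coordinate more closely", {
  # low sensory noise (partner-visible-like) vs high (haptic-like); the
  # end-of-training distance to the partner via-point must be smaller with
  # reliable sensing, and leadership indices mark leading into the own
  # via-point, following into the partner's
  cfg <- viapoint_config("asymmetric")
  res <- lapply(c(2.5e-5, 4e-4), function(sy) {
    runs <- simulate_dyads(viapoint_session_config(cfg, Sigma_y = sy),
                           5, 100, seed = round(1e6 * sy) + 13)
    mets <- lapply(runs, function(s)
      coordination_metrics(viapoint_recordings(s), cfg$VP1, cfg$VP2))
    li <- function(win, col1, col2) mean(vapply(mets, function(m) {
      mm <- m[m$trial %in% win, ]
      mean(ifelse(mm$player == 1, mm[[col1]], mm[[col2]]))
    }, numeric(1)))
    list(md = mean(vapply(mets, function(m)
           mean(m$MD_other[m$trial > 88]), numeric(1))),
         li_own = li(45:56, "LI1", "LI2"),   # mid-training window:
         li_oth = li(45:56, "LI2", "LI1"))   # roles fade as dyads converge
  })
  expect_lt(res[[1]]$md, res[[2]]$md)
  # while coordination is being negotiated, each player leads (negative
  # power) into their own via-point and follows (positive) into the
  # partner's; clearest under unreliable sensing
  expect_lt(res[[2]]$li_own, 0)
  expect_gt(res[[2]]$li_oth, 0)
  # with a reliably sensed partner the dyad is closer to the equilibrium
  # and the leading role is weaker
  expect_lt(abs(res[[1]]$li_own), abs(res[[2]]$li_own))
})
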