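basis <- viapoint_basis()
cfg_a <- viapoint_config("asymmetric")
cfg_s <- viapoint_config("symmetric")

test_that("spline basis interpolates node values and boundary conditions exactly", {
  set.seed(501)
  u <- rnorm(basis$n_free, 0, 0.03)
  at <- function(tt) {
    r <- basis_row(basis, tt)
    sum(r$b * u) + sum(r$c0 * basis$u0[1, ])
  }
  expect_lt(max(abs(vapply(basis$free_times, at, numeric(1)) - u)), 1e-10)
  expect_equal(at(0), -0.05, tolerance = 1e-10)
  expect_equal(at(basis$dt), -0.05, tolerance = 1e-10)
  expect_equal(at(basis$T - basis$dt), 0.05, tolerance = 1e-10)
  expect_equal(at(basis$T), 0.05, tolerance = 1e-10)
  expect_error(viapoint_basis(M = 4L), "M >= 5")
})

test_that("spline reproduces affine paths through its linear term", {
  # node values and boundary block all on one straight line
  line <- function(tt) -0.05 + 0.1 * tt
  u <- cbind(line(basis$free_times), 2 * line(basis$free_times))
  u0 <- rbind(line(basis$fixed_times), 2 * line(basis$fixed_times))
  tr <- sample_trajectory(basis, u, u0 = u0)
  expect_lt(max(abs(tr$x - line(tr$t))), 1e-9)
  expect_lt(max(abs(tr$y - 2 * line(tr$t))), 1e-9)
  expect_lt(max(abs(tr$vx - 0.1)), 1e-7)
  expect_lt(max(abs(tr$ax)), 1e-5)
})

test_that("a collapsed geometry gives a constant path with zero velocity", {
  b0 <- viapoint_basis(p_start = c(0.01, 0.02), p_end = c(0.01, 0.02))
  u <- cbind(rep(0.01, b0$n_free), rep(0.02, b0$n_free))
  tr <- sample_trajectory(b0, u)
  expect_lt(max(abs(tr$x - 0.01)), 1e-10)
  expect_lt(max(abs(tr$vx)), 1e-8)
  expect_lt(max(abs(tr$vy)), 1e-8)
})

test_that("assembled quadratic game equals direct evaluation on sampled trajectories", {
  set.seed(511)
  game <- viapoint_game(cfg_a, basis)
  for (k in 1:50) {
    u1 <- straight_action(basis) + rnorm(10, 0, 0.02)
    u2 <- straight_action(basis) + rnorm(10, 0, 0.02)
    s <- sample(c("E", "M", "L"), 1)
    i <- sample(1:2, 1)
    uo <- if (i == 1) u1 else u2; up <- if (i == 1) u2 else u1
    quad <- deterministic_cost(game$specs[[i]], uo, up, s)
    direct <- viapoint_cost_direct(cfg_a, basis, uo, up, s, player = i)
    expect_lt(abs(quad - direct) / abs(direct), 1e-8)
  }
})

test_that("all own-curvature blocks are positive definite at the default weights", {
  game <- viapoint_game(cfg_a, basis)
  for (spec in game$specs) for (s in spec$strategies) {
    ev <- eigen(spec$blocks[[s]]$Q_own, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("the equilibrium scan finds exactly the two crossing-order classes", {
  game <- viapoint_game(cfg_a, basis)
  po <- equilibrium_path_orders(game, cfg_a, basis)
  expect_identical(po$orders, c("VP1-first", "VP2-first"))
  eq <- po$equilibria
  stable <- eq[eq$is_equilibrium, ]
  # every stable pair has distinct crossing times and a consistent order:
  # strategies map to times E < M < L for each player's own via-point
  ct <- cfg_a$crossing_times
  expect_true(all(ct[stable$s1] != ct[stable$s2]))
  expect_identical(stable$order,
                   unname(ifelse(ct[stable$s1] < ct[stable$s2],
                                 "VP1-first", "VP2-first")))
  # the asymmetric geometry makes the VP1-first class cheaper
  expect_lt(po$best[["VP1-first"]], po$best[["VP2-first"]])
})

test_that("symmetric via-points make the two equilibrium orders cost-equivalent", {
  game <- viapoint_game(cfg_s, basis)
  e1 <- nash_equilibrium(game, c("E", "L"))
  e2 <- nash_equilibrium(game, c("L", "E"))
  # mirror symmetry about the start-target axis maps one onto the other
  expect_equal(sort(e1$costs), sort(e2$costs), tolerance = 1e-9)
  expect_equal(e1$u1[1:5], e2$u2[1:5], tolerance = 1e-9)        # x coordinates
  expect_equal(e1$u1[6:10], -e2$u2[6:10], tolerance = 1e-9)     # mirrored y
  po <- equilibrium_path_orders(game, cfg_s, basis)
  expect_lt(abs(po$best[["VP1-first"]] - po$best[["VP2-first"]]), 1e-9)
})

test_that("removing the coupling decouples the game into solo optima", {
  cfg0 <- viapoint_config("asymmetric", d_max = Inf, k = 0)
  game <- viapoint_game(cfg0, basis)
  for (spec in game$specs) for (s in spec$strategies)
    expect_equal(max(abs(spec$blocks[[s]]$Q_cross)), 0)
  ne <- nash_equilibrium(game, c("E", "E"))
  solo <- expected_cost(game$specs[[1]], rep(0, 10), 0, "E")$u_star
  expect_equal(ne$u1, solo, tolerance = 1e-9)
})

test_that("motor command matches a finite-difference oracle away from the edges", {
  set.seed(521)
  u1 <- straight_action(basis) + rnorm(10, 0, 0.02)
  u2 <- straight_action(basis) + rnorm(10, 0, 0.02)
  t1 <- sample_trajectory(basis, u1); t2 <- sample_trajectory(basis, u2)
  Fm <- motor_command(t1, t2, m = 1, b = 5, k = 30)
  h <- diff(t1$t[1:2])
  idx <- 3:(nrow(t1) - 2)
  vfd <- (t1$x[idx + 1] - t1$x[idx - 1]) / (2 * h)
  afd <- (t1$x[idx + 1] - 2 * t1$x[idx] + t1$x[idx - 1]) / h^2
  Ffd <- 1 * afd + 5 * vfd + 30 * (t1$x[idx] - t2$x[idx])
  expect_lt(max(abs(Fm[idx, 1] - Ffd)), 0.05 * max(1, max(abs(Ffd))))
  # stationary coincident players exert no force
  b0 <- viapoint_basis(p_start = c(0, 0), p_end = c(0, 0))
  z <- sample_trajectory(b0, matrix(0, b0$n_free, 2))
  expect_lt(max(abs(motor_command(z, z, 1, 5, 30))), 1e-8)
})

test_that("interaction force is antisymmetric and linear in the stiffness", {
  set.seed(531)
  u1 <- straight_action(basis) + rnorm(10, 0, 0.02)
  u2 <- straight_action(basis) + rnorm(10, 0, 0.02)
  t1 <- sample_trajectory(basis, u1); t2 <- sample_trajectory(basis, u2)
  F12 <- interaction_force(t1, t2, 30)
  F21 <- interaction_force(t2, t1, 30)
  expect_equal(unname(F12), unname(-F21))
  expect_equal(unname(interaction_force(t1, t2, 60)), unname(2 * F12))
  expect_equal(max(abs(interaction_force(t1, t1, 30))), 0)
})
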