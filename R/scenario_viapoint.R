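# Two via-point (2-VP) reaching game. Planar point-to-point movements through
# one of two via-points, mechanically coupled through a virtual spring.
# Trajectories are parameterized by a cubic polyharmonic spline over free node
# coordinates; the per-trial action is the vector of free node coordinates
# (x block stacked over y block). The via-point crossing time is the discrete
# strategy (early / middle / late), and the Bryson-weighted cost reduces to a
# quadratic game in the two players' actions.

.phs_g <- function(tau, node_times, deriv = 0L) {
  d <- tau - node_times
  rb <- switch(as.character(deriv),
               "0" = abs(d)^3, "1" = 3 * d * abs(d), "2" = 6 * abs(d),
               stop("deriv must be 0, 1 or 2"))
  lin <- switch(as.character(deriv), "0" = c(tau, 1), "1" = c(1, 0), "2" = c(0, 0))
  c(rb, lin)
}

#' Polyharmonic spline basis for trajectory actions
#'
#' Interpolates a planar trajectory through M node values with a cubic
#' radial-basis spline plus linear term. Four nodes are boundary-constrained:
#' p(0) = p(dt) = p_start and p(T - dt) = p(T) = p_end, which pins the start
#' and end positions and enforces (approximately) zero boundary velocity over
#' the short offset dt. The remaining M - 4 node values are the free action
#' coordinates; free node times are uniformly spaced in (0, T). Position,
#' velocity and acceleration anywhere are linear in the free coordinates:
#' p(tau) = g(tau)' (S1 u + S0 u0).
#'
#' @param M total node count (>= 5; default 9, i.e. 5 free nodes per
#'   coordinate and a 10-dimensional planar action).
#' @param T movement duration (normalized, default 1).
#' @param dt boundary-condition offset in the same units (default 0.01).
#' @param p_start,p_end planar endpoints (m).
#' @param n_grid number of uniform cost/sampling grid points (default 100,
#'   i.e. 100 Hz over a 1 s movement).
#' @return object of class `spline_basis` with the interpolation matrices and
#'   the position/velocity/acceleration grid maps.
#' @export
viapoint_basis <- function(M = 9L, T = 1, dt = 0.01,
                           p_start = c(-0.05, 0), p_end = c(0.05, 0),
                           n_grid = 100L) {
  if (M < 5L) stop("need M >= 5 (4 boundary-constrained nodes + >= 1 free)")
  n_free <- M - 4L
  free_times <- T * seq_len(n_free) / (n_free + 1)
  fixed_times <- c(0, dt, T - dt, T)
  node_times <- sort(c(fixed_times, free_times))
  if (anyDuplicated(node_times)) stop("duplicate node times; interpolation system singular")
  G <- abs(outer(node_times, node_times, "-"))^3
  Pm <- cbind(node_times, 1)
  A <- rbind(cbind(G, Pm), cbind(t(Pm), matrix(0, 2, 2)))
  if (rcond(A) < 1e-15) stop("singular interpolation system")
  S <- solve(A)[, seq_len(M)]                       # (M+2) x M coefficient map
  fixed_idx <- match(fixed_times, node_times)
  free_idx <- match(free_times, node_times)
  S1 <- S[, free_idx, drop = FALSE]
  S0 <- S[, fixed_idx, drop = FALSE]
  times <- seq(0, T, length.out = n_grid)
  gmat <- function(deriv) t(vapply(times, .phs_g, numeric(M + 2L),
                                   node_times = node_times, deriv = deriv))
  G0 <- gmat(0L); G1 <- gmat(1L); G2 <- gmat(2L)
  u0 <- rbind(c(p_start[1], p_start[1], p_end[1], p_end[1]),
              c(p_start[2], p_start[2], p_end[2], p_end[2]))  # row d, 4 cols
  structure(list(
    M = M, n_free = n_free, T = T, dt = dt, node_times = node_times,
    free_times = free_times, fixed_times = fixed_times,
    p_start = p_start, p_end = p_end, u0 = u0,
    S1 = S1, S0 = S0, times = times, n_grid = n_grid,
    Bp = G0 %*% S1, Bv = G1 %*% S1, Ba = G2 %*% S1,
    C0p = G0 %*% S0, C0v = G1 %*% S0, C0a = G2 %*% S0),
    class = "spline_basis")
}

#' Evaluate the basis at an arbitrary time
#'
#' @param basis a [viapoint_basis()].
#' @param tau evaluation time.
#' @param deriv derivative order (0 = position, 1 = velocity, 2 = acceleration).
#' @return list with `b` (row over free node coordinates) and `c0` (row over
#'   the four boundary values), such that p(tau) = b u + c0 u0 per coordinate.
#' @export
basis_row <- function(basis, tau, deriv = 0L) {
  g <- .phs_g(tau, basis$node_times, deriv)
  list(b = as.numeric(g %*% basis$S1), c0 = as.numeric(g %*% basis$S0))
}

#' Reconstruct a sampled trajectory from a free-node action
#'
#' @param basis a [viapoint_basis()].
#' @param u free-node action: either a length 2(M-4) vector (x block then y
#'   block) or an (M-4) x 2 matrix.
#' @param u0 optional 2 x 4 boundary-value override (rows x/y, columns
#'   p(0), p(dt), p(T-dt), p(T)); defaults to the basis boundary block.
#' @return data.frame with columns t, x, y, vx, vy, ax, ay on the basis grid.
#' @export
sample_trajectory <- function(basis, u, u0 = basis$u0) {
  U <- if (is.matrix(u)) u else matrix(u, basis$n_free, 2L)
  val <- function(B, C0) B %*% U + C0 %*% t(u0)
  p <- val(basis$Bp, basis$C0p); v <- val(basis$Bv, basis$C0v)
  a <- val(basis$Ba, basis$C0a)
  data.frame(t = basis$times, x = p[, 1], y = p[, 2],
             vx = v[, 1], vy = v[, 2], ax = a[, 1], ay = a[, 2])
}

#' Free-node action of a straight constant-speed path
#'
#' Useful as a neutral prior mean: the node values of the straight segment
#' from the basis start to end point.
#'
#' @param basis a [viapoint_basis()].
#' @return length 2(M-4) action vector.
#' @export
straight_action <- function(basis) {
  f <- basis$free_times / basis$T
  c(basis$p_start[1] + f * (basis$p_end[1] - basis$p_start[1]),
    basis$p_start[2] + f * (basis$p_end[2] - basis$p_start[2]))
}

#' 2-VP scenario configuration
#'
#' Geometry in meters in the robot frame: start (-5, 0) cm, target (5, 0) cm.
#' Experiment-1 (asymmetric) via-points (-2, -3) and (2, 3) cm with crossing
#' times 0.32/0.5/0.68 T; experiment-2 (symmetric) via-points (0, -3) and
#' (0, 3) cm with 0.38/0.5/0.62 T. Cost weights follow the Bryson rule
#' (inverse squared maximum acceptable magnitudes): w1 = 1/r_VP^2 with
#' r_VP = 2.5 mm, w2 = 1/d_max^2 with d_max = 2 mm, r = 1/F_max^2 with
#' F_max = 1 N. Body dynamics m (kg), b (N s/m) and coupling stiffness k
#' (N/m) are order-of-magnitude arm/robot values.
#'
#' @param geometry `"asymmetric"` or `"symmetric"` preset, or supply VPs.
#' @param VP1,VP2 via-point positions (m); override the preset.
#' @param crossing_times named fractions of T for strategies E, M, L.
#' @param p_start,p_end endpoints (m).
#' @param r_VP,d_max,F_max Bryson maxima (m, m, N).
#' @param m,b,k body mass, damping and spring stiffness.
#' @return list of class `viapoint_config`.
#' @export
viapoint_config <- function(geometry = c("asymmetric", "symmetric"),
                            VP1 = NULL, VP2 = NULL, crossing_times = NULL,
                            p_start = c(-0.05, 0), p_end = c(0.05, 0),
                            r_VP = 2.5e-3, d_max = 2e-3, F_max = 1,
                            m = 1, b = 5, k = 30) {
  geometry <- match.arg(geometry)
  if (is.null(VP1)) VP1 <- if (geometry == "asymmetric") c(-0.02, -0.03) else c(0, -0.03)
  if (is.null(VP2)) VP2 <- if (geometry == "asymmetric") c(0.02, 0.03) else c(0, 0.03)
  if (is.null(crossing_times))
    crossing_times <- if (geometry == "asymmetric")
      c(E = 0.32, M = 0.5, L = 0.68) else c(E = 0.38, M = 0.5, L = 0.62)
  if (any(crossing_times <= 0) || any(crossing_times >= 1))
    stop("crossing times must lie strictly inside (0, T)")
  structure(list(geometry = geometry, VP1 = VP1, VP2 = VP2,
                 crossing_times = crossing_times, p_start = p_start,
                 p_end = p_end, w1 = 1 / r_VP^2, w2 = 1 / d_max^2,
                 r = 1 / F_max^2, m = m, b = b, k = k),
            class = "viapoint_config")
}

# Per-coordinate quadratic blocks of the 2-VP cost for one player and one
# crossing-time strategy. Returns blocks over the stacked (x, y) action.
.viapoint_blocks <- function(config, basis, vp, tau_s) {
  N <- basis$n_grid
  Mp <- crossprod(basis$Bp)
  D <- config$m * basis$Ba + config$b * basis$Bv + config$k * basis$Bp
  row_s <- basis_row(basis, tau_s, 0L)
  a <- row_s$b
  Qblk <- config$w1 * tcrossprod(a) + (config$w2 / N) * Mp +
    (config$r / N) * crossprod(D)
  Qcrossblk <- -(config$w2 / N) * Mp - (config$r / N) * config$k * crossprod(D, basis$Bp)
  Qotherblk <- ((config$w2 + config$r * config$k^2) / N) * Mp
  nf <- basis$n_free
  blk2 <- function(Bxy) rbind(cbind(Bxy, matrix(0, nf, nf)),
                              cbind(matrix(0, nf, nf), Bxy))
  r_own <- numeric(2L * nf); r_other <- numeric(2L * nf); z <- 0
  for (d in 1:2) {
    u0d <- basis$u0[d, ]
    c_s <- sum(row_s$c0 * u0d)
    f0 <- config$m * (basis$C0a %*% u0d) + config$b * (basis$C0v %*% u0d)
    idx <- (d - 1L) * nf + seq_len(nf)
    r_own[idx] <- config$w1 * (c_s - vp[d]) * a +
      (config$r / N) * as.numeric(crossprod(D, f0))
    r_other[idx] <- -(config$r / N) * config$k * as.numeric(crossprod(basis$Bp, f0))
    z <- z + 0.5 * config$w1 * (c_s - vp[d])^2 + (config$r / (2 * N)) * sum(f0^2)
  }
  list(Q_own = blk2(Qblk), Q_cross = blk2(Qcrossblk), Q_other = blk2(Qotherblk),
       r_own = r_own, r_other = r_other, z = z)
}

#' Assemble the 2-VP quadratic game
#'
#' For each crossing-time strategy s in {E, M, L} the cost
#' \deqn{J_i = \tfrac12 w_1 \|p_i(\tau_i(s)) - VP_i\|^2 + \tfrac1{2N}\sum_\tau
#'   [w_2 \|p_i - p_{-i}\|^2 + r \|F_i\|^2]}
#' (with the motor command F_i from the linear body dynamics, and the time sum
#' averaged over the basis grid of N samples) is expanded into quadratic
#' blocks over the two players' free-node actions.
#'
#' @param config a [viapoint_config()].
#' @param basis a [viapoint_basis()] (defaults to one built from the config's
#'   endpoints).
#' @return a [joint_game()]; each player's spec has strategies c("E","M","L").
#' @export
viapoint_game <- function(config = viapoint_config(),
                          basis = viapoint_basis(p_start = config$p_start,
                                                 p_end = config$p_end)) {
  specs <- lapply(1:2, function(i) {
    vp <- if (i == 1L) config$VP1 else config$VP2
    blocks <- lapply(config$crossing_times, function(f)
      .viapoint_blocks(config, basis, vp, f * basis$T))
    names(blocks) <- names(config$crossing_times)
    nd <- 2L * basis$n_free
    player_game_spec(strategies = names(blocks), n_own = nd, n_other = nd,
                     Q_own = lapply(blocks, `[[`, "Q_own"),
                     Q_cross = lapply(blocks, `[[`, "Q_cross"),
                     Q_other = lapply(blocks, `[[`, "Q_other"),
                     r_own = lapply(blocks, `[[`, "r_own"),
                     r_other = lapply(blocks, `[[`, "r_other"),
                     z = lapply(blocks, `[[`, "z"))
  })
  joint_game(specs[[1]], specs[[2]])
}

#' Direct (sampled-trajectory) evaluation of the 2-VP cost
#'
#' Independent of the quadratic-block expansion: reconstructs both sampled
#' trajectories and sums the via-point, distance and motor-command terms
#' numerically. Used as an oracle for [viapoint_game()].
#'
#' @param config a [viapoint_config()].
#' @param basis a [viapoint_basis()].
#' @param u_own,u_other free-node actions.
#' @param s strategy label ("E", "M" or "L").
#' @param player 1 or 2 (selects the own via-point).
#' @return scalar cost.
#' @export
viapoint_cost_direct <- function(config, basis, u_own, u_other, s, player = 1L) {
  tr1 <- sample_trajectory(basis, u_own)
  tr2 <- sample_trajectory(basis, u_other)
  vp <- if (player == 1L) config$VP1 else config$VP2
  tau_s <- config$crossing_times[[s]] * basis$T
  r0 <- basis_row(basis, tau_s, 0L)
  U <- matrix(u_own, basis$n_free, 2L)
  p_at <- as.numeric(r0$b %*% U) + as.numeric(r0$c0 %*% t(basis$u0))
  F_own <- motor_command(tr1, tr2, m = config$m, b = config$b, k = config$k)
  dd <- cbind(tr1$x - tr2$x, tr1$y - tr2$y)
  N <- basis$n_grid
  0.5 * config$w1 * sum((p_at - vp)^2) +
    (1 / (2 * N)) * sum(config$w2 * rowSums(dd^2) + config$r * rowSums(F_own^2))
}

#' Motor command implied by the body dynamics
#'
#' F = m p'' + b p' + k (p_own - p_other), per sample and coordinate.
#'
#' @param p_own,p_other sampled trajectories (data.frames from
#'   [sample_trajectory()], aligned grids).
#' @param m,b,k mass, damping, coupling stiffness.
#' @return n x 2 matrix of force samples (Fx, Fy).
#' @export
motor_command <- function(p_own, p_other, m, b, k) {
  if (nrow(p_own) != nrow(p_other) || max(abs(p_own$t - p_other$t)) > 1e-12)
    stop("trajectory grids are not aligned")
  cbind(Fx = m * p_own$ax + b * p_own$vx + k * (p_own$x - p_other$x),
        Fy = m * p_own$ay + b * p_own$vy + k * (p_own$y - p_other$y))
}

#' Spring interaction force on a player
#'
#' F_int = -k (p_own - p_other); antisymmetric between the two players.
#'
#' @param p_own,p_other sampled trajectories (aligned grids).
#' @param k spring stiffness (N/m).
#' @return n x 2 matrix of force samples.
#' @export
interaction_force <- function(p_own, p_other, k) {
  if (nrow(p_own) != nrow(p_other)) stop("trajectory grids are not aligned")
  cbind(Fx = -k * (p_own$x - p_other$x), Fy = -k * (p_own$y - p_other$y))
}

#' Scan all joint strategy pairs for pure Nash equilibria
#'
#' For every joint strategy pair, solves the conditional quadratic game and
#' checks whether either player could lower their cost by unilaterally
#' switching strategy (re-optimizing their continuous action against the
#' partner's equilibrium action).
#'
#' @param game a [joint_game()].
#' @param tol cost tolerance for the best-alternative comparison.
#' @return data.frame with one row per joint strategy pair: labels, both
#'   players' equilibrium costs, and `is_equilibrium`.
#' @export
pure_equilibria <- function(game, tol = 1e-9) {
  s1 <- game$specs[[1]]$strategies; s2 <- game$specs[[2]]$strategies
  grid <- expand.grid(s1 = s1, s2 = s2, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    js <- c(grid$s1[r], grid$s2[r])
    ne <- nash_equilibrium(game, js)
    ok <- TRUE
    for (i in 1:2) {
      x_other <- if (i == 1L) ne$u2 else ne$u1
      vals <- vapply(game$specs[[i]]$strategies, function(s)
        expected_cost(game$specs[[i]], x_other, 0, s)$q, numeric(1))
      scale <- max(1, abs(vals[js[i]]))
      if (vals[js[i]] > min(vals) + tol * scale) ok <- FALSE
    }
    data.frame(s1 = js[1], s2 = js[2], cost1 = ne$costs[1], cost2 = ne$costs[2],
               is_equilibrium = ok)
  })
  do.call(rbind, res)
}

#' Group pure equilibria by via-point crossing order
#'
#' The task's equilibrium solutions are paths on which both players cross
#' both via-points, either VP1 first or VP2 first; each path order is
#' realized by several crossing-time strategy labelings (e.g. VP1-first by
#' (E, M), (E, L) and (M, L)). This helper classifies every pure equilibrium
#' of [pure_equilibria()] by the order in which player 1's equilibrium
#' trajectory attains its closest approach to the two via-points, and reports
#' the distinct orders with the cheapest equilibrium realizing each.
#'
#' @param game a [joint_game()] built by [viapoint_game()].
#' @param config the [viapoint_config()] used.
#' @param basis the [viapoint_basis()] used.
#' @return list with `orders` (character vector of distinct crossing orders,
#'   "VP1-first"/"VP2-first"), `equilibria` (the scan table with an added
#'   `order` column), and `best` (per order, the minimum total cost).
#' @export
equilibrium_path_orders <- function(game, config = viapoint_config(),
                                    basis = viapoint_basis(p_start = config$p_start,
                                                           p_end = config$p_end)) {
  eq <- pure_equilibria(game)
  eq$order <- NA_character_
  for (r in which(eq$is_equilibrium)) {
    ne <- nash_equilibrium(game, c(eq$s1[r], eq$s2[r]))
    tr <- sample_trajectory(basis, ne$u1)
    tc <- vapply(list(config$VP1, config$VP2), function(vp)
      tr$t[which.min((tr$x - vp[1])^2 + (tr$y - vp[2])^2)], numeric(1))
    eq$order[r] <- if (tc[1] < tc[2]) "VP1-first" else "VP2-first"
  }
  keep <- eq[eq$is_equilibrium, , drop = FALSE]
  best <- tapply(keep$cost1 + keep$cost2, keep$order, min)
  list(orders = sort(unique(keep$order)), equilibria = eq, best = best)
}

#' Baseline 2-VP player parameters
#'
#' Spherical noises over the free-node coordinates ("noises affect equally
#' all the nodes"). The prior mean is the straight-path action: a player
#' initially expects the partner to move straight from start to target.
#' Default noise scales (per-node variance in m^2) correspond to sensing the
#' partner's node positions to about 0.5 cm (partner visible), with less
#' reliable sensing modeled by larger Sigma_y.
#'
#' @param basis a [viapoint_basis()].
#' @param Sigma_y sensory-noise variance per node coordinate (m^2).
#' @param Sigma_x internal-noise variance per node coordinate (m^2).
#' @param lambda1,a initial temperature and decay rate.
#' @param A,P0 retention and prior covariance.
#' @return a [player_params()].
#' @export
viapoint_params <- function(basis, Sigma_y = 2.5e-5, Sigma_x = 2.5e-5,
                            lambda1 = 1, a = 0.99, A = 0.99, P0 = 1e-6) {
  player_params(Sigma_y = Sigma_y, mu = straight_action(basis), P0 = P0,
                A = A, Sigma_x = Sigma_x, lambda1 = lambda1, a = a,
                dim = 2L * basis$n_free)
}

#' Full 2-VP session config
#'
#' @param config a [viapoint_config()].
#' @param basis a [viapoint_basis()].
#' @param Sigma_y,Sigma_x per-node noise variances (m^2); scalars.
#' @param ... further arguments to [viapoint_params()].
#' @return config list for [run_session()] / [simulate_dyads()], carrying the
#'   basis and scenario config as metadata.
#' @export
viapoint_session_config <- function(config = viapoint_config(),
                                    basis = viapoint_basis(p_start = config$p_start,
                                                           p_end = config$p_end),
                                    Sigma_y = 2.5e-5, Sigma_x = 2.5e-5, ...) {
  p <- viapoint_params(basis, Sigma_y = Sigma_y, Sigma_x = Sigma_x, ...)
  list(game = viapoint_game(config, basis), params = list(p, p),
       scenario = "viapoint", scenario_config = unclass(config), basis = basis)
}

#' Export simulated 2-VP trials as sampled recordings
#'
#' Reconstructs both players' trajectories for every trial of a simulated
#' session and emits the tidy 100 Hz table the metrics stage consumes — the
#' same shape a recorded experiment would have: one row per trial, player and
#' sample with position and interaction force.
#'
#' @param series a `dyad_series` from a 2-VP session.
#' @param basis the [viapoint_basis()] used (defaults to the one stored in
#'   the series config).
#' @param k coupling stiffness used for the interaction force (defaults to
#'   the scenario config's).
#' @return data.frame with columns trial, player, t, x, y, Fx, Fy.
#' @export
viapoint_recordings <- function(series, basis = series$config$basis,
                                k = series$config$scenario_config$k) {
  if (is.null(basis)) stop("no spline basis available")
  out <- vector("list", 2L * series$n_trials)
  for (tr in seq_len(series$n_trials)) {
    t1 <- sample_trajectory(basis, series$players[[1]]$u[tr, ])
    t2 <- sample_trajectory(basis, series$players[[2]]$u[tr, ])
    F1 <- interaction_force(t1, t2, k)
    F2 <- interaction_force(t2, t1, k)
    out[[2L * tr - 1L]] <- data.frame(trial = tr, player = 1L, t = t1$t,
                                      x = t1$x, y = t1$y, Fx = F1[, 1], Fy = F1[, 2])
    out[[2L * tr]] <- data.frame(trial = tr, player = 2L, t = t2$t,
                                 x = t2$x, y = t2$y, Fx = F2[, 1], Fy = F2[, 2])
  }
  do.call(rbind, out)
}
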