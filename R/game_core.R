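# Quadratic games with discrete strategy choice: representation, deterministic
# cost, closed-form Nash solution, and the expected-cost decomposition under a
# Gaussian belief about the partner's action.

.as_mat <- function(x, nr, nc, what) {
  if (is.null(x)) x <- matrix(0, nr, nc)
  if (length(x) == 1L && !is.matrix(x)) x <- diag(as.numeric(x), nr, nc)
  x <- as.matrix(x)
  if (nrow(x) != nr || ncol(x) != nc)
    stop(sprintf("'%s' must be %dx%d, got %dx%d", what, nr, nc, nrow(x), ncol(x)))
  x
}

.as_vec <- function(x, n, what) {
  if (is.null(x)) x <- rep(0, n)
  x <- as.numeric(x)
  if (length(x) == 1L && n > 1L) x <- rep(x, n)
  if (length(x) != n) stop(sprintf("'%s' must have length %d", what, n))
  x
}

.check_pd <- function(Q, label) {
  if (max(abs(Q - t(Q))) > 1e-8 * max(1, max(abs(Q))))
    stop(sprintf("%s must be symmetric", label))
  ev <- eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("%s must be positive definite (competitive/non-PD games are unsupported)", label))
  if (min(ev) < max(ev) / 1e12)
    stop(sprintf("%s is numerically singular (condition number > 1e12)", label))
  invisible(ev)
}

#' One player's quadratic game specification
#'
#' Represents the cost function of one player in a static quadratic game,
#' optionally indexed by a discrete strategy. For strategy \eqn{s} the cost of
#' playing \eqn{u} against partner action \eqn{u'} is
#' \deqn{J(u, u', s) = \tfrac12 u^T Q_{own}(s) u + u^T Q_{cross}(s) u' +
#'   \tfrac12 u'^T Q_{other}(s) u' + r_{own}(s)^T u + r_{other}(s)^T u' + z(s).}
#' Each \eqn{Q_{own}(s)} must be symmetric positive definite, so the player's
#' conditional best response is unique and the Boltzmann action density is a
#' (mixture of) Gaussian(s).
#'
#' @param strategies character vector of strategy labels (length M >= 1).
#' @param n_own,n_other own / partner action dimensions.
#' @param Q_own,Q_cross,Q_other,r_own,r_other,z either a single value (shared
#'   by all strategies) or a list keyed by strategy label. Scalars are expanded
#'   to scaled identities / constant vectors; NULL means zero.
#' @return an object of class `player_game_spec`.
#' @export
player_game_spec <- function(strategies = "s1", n_own, n_other,
                             Q_own, Q_cross = NULL, Q_other = NULL,
                             r_own = NULL, r_other = NULL, z = NULL) {
  strategies <- as.character(strategies)
  if (length(strategies) < 1L || anyDuplicated(strategies))
    stop("'strategies' must be a non-empty set of unique labels")
  pick <- function(x, s) if (is.list(x) && !is.matrix(x)) x[[s]] else x
  blocks <- list()
  for (s in strategies) {
    Qo <- .as_mat(pick(Q_own, s), n_own, n_own, "Q_own")
    .check_pd(Qo, sprintf("Q_own('%s')", s))
    Qot <- .as_mat(pick(Q_other, s), n_other, n_other, "Q_other")
    if (max(abs(Qot - t(Qot))) > 1e-8 * max(1, max(abs(Qot))))
      stop(sprintf("Q_other('%s') must be symmetric", s))
    blocks[[s]] <- list(
      Q_own   = Qo,
      Q_cross = .as_mat(pick(Q_cross, s), n_own, n_other, "Q_cross"),
      Q_other = Qot,
      r_own   = .as_vec(pick(r_own, s), n_own, "r_own"),
      r_other = .as_vec(pick(r_other, s), n_other, "r_other"),
      z       = as.numeric(pick(z, s) %||% 0),
      chol_Q  = chol(Qo))
    blocks[[s]]$logdet_Q <- 2 * sum(log(diag(blocks[[s]]$chol_Q)))
  }
  structure(list(strategies = strategies, n_own = n_own, n_other = n_other,
                 blocks = blocks),
            class = "player_game_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.spec_block <- function(spec, s) {
  b <- spec$blocks[[as.character(s)]]
  if (is.null(b)) stop(sprintf("unknown strategy label '%s'", s))
  b
}

#' @export
print.player_game_spec <- function(x, ...) {
  cat(sprintf("Quadratic game spec: %d-dim own action vs %d-dim partner, %d strateg%s (%s)\n",
              x$n_own, x$n_other, length(x$strategies),
              if (length(x$strategies) == 1L) "y" else "ies",
              paste(x$strategies, collapse = ", ")))
  invisible(x)
}

#' Realized (deterministic) cost of a pair of actions
#'
#' @param spec a [player_game_spec()].
#' @param u_own,u_other the two realized action vectors.
#' @param s strategy label (defaults to the only strategy for M = 1 games).
#' @return scalar cost.
#' @export
deterministic_cost <- function(spec, u_own, u_other, s = spec$strategies[1L]) {
  b <- .spec_block(spec, s)
  u1 <- .as_vec(u_own, spec$n_own, "u_own")
  u2 <- .as_vec(u_other, spec$n_other, "u_other")
  as.numeric(0.5 * crossprod(u1, b$Q_own %*% u1) + crossprod(u1, b$Q_cross %*% u2) +
             0.5 * crossprod(u2, b$Q_other %*% u2) +
             sum(b$r_own * u1) + sum(b$r_other * u2) + b$z)
}

#' Two-player joint quadratic game
#'
#' Couples two [player_game_spec()]s into one game; player 1's partner is
#' player 2 and vice versa, so `spec1$n_other == spec2$n_own` etc.
#'
#' @param spec1,spec2 the two players' specs.
#' @return object of class `joint_game`.
#' @export
joint_game <- function(spec1, spec2) {
  if (spec1$n_other != spec2$n_own || spec2$n_other != spec1$n_own)
    stop("player specs have inconsistent action dimensions")
  structure(list(specs = list(spec1, spec2)), class = "joint_game")
}

#' @export
print.joint_game <- function(x, ...) {
  cat("Two-player quadratic game\n")
  print(x$specs[[1]]); print(x$specs[[2]])
  invisible(x)
}

#' Closed-form Nash equilibrium for a joint strategy pair
#'
#' Stacks both players' first-order conditions into one linear system
#' \eqn{R u^* = -r} and solves it. At the returned point each player's own-cost
#' gradient, holding the partner fixed, is zero; positive-definite own blocks
#' make it the unique equilibrium of the (conditional) game.
#'
#' @param game a [joint_game()].
#' @param joint_strategy length-2 character vector (player 1's, player 2's
#'   strategy); defaults to first-listed strategies.
#' @return list with `u1`, `u2` (equilibrium actions) and `costs` (each
#'   player's realized cost at the equilibrium).
#' @export
nash_equilibrium <- function(game,
                             joint_strategy = c(game$specs[[1]]$strategies[1L],
                                                game$specs[[2]]$strategies[1L])) {
  b1 <- .spec_block(game$specs[[1]], joint_strategy[1L])
  b2 <- .spec_block(game$specs[[2]], joint_strategy[2L])
  n1 <- game$specs[[1]]$n_own; n2 <- game$specs[[2]]$n_own
  R <- rbind(cbind(b1$Q_own, b1$Q_cross),
             cbind(b2$Q_cross, b2$Q_own))
  r <- c(b1$r_own, b2$r_own)
  if (rcond(R) < 1e-12)
    stop("stacked system matrix is singular; no unique equilibrium")
  u <- unname(solve(R, -r))
  u1 <- u[seq_len(n1)]; u2 <- u[n1 + seq_len(n2)]
  list(u1 = u1, u2 = u2,
       costs = c(deterministic_cost(game$specs[[1]], u1, u2, joint_strategy[1L]),
                 deterministic_cost(game$specs[[2]], u2, u1, joint_strategy[2L])))
}

#' Expected cost under a Gaussian partner belief
#'
#' Averages the quadratic cost over the partner action \eqn{u' \sim N(x, P)}.
#' The expectation is again quadratic in the own action and is returned in the
#' completed-square form
#' \deqn{E\{J\}(u) = \tfrac12 (u - u^*)^T Q_{own} (u - u^*) + q(s, x, P),}
#' with \eqn{u^* = -Q_{own}^{-1}(Q_{cross} x + r_{own})} the conditional
#' optimum and the residual \eqn{q} carrying the partner-uncertainty penalty
#' \eqn{\tfrac12 \mathrm{tr}(Q_{other} P)}.
#'
#' @param spec a [player_game_spec()].
#' @param x belief mean over the partner's action.
#' @param P belief covariance (scalar = spherical), symmetric PSD.
#' @param s strategy label.
#' @return list of class `expected_cost` with `u_star`, `q`, `Q_own`.
#' @export
expected_cost <- function(spec, x, P = 0, s = spec$strategies[1L]) {
  b <- .spec_block(spec, s)
  x <- .as_vec(x, spec$n_other, "x")
  P <- .as_mat(P, spec$n_other, spec$n_other, "P")
  evP <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evP) < -1e-8 * max(1, max(abs(evP))))
    stop("belief covariance P must be positive semidefinite")
  rhs <- b$Q_cross %*% x + b$r_own
  u_star <- -backsolve(b$chol_Q, backsolve(b$chol_Q, rhs, transpose = TRUE))
  q <- as.numeric(0.5 * crossprod(x, b$Q_other %*% x) + 0.5 * sum(b$Q_other * P) +
                  sum(b$r_other * x) + b$z -
                  0.5 * crossprod(u_star, b$Q_own %*% u_star))
  structure(list(u_star = as.numeric(u_star), q = q, Q_own = b$Q_own),
            class = "expected_cost")
}

#' Serialize / deserialize a game spec
#'
#' Game specs round-trip through a plain nested-list form (numeric arrays
#' keyed by strategy) suitable for YAML/JSON configs.
#'
#' @param spec a [player_game_spec()].
#' @return for `spec_to_list`, a plain list; `spec_from_list` inverts it.
#' @export
spec_to_list <- function(spec) {
  rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  list(strategies = spec$strategies, n_own = spec$n_own, n_other = spec$n_other,
       blocks = lapply(spec$blocks, function(b)
         list(Q_own = rows(b$Q_own), Q_cross = rows(b$Q_cross),
              Q_other = rows(b$Q_other),
              r_own = b$r_own, r_other = b$r_other, z = b$z)))
}

#' @rdname spec_to_list
#' @param x a list produced by `spec_to_list` (possibly via YAML/JSON).
#' @export
spec_from_list <- function(x) {
  g <- function(f) lapply(x$blocks, function(b) {
    v <- b[[f]]
    if (f %in% c("Q_own", "Q_cross", "Q_other"))
      do.call(rbind, lapply(v, as.numeric))
    else if (f == "z") as.numeric(v) else as.numeric(unlist(v))
  })
  player_game_spec(strategies = x$strategies, n_own = x$n_own, n_other = x$n_other,
                   Q_own = g("Q_own"), Q_cross = g("Q_cross"), Q_other = g("Q_other"),
                   r_own = g("r_own"), r_other = g("r_other"), z = g("z"))
}
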