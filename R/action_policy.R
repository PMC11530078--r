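# Stochastic strategy/action selection: Boltzmann (softmax) distribution over
# the expected cost given the partner belief, with geometric temperature decay.

.LAMBDA_MIN <- 1e-12

#' Per-trial state of the stochastic action policy
#'
#' @param lam current temperature (cost units), must be positive.
#' @param trial_index trial counter.
#' @return object of class `policy_state`.
#' @export
policy_state <- function(lam, trial_index = 1L) {
  if (!(lam > 0)) stop("temperature 'lam' must be positive")
  structure(list(lam = as.numeric(lam), trial_index = as.integer(trial_index)),
            class = "policy_state")
}

#' Boltzmann strategy-choice probabilities
#'
#' Marginalizing the Boltzmann density over the continuous action gives, for
#' positive-definite own-curvature blocks,
#' \deqn{\Pr(s) \propto |Q_{own}(s)|^{-1/2} \exp\{-q(s, x, P)/\lambda\},}
#' where \eqn{q} is the residual expected cost at the conditional optimum
#' (see [expected_cost()]). Computed with log-sum-exp stabilization.
#'
#' @param spec a [player_game_spec()].
#' @param x,P partner-belief mean and covariance.
#' @param lam temperature (> 0).
#' @return named probability vector over the spec's strategies (sums to 1).
#' @export
strategy_probabilities <- function(spec, x, P = 0, lam) {
  if (!(lam > 0)) stop("temperature 'lam' must be positive")
  lam <- max(lam, .LAMBDA_MIN)
  logw <- vapply(spec$strategies, function(s) {
    b <- .spec_block(spec, s)
    ec <- expected_cost(spec, x, P, s)
    -0.5 * b$logdet_Q - ec$q / lam
  }, numeric(1))
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  names(p) <- spec$strategies
  p
}

#' Sample a (strategy, action) pair from the Boltzmann policy
#'
#' Draws the strategy from [strategy_probabilities()], then the action from
#' the conditional Gaussian \eqn{N(u^*(s, x), \lambda Q_{own}(s)^{-1})}. The
#' covariance scales with the temperature and with the inverse cost curvature,
#' so variability concentrates along task-irrelevant (low-curvature)
#' directions — a minimum-intervention-style signature. Uses the current RNG
#' state; at temperatures at or below the floor (1e-12) the most probable
#' strategy and its conditional optimum are returned deterministically (ties
#' break to the first-listed strategy).
#'
#' @inheritParams strategy_probabilities
#' @return list with `s` (label), `u` (action), `probs` (strategy
#'   probabilities used).
#' @export
sample_action <- function(spec, x, P = 0, lam) {
  probs <- strategy_probabilities(spec, x, P, lam)
  if (lam <= .LAMBDA_MIN) {
    s <- spec$strategies[which.max(probs)]
    return(list(s = s, u = expected_cost(spec, x, P, s)$u_star, probs = probs))
  }
  s <- if (length(probs) == 1L) spec$strategies else
    sample(spec$strategies, 1L, prob = probs)
  b <- .spec_block(spec, s)
  u_star <- expected_cost(spec, x, P, s)$u_star
  zdraw <- stats::rnorm(spec$n_own)
  u <- u_star + sqrt(lam) * backsolve(b$chol_Q, zdraw)
  list(s = s, u = as.numeric(u), probs = probs)
}

#' Geometric temperature decay
#'
#' lam' = a * lam, applied once per trial after action selection; a floor of
#' 1e-12 keeps long runs numerically non-degenerate.
#'
#' @param state a [policy_state()].
#' @param a decay rate, 0 < a <= 1.
#' @return updated [policy_state()] with incremented trial index.
#' @export
decay_temperature <- function(state, a) {
  if (!(a > 0 && a <= 1)) stop("'a' must satisfy 0 < a <= 1")
  policy_state(max(a * state$lam, .LAMBDA_MIN), state$trial_index + 1L)
}
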