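# Spatial Stag Hunt: a 1-D, two-strategy quadratic game. Each player moves a
# cursor toward either a "rabbit" (safe, partner-independent payoff) or a
# "stag" (better payoff, but only if both players go for it). The curvature
# weight and the two offsets are calibrated from the game's cost matrix.

#' Calibrate the Stag Hunt cost parameters from a cost matrix
#'
#' The four corner costs (rabbit row is partner-independent) uniquely
#' determine the quadratic weight and the two offsets:
#' z_R = J(R, .), z_S = J(S, S), w = 2 (J(S, R) - z_S) / |u_R - u_S|^2.
#'
#' @param cost_matrix numeric vector of the four corner costs, in the order
#'   J(rabbit, rabbit), J(rabbit, stag), J(stag, rabbit), J(stag, stag); may
#'   be named. The two rabbit-row entries must be equal and the stag-hunt
#'   ordering J(S,R) > J(R,.) > J(S,S) must hold.
#' @param u_R,u_S rabbit and stag positions (workspace units), distinct.
#' @return list (w, z_R, z_S).
#' @export
stag_hunt_calibrate <- function(cost_matrix, u_R, u_S) {
  if (u_R == u_S) stop("rabbit and stag positions must be distinct")
  cm <- as.numeric(cost_matrix)
  if (length(cm) != 4L) stop("'cost_matrix' must contain four corner costs")
  J_RR <- cm[1L]; J_RS <- cm[2L]; J_SR <- cm[3L]; J_SS <- cm[4L]
  if (abs(J_RR - J_RS) > 1e-12)
    stop("rabbit cost must be independent of the partner (J(R,R) == J(R,S))")
  if (!(J_SR > J_RR && J_RR > J_SS))
    stop("not a stag hunt: need J(S,R) > J(R,.) > J(S,S)")
  list(w = 2 * (J_SR - J_SS) / (u_R - u_S)^2, z_R = J_RR, z_S = J_SS)
}

#' Spatial Stag Hunt scenario configuration
#'
#' @param u_R,u_S rabbit and stag positions. Defaults place them
#'   symmetrically about the origin (spacing 2), so the zero prior belief is
#'   equidistant from both targets.
#' @param cost_matrix corner costs, see [stag_hunt_calibrate()]; default
#'   (5, 5, 10, 1).
#' @param form which stag-branch coupling to build: `"partner_distance"`
#'   (default; the stag cost penalizes the distance between the two players)
#'   or `"stag_distance"` (penalizes each player's distance to the stag; an
#'   uncoupled variant that reproduces the same corner costs).
#' @return list of class `stag_hunt_config` with the calibrated (w, z_R, z_S).
#' @export
stag_hunt_config <- function(u_R = -1, u_S = 1, cost_matrix = c(5, 5, 10, 1),
                             form = c("partner_distance", "stag_distance")) {
  form <- match.arg(form)
  cal <- stag_hunt_calibrate(cost_matrix, u_R, u_S)
  structure(list(u_R = u_R, u_S = u_S, cost_matrix = as.numeric(cost_matrix),
                 w = cal$w, z_R = cal$z_R, z_S = cal$z_S, form = form),
            class = "stag_hunt_config")
}

#' Build the Stag Hunt quadratic game
#'
#' Constructs the per-strategy cost blocks for one player. With the decision
#' variable s = 1 for "rabbit" and s = 0 for "stag", the default block form
#' is (per player):
#' Q_own = s w + 2 (1-s) w; Q_cross = -(1-s) w; Q_other = (1-s) w;
#' r_own = -s w u_R - (1-s) w u_S; r_other = 0;
#' z = s (w u_R^2 / 2 + z_R) + (1-s) (w u_S^2 / 2 + z_S).
#' The stag branch thus expands to
#' w/2 (u - u_S)^2 + w/2 (u - u')^2 + z_S: own distance to the stag plus
#' distance to the partner. The `"stag_distance"` form instead uses
#' w/2 (u - u_S)^2 + w/2 (u' - u_S)^2 + z_S (both distances to the stag,
#' no cross-coupling); both reproduce the corner cost matrix exactly.
#'
#' @param config a [stag_hunt_config()] (or arguments to build one).
#' @return a [joint_game()] whose two identical specs have strategies
#'   `c("rabbit", "stag")`.
#' @export
stag_hunt_game <- function(config = stag_hunt_config()) {
  w <- config$w; u_R <- config$u_R; u_S <- config$u_S
  z_R <- config$z_R; z_S <- config$z_S
  blocks <- if (config$form == "partner_distance") {
    list(Q_own  = list(rabbit = w, stag = 2 * w),
         Q_cross = list(rabbit = 0, stag = -w),
         Q_other = list(rabbit = 0, stag = w),
         r_own  = list(rabbit = -w * u_R, stag = -w * u_S),
         r_other = list(rabbit = 0, stag = 0),
         z = list(rabbit = 0.5 * w * u_R^2 + z_R, stag = 0.5 * w * u_S^2 + z_S))
  } else {
    list(Q_own  = list(rabbit = w, stag = w),
         Q_cross = list(rabbit = 0, stag = 0),
         Q_other = list(rabbit = 0, stag = w),
         r_own  = list(rabbit = -w * u_R, stag = -w * u_S),
         r_other = list(rabbit = 0, stag = -w * u_S),
         z = list(rabbit = 0.5 * w * u_R^2 + z_R,
                  stag = 0.5 * w * u_S^2 + 0.5 * w * u_S^2 + z_S))
  }
  spec <- player_game_spec(strategies = c("rabbit", "stag"), n_own = 1L,
                           n_other = 1L, Q_own = blocks$Q_own,
                           Q_cross = blocks$Q_cross, Q_other = blocks$Q_other,
                           r_own = blocks$r_own, r_other = blocks$r_other,
                           z = blocks$z)
  joint_game(spec, spec)
}

#' Baseline Stag Hunt player parameters
#'
#' The printed baseline: mu = 0, P0 = eps (near-deterministic prior),
#' A = 0.99, lambda1 = 0.1, a = 0.999, with the sensory and internal noise
#' variances as the swept factors (each either 0.1 or 10 in the convergence
#' map).
#'
#' @param Sigma_y,Sigma_x noise variances.
#' @param P0_eps prior covariance epsilon (default 1e-6).
#' @return a [player_params()].
#' @export
stag_hunt_params <- function(Sigma_y = 0.1, Sigma_x = 0.1, P0_eps = 1e-6) {
  player_params(Sigma_y = Sigma_y, mu = 0, P0 = P0_eps, A = 0.99,
                Sigma_x = Sigma_x, lambda1 = 0.1, a = 0.999, dim = 1L)
}

#' Full Stag Hunt session config
#'
#' @inheritParams stag_hunt_params
#' @param config a [stag_hunt_config()].
#' @return config list consumable by [run_session()] / [simulate_dyads()].
#' @export
stag_hunt_session_config <- function(Sigma_y = 0.1, Sigma_x = 0.1,
                                     config = stag_hunt_config()) {
  p <- stag_hunt_params(Sigma_y, Sigma_x)
  list(game = stag_hunt_game(config), params = list(p, p),
       scenario = "staghunt", scenario_config = unclass(config))
}
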