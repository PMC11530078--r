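# Bayesian partner-action prediction: noisy sensing of the partner's realized
# action and a trial-wise Kalman update of the belief (mean x, covariance P).

.param_mat <- function(x, d) {
  if (is.null(x)) return(matrix(0, d, d))
  if (length(x) == 1L && !is.matrix(x)) return(diag(as.numeric(x), d))
  .as_mat(x, d, d, "parameter matrix")
}

#' Behavioral parameters of one player
#'
#' The seven parameters governing one player's perception, partner model and
#' action selection, plus the sensory map H:
#' \describe{
#'   \item{Sigma_y}{sensory-noise covariance (action units squared); how
#'     unreliable the player's sensing of the partner is.}
#'   \item{mu, P0}{mean and covariance of the initial (prior) partner belief.}
#'   \item{A}{retention rate of the partner model (0 = memoryless prior,
#'     1 = stationary-partner belief).}
#'   \item{Sigma_x}{internal/process-noise covariance; the player's belief in
#'     partner erraticness.}
#'   \item{lambda1, a}{initial Boltzmann temperature (cost units) and its
#'     per-trial geometric decay rate (0 < a <= 1).}
#' }
#' Scalars are interpreted as spherical (scalar times identity), the
#' configuration in which the player has exactly 7 free scalar parameters;
#' full matrices are accepted for Sigma_y, P0, A, Sigma_x and H.
#'
#' @param Sigma_y,mu,P0,A,Sigma_x,lambda1,a see above.
#' @param H sensory map from partner action to observation; default identity.
#' @param dim partner action dimension (default: inferred from mu, else 1).
#' @return object of class `player_params`.
#' @export
player_params <- function(Sigma_y, mu = 0, P0 = 1e-6, A = 1, Sigma_x = 0,
                          lambda1 = 0.1, a = 0.999, H = NULL, dim = NULL) {
  d <- dim %||% if (length(mu) > 1L) length(mu) else 1L
  raw <- list(Sigma_y = Sigma_y, mu = mu, P0 = P0, A = A, Sigma_x = Sigma_x,
              lambda1 = lambda1, a = a)
  p <- list(Sigma_y = Sigma_y, mu = .as_vec(mu, d, "mu"), P0 = P0, A = A,
            Sigma_x = Sigma_x, lambda1 = as.numeric(lambda1), a = as.numeric(a),
            H = H %||% diag(d), dim = d,
            free_counts = vapply(raw, length, integer(1)))
  for (nm in c("Sigma_y", "P0", "Sigma_x")) {
    m <- .param_mat(p[[nm]], d)
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(1, max(abs(ev))))
      stop(sprintf("'%s' must be positive semidefinite", nm))
  }
  if (!(p$a > 0 && p$a <= 1)) stop("'a' must satisfy 0 < a <= 1")
  if (p$lambda1 <= 0) stop("'lambda1' must be positive")
  structure(p, class = "player_params")
}

#' @export
print.player_params <- function(x, ...) {
  sc <- function(v) if (length(v) == 1L && !is.matrix(v)) format(v) else "<matrix>"
  cat(sprintf(
    "Player parameters (%d-dim partner action):\n  Sigma_y=%s mu=%s P0=%s A=%s Sigma_x=%s lambda1=%g a=%g\n",
    x$dim, sc(x$Sigma_y), paste(signif(x$mu, 4), collapse = ","), sc(x$P0),
    sc(x$A), sc(x$Sigma_x), x$lambda1, x$a))
  invisible(x)
}

#' Number of free scalar parameters of a player
#'
#' In the spherical-covariance configuration every parameter is a single
#' scalar and a player is fully described by 7 numbers.
#'
#' @param params a [player_params()].
#' @return integer count of free scalars.
#' @export
n_free_parameters <- function(params) {
  as.integer(sum(params$free_counts))
}

#' Running belief about the partner's next action
#'
#' @param x predicted partner-action mean.
#' @param P prediction covariance.
#' @param K last Kalman gain used (NULL before the first update).
#' @return object of class `partner_belief`.
#' @export
partner_belief <- function(x, P, K = NULL) {
  d <- length(x)
  P <- .param_mat(P, d)
  structure(list(x = as.numeric(x), P = (P + t(P)) / 2, K = K),
            class = "partner_belief")
}

#' Initial belief implied by a parameter set
#' @param params a [player_params()].
#' @return a [partner_belief()] at (mu, P0).
#' @export
initial_belief <- function(params) partner_belief(params$mu, .param_mat(params$P0, params$dim))

#' Noisy sensory observation of the partner's action
#'
#' Draws y = H u' + v with v ~ N(0, Sigma_y), using the current RNG state.
#'
#' @param u_other partner's realized action.
#' @param H sensory map.
#' @param Sigma_y sensory-noise covariance (scalar = spherical).
#' @return observation vector.
#' @export
observe <- function(u_other, H, Sigma_y) {
  u_other <- as.numeric(u_other)
  if (length(H) == 1L && !is.matrix(H)) H <- diag(as.numeric(H), length(u_other))
  H <- .as_mat(H, nrow(H), length(u_other), "H")
  m <- nrow(H)
  S <- .param_mat(Sigma_y, m)
  y <- as.numeric(H %*% u_other)
  if (any(S != 0)) {
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), m)
    y <- y + as.numeric(L %*% stats::rnorm(m))
  } else {
    # burn no RNG draws in the noiseless case
  }
  y
}

#' Kalman gain
#'
#' K = P H' (H P H' + Sigma_y)^{-1}.
#'
#' @param P prior covariance.
#' @param H sensory map.
#' @param Sigma_y sensory-noise covariance.
#' @return gain matrix.
#' @export
kalman_gain <- function(P, H, Sigma_y) {
  d <- nrow(as.matrix(P))
  P <- .param_mat(P, d)
  H <- as.matrix(H)
  S <- .param_mat(Sigma_y, nrow(H))
  if (max(abs(S)) == 0 && nrow(H) == ncol(H) && rcond(H) > 1e-12)
    return(solve(H))            # noiseless sensing: full correction
  if (max(abs(P)) == 0) return(matrix(0, d, nrow(H)))  # fully confident prior
  innov <- H %*% P %*% t(H) + S
  if (rcond(innov) < 1e-14) stop("singular innovation covariance")
  t(solve(innov, H %*% P))
}

#' One trial-wise Kalman update of the partner belief
#'
#' Applies the printed correct-then-propagate form: the corrected estimate
#' x + K (y - H x) is passed through the retention dynamics A, and the
#' covariance follows P' = A (I - K H) P A' + Sigma_x (symmetrized after the
#' update for numerical hygiene).
#'
#' @param belief a [partner_belief()].
#' @param y the observation for this trial.
#' @param params a [player_params()].
#' @return the updated [partner_belief()], with the gain used in `$K`.
#' @export
kalman_step <- function(belief, y, params) {
  d <- length(belief$x)
  A <- if (length(params$A) == 1L && !is.matrix(params$A))
    diag(as.numeric(params$A), d) else as.matrix(params$A)
  H <- as.matrix(params$H)
  K <- kalman_gain(belief$P, H, params$Sigma_y)
  x_new <- as.numeric(A %*% (belief$x + K %*% (as.numeric(y) - H %*% belief$x)))
  P_new <- A %*% (diag(d) - K %*% H) %*% belief$P %*% t(A) + .param_mat(params$Sigma_x, d)
  partner_belief(x_new, (P_new + t(P_new)) / 2, K = K)
}
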