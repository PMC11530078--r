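# Maximum-likelihood identification of the seven behavioral parameters of one
# player from a dyad's per-trial action series. The partner-model filter is
# replayed over the player's sensory observation series (for simulated data,
# the logged observations; for recordings, the partner's actions are the
# natural plug-in), and each observed own action is scored under the
# Gaussian-mixture Boltzmann policy implied by the filtered belief and the
# annealed temperature.

.check_spherical <- function(params) {
  for (nm in c("Sigma_y", "P0", "A", "Sigma_x"))
    if (length(params[[nm]]) != 1L || is.matrix(params[[nm]]))
      stop("identification requires the spherical/scalar parameter configuration")
  if (!isTRUE(all.equal(unname(as.matrix(params$H)), diag(params$dim))))
    stop("identification assumes an identity sensory map H")
}

.lik_precomp <- function(spec) {
  lapply(spec$strategies, function(s) {
    b <- .spec_block(spec, s)
    list(Q = b$Q_own, logdetQ = b$logdet_Q,
         M1 = backsolve(b$chol_Q, backsolve(b$chol_Q, b$Q_cross, transpose = TRUE)),
         m0 = as.numeric(backsolve(b$chol_Q, backsolve(b$chol_Q, b$r_own,
                                                       transpose = TRUE))),
         Qo = b$Q_other, trQo = sum(diag(b$Q_other)), r_other = b$r_other,
         z = b$z)
  })
}

# Spherical-filter replay: returns belief means X (T x d) and variances Pv
# (length T) *before* each trial's update, i.e. the belief the action at
# trial t was drawn from.
.filter_replay <- function(obs, mu, P0, A, Sigma_x, Sigma_y) {
  T_ <- nrow(obs); d <- ncol(obs)
  X <- matrix(0, T_, d); Pv <- numeric(T_)
  x <- rep(mu, length.out = d); p <- P0
  for (t in seq_len(T_)) {
    X[t, ] <- x; Pv[t] <- p
    K <- p / (p + Sigma_y)
    x <- A * (x + K * (obs[t, ] - x))
    p <- A^2 * (1 - K) * p + Sigma_x
  }
  list(X = X, Pv = Pv)
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Log-likelihood of an observed action series
#'
#' Replays the partner-model Kalman filter forward over the player's sensory
#' observation series and scores each observed own action under the mixture
#' density \eqn{\sum_s \Pr(s | x_t, P_t, \lambda_t) N(u_t; u^*(s, x_t),
#' \lambda_t Q_{own}(s)^{-1})} with \eqn{\lambda_t = \lambda_1 a^{t-1}}
#' (floored at 1e-12). Requires the spherical/scalar parameter configuration
#' and an identity sensory map.
#'
#' @param params a [player_params()] with scalar parameters.
#' @param own_actions T x d matrix (or vector) of the player's actions.
#' @param partner_obs T x d matrix of the player's sensory observations of
#'   the partner (for simulated data the engine's logged `y`; for recordings
#'   the partner's actions).
#' @param spec the player's [player_game_spec()].
#' @return scalar log-likelihood.
#' @export
action_loglik <- function(params, own_actions, partner_obs, spec) {
  .check_spherical(params)
  own <- as.matrix(own_actions); obs <- as.matrix(partner_obs)
  if (nrow(own) != nrow(obs)) stop("own and observation series must be aligned")
  parts <- .action_density_parts(params, own, obs, spec)
  sum(parts$logdens)
}

# Shared workhorse: per-trial mixture log-density and per-trial strategy
# probabilities / conditional means.
.action_density_parts <- function(params, own, obs, spec) {
  T_ <- nrow(own); d <- ncol(own)
  pre <- .lik_precomp(spec); nS <- length(pre)
  fr <- .filter_replay(obs, params$mu, as.numeric(params$P0), as.numeric(params$A),
                       as.numeric(params$Sigma_x), as.numeric(params$Sigma_y))
  X <- fr$X; Pv <- fr$Pv
  lam <- pmax(params$lambda1 * params$a^(seq_len(T_) - 1L), 1e-12)
  logw <- matrix(0, T_, nS); logN <- matrix(0, T_, nS)
  Ustars <- vector("list", nS)
  for (k in seq_len(nS)) {
    pk <- pre[[k]]
    Ustar <- -(X %*% t(pk$M1) + matrix(pk$m0, T_, d, byrow = TRUE))
    Ustars[[k]] <- Ustar
    q <- 0.5 * rowSums((X %*% pk$Qo) * X) + 0.5 * Pv * pk$trQo +
      as.numeric(X %*% pk$r_other) + pk$z -
      0.5 * rowSums((Ustar %*% pk$Q) * Ustar)
    logw[, k] <- -0.5 * pk$logdetQ - q / lam
    resid <- own - Ustar
    logN[, k] <- -0.5 * d * log(2 * pi * lam) + 0.5 * pk$logdetQ -
      rowSums((resid %*% pk$Q) * resid) / (2 * lam)
  }
  logPr <- logw - .logsumexp_rows(logw)
  logdens <- .logsumexp_rows(logPr + logN)
  list(logdens = logdens, logPr = logPr, Ustars = Ustars, X = X, Pv = Pv)
}

#' Model-predicted action series
#'
#' Per trial, the mixture mean \eqn{\sum_s \Pr(s | x_t) u^*(s, x_t)} of the
#' action density implied by the replayed filter; the series compared with
#' the observed actions in the goodness-of-fit R-squared.
#'
#' @inheritParams action_loglik
#' @return T x d matrix of predicted action means.
#' @export
predicted_actions <- function(params, partner_obs, spec) {
  .check_spherical(params)
  obs <- as.matrix(partner_obs)
  own0 <- matrix(0, nrow(obs), spec$n_own)   # own actions unused for prediction
  parts <- .action_density_parts(params, own0, obs, spec)
  Pr <- exp(parts$logPr)
  pred <- matrix(0, nrow(obs), spec$n_own)
  for (k in seq_along(parts$Ustars)) pred <- pred + Pr[, k] * parts$Ustars[[k]]
  pred
}

#' Coefficient of determination between series
#'
#' R-squared computed per coordinate (1 - SS_res / SS_tot) and averaged.
#'
#' @param observed,predicted equally shaped matrices or vectors.
#' @return scalar R-squared (<= 1; negative when worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  obs <- as.matrix(observed); prd <- as.matrix(predicted)
  mean(vapply(seq_len(ncol(obs)), function(j) {
    ss_tot <- sum((obs[, j] - mean(obs[, j]))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((obs[, j] - prd[, j])^2) / ss_tot
  }, numeric(1)), na.rm = TRUE)
}

# Transform between the 7 free parameters and an unconstrained vector.
# Variances and temperature are optimized in (bounded) log space, retention
# and decay in logit space.
.sigmoid <- function(z) 1 / (1 + exp(-z))
.logit <- function(p) log(p / (1 - p))
.VAR_LO <- log(1e-9); .VAR_HI <- log(1e4)
.LAM_LO <- log(1e-6); .LAM_HI <- log(1e3)
.A_DECAY_LO <- 0.9

.theta_to_params <- function(theta, d) {
  vb <- function(z, lo, hi) exp(lo + (hi - lo) * .sigmoid(z))
  player_params(Sigma_y = vb(theta[1], .VAR_LO, .VAR_HI),
                mu = theta[2],
                P0 = vb(theta[3], .VAR_LO, .VAR_HI),
                A = .sigmoid(theta[4]),
                Sigma_x = vb(theta[5], .VAR_LO, .VAR_HI),
                lambda1 = vb(theta[6], .LAM_LO, .LAM_HI),
                a = .A_DECAY_LO + (1 - .A_DECAY_LO) * .sigmoid(theta[7]),
                dim = d)
}

.params_to_theta <- function(params) {
  ib <- function(v, lo, hi) .logit(pmin(pmax((log(v) - lo) / (hi - lo), 1e-9), 1 - 1e-9))
  c(ib(as.numeric(params$Sigma_y), .VAR_LO, .VAR_HI),
    params$mu[1],
    ib(as.numeric(params$P0), .VAR_LO, .VAR_HI),
    .logit(pmin(pmax(as.numeric(params$A), 1e-9), 1 - 1e-9)),
    ib(as.numeric(params$Sigma_x), .VAR_LO, .VAR_HI),
    ib(params$lambda1, .LAM_LO, .LAM_HI),
    .logit(pmin(pmax((params$a - .A_DECAY_LO) / (1 - .A_DECAY_LO), 1e-9), 1 - 1e-9)))
}

#' Fit one player's behavioral parameters by maximum likelihood
#'
#' Multi-start Nelder-Mead maximization of [action_loglik()] over the seven
#' scalar parameters (Sigma_y, mu, P0, A, Sigma_x, lambda1, a), with variance
#' and temperature parameters optimized in bounded log space, retention in
#' logit space on [0, 1] and the decay rate in logit space on [0.9, 1).
#' Restart initial points are drawn from a seeded RNG, so fits are
#' reproducible. Series without persistent excitation (numerically constant
#' actions) are reported as degenerate rather than fitted.
#'
#' @inheritParams action_loglik
#' @param n_restarts number of optimizer restarts (default 10).
#' @param seed integer seed for the restart draws.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @param min_trials minimum series length accepted.
#' @return object of class `fit_result`: `params` (the estimates as
#'   [player_params()]), `loglik`, `predicted` (per-trial predicted means),
#'   `R2`, `degenerate`, `converged`, and per-restart diagnostics.
#' @export
fit_player <- function(own_actions, partner_obs, spec, n_restarts = 10L,
                       seed = 1L, maxit = 400L, min_trials = 20L) {
  own <- as.matrix(own_actions); obs <- as.matrix(partner_obs)
  d <- ncol(own)
  if (nrow(own) < min_trials)
    stop(sprintf("need at least %d trials", min_trials))
  if (stats::sd(as.numeric(own)) < 1e-10 || stats::sd(as.numeric(obs)) < 1e-10) {
    return(structure(list(params = NULL, loglik = NA_real_, predicted = NULL,
                          R2 = NA_real_, degenerate = TRUE, converged = FALSE,
                          restarts = NULL),
                     class = "fit_result"))
  }
  negll <- function(theta) {
    p <- try(.theta_to_params(theta, d), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    v <- try(action_loglik(p, own, obs, spec), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    -v
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  # data-informed centers: prior mean at the observation average, noises on
  # the scale of the per-coordinate trial-to-trial variability (one center
  # with sensing noise at that scale, one nearly noiseless), small
  # temperature relative to the cost curvature, and a decay rate that anneals
  # the temperature by about e^-2 over the length of the series
  vscale <- max(mean(apply(obs, 2L, stats::var)), 1e-8)
  a0 <- min(max(exp(-2 / nrow(own)), 0.905), 0.9999)
  mk_center <- function(Sy) .params_to_theta(player_params(
    Sigma_y = Sy, mu = mean(obs), P0 = vscale / 10, A = 0.95,
    Sigma_x = vscale / 10, lambda1 = 0.1, a = a0, dim = d))
  centers <- list(mk_center(vscale), mk_center(vscale / 100))
  starts <- c(centers,
              lapply(seq_len(max(0L, n_restarts - length(centers))), function(k)
                centers[[1L]] + stats::rnorm(7L, 0, 2)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  # coarse pass on every start, then refine the best few
  fits <- lapply(starts, function(th0) {
    opt <- stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(maxit = ceiling(maxit / 2), reltol = 1e-7))
    list(value = opt$value, par = opt$par, convergence = opt$convergence)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  for (i in utils::head(order(vals), 3L)) {
    opt <- stats::optim(fits[[i]]$par, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    fits[[i]] <- list(value = opt$value, par = opt$par,
                      convergence = opt$convergence)
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  # gradient polish of the best candidates
  for (i in utils::head(order(vals), 2L)) {
    if (vals[i] >= 1e10) next
    opt <- stats::optim(fits[[i]]$par, negll, method = "BFGS",
                        control = list(maxit = 100L))
    if (opt$value <= fits[[i]]$value)
      fits[[i]] <- list(value = opt$value, par = opt$par,
                        convergence = opt$convergence)
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(vals >= 1e10))
    return(structure(list(params = NULL, loglik = NA_real_, predicted = NULL,
                          R2 = NA_real_, degenerate = FALSE, converged = FALSE,
                          restarts = fits),
                     class = "fit_result"))
  best <- fits[[which.min(vals)]]
  params <- .theta_to_params(best$par, d)
  pred <- predicted_actions(params, obs, spec)
  structure(list(params = params, loglik = -best$value, predicted = pred,
                 R2 = r_squared(own, pred), degenerate = FALSE,
                 converged = TRUE, restarts = fits),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Fit result: degenerate series (no persistent excitation); no estimates.\n")
  } else if (!isTRUE(x$converged)) {
    cat("Fit result: no restart converged.\n")
  } else {
    cat(sprintf("Fit result: loglik = %.3f, R2 = %.4f\n", x$loglik, x$R2))
    print(x$params)
  }
  invisible(x)
}
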