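# Per-trial interaction loop: both players act simultaneously from their
# current beliefs, observe each other's realized action, update their partner
# models and anneal their temperatures. Iterated over a session this is
# fictitious play with a Kalman-filtered opponent model; the same loop is the
# package's synthetic-data generator.

# Independent RNG streams (one per player, one for population jitter) realized
# by swapping .Random.seed states; keeps one player's draws unchanged when the
# partner's configuration changes.
.new_streams <- function(seed, names) {
  glob <- globalenv()
  old <- if (exists(".Random.seed", envir = glob)) get(".Random.seed", envir = glob) else NULL
  env <- new.env(parent = emptyenv())
  env$states <- list()
  for (i in seq_along(names)) {
    set.seed((as.integer(seed) + 1000003L * i) %% 2147483647L)
    env$states[[names[i]]] <- get(".Random.seed", envir = glob)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = glob) else
    rm(list = ".Random.seed", envir = glob)
  env
}

.with_stream <- function(streams, name, fn) {
  if (is.null(streams)) return(fn())
  glob <- globalenv()
  old <- if (exists(".Random.seed", envir = glob)) get(".Random.seed", envir = glob) else NULL
  assign(".Random.seed", streams$states[[name]], envir = glob)
  res <- fn()
  streams$states[[name]] <- get(".Random.seed", envir = glob)
  if (!is.null(old)) assign(".Random.seed", old, envir = glob)
  res
}

#' One trial of the dyadic interaction loop
#'
#' Event order within a trial: (1) both players sample a (strategy, action)
#' pair from their current partner beliefs — simultaneous moves, neither sees
#' the other's current-trial action before acting; (2) each player receives a
#' noisy observation of the partner's realized action; (3) both partner
#' beliefs are Kalman-updated; (4) both temperatures decay. Realized
#' (deterministic) costs are logged for display.
#'
#' @param game a [joint_game()].
#' @param params list of two [player_params()].
#' @param beliefs list of two [partner_belief()]s.
#' @param policies list of two [policy_state()]s.
#' @param streams optional RNG stream set from the session (NULL = current RNG).
#' @return list with `record` (per-trial log), and updated `beliefs`,
#'   `policies`.
#' @export
run_trial <- function(game, params, beliefs, policies, streams = NULL) {
  acts <- vector("list", 2L)
  for (i in 1:2) {
    acts[[i]] <- .with_stream(streams, paste0("player", i), function()
      sample_action(game$specs[[i]], beliefs[[i]]$x, beliefs[[i]]$P,
                    policies[[i]]$lam))
  }
  rec <- list(t = policies[[1L]]$trial_index, players = vector("list", 2L))
  for (i in 1:2) {
    j <- 3L - i
    y <- .with_stream(streams, paste0("player", i), function()
      observe(acts[[j]]$u, params[[i]]$H, params[[i]]$Sigma_y))
    beliefs[[i]] <- kalman_step(beliefs[[i]], y, params[[i]])
    rec$players[[i]] <- list(
      s = acts[[i]]$s, u = acts[[i]]$u, y = y,
      x = beliefs[[i]]$x, P = beliefs[[i]]$P, lam = policies[[i]]$lam,
      cost = deterministic_cost(game$specs[[i]], acts[[i]]$u, acts[[j]]$u,
                                acts[[i]]$s))
    policies[[i]] <- decay_temperature(policies[[i]], params[[i]]$a)
  }
  list(record = rec, beliefs = beliefs, policies = policies)
}

#' Simulate a session of repeated trials for one dyad
#'
#' Runs [run_trial()] `n_trials` times from the initial beliefs (mu, P0) and
#' temperatures lambda1, with one RNG stream per player seeded from `seed`.
#' Identical (config, seed) pairs give bit-identical output.
#'
#' @param config list with elements `game` (a [joint_game()]) and `params`
#'   (list of two [player_params()]); any further elements are kept as
#'   metadata in the returned series.
#' @param n_trials number of trials (>= 1).
#' @param seed integer session seed.
#' @param verbose if TRUE, print a progress line every 100 trials.
#' @return object of class `dyad_series`: per player, matrices of actions
#'   `u`, observations `y`, belief means `x`; vectors of strategies `s`,
#'   temperatures `lam`, realized costs `cost`; belief covariances `P` (list);
#'   plus the config snapshot and seed.
#' @export
run_session <- function(config, n_trials, seed, verbose = FALSE) {
  if (is.null(config$game) || is.null(config$params))
    stop("invalid config: required fields 'game' and 'params'")
  if (!inherits(config$game, "joint_game"))
    stop("invalid config: 'game' must be a joint_game")
  if (length(config$params) != 2L)
    stop("invalid config: 'params' must list two players")
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  n_trials <- as.integer(n_trials)
  game <- config$game; params <- config$params
  streams <- .new_streams(seed, c("player1", "player2"))
  beliefs <- lapply(params, initial_belief)
  policies <- lapply(params, function(p) policy_state(p$lambda1, 1L))
  d <- vapply(game$specs, function(s) s$n_own, integer(1))
  dy <- vapply(params, function(p) nrow(as.matrix(p$H)), integer(1))
  players <- lapply(1:2, function(i) list(
    u = matrix(NA_real_, n_trials, d[i]), s = character(n_trials),
    y = matrix(NA_real_, n_trials, dy[i]), x = matrix(NA_real_, n_trials, d[3L - i]),
    P = vector("list", n_trials), lam = numeric(n_trials), cost = numeric(n_trials)))
  for (t in seq_len(n_trials)) {
    step <- run_trial(game, params, beliefs, policies, streams)
    beliefs <- step$beliefs; policies <- step$policies
    for (i in 1:2) {
      p <- step$record$players[[i]]
      players[[i]]$u[t, ] <- p$u; players[[i]]$s[t] <- p$s
      players[[i]]$y[t, ] <- p$y; players[[i]]$x[t, ] <- p$x
      players[[i]]$P[[t]] <- p$P; players[[i]]$lam[t] <- p$lam
      players[[i]]$cost[t] <- p$cost
    }
    if (verbose && t %% 100L == 0L)
      message(sprintf("trial %d/%d: s = (%s, %s)", t, n_trials,
                      players[[1]]$s[t], players[[2]]$s[t]))
  }
  structure(list(n_trials = n_trials, players = players, config = config,
                 seed = as.integer(seed)),
            class = "dyad_series")
}

#' @export
print.dyad_series <- function(x, ...) {
  cat(sprintf("Dyad series: %d trials, seed %d\n", x$n_trials, x$seed))
  tab <- table(paste(x$players[[1]]$s, x$players[[2]]$s, sep = "-"))
  cat("Joint-strategy counts:\n"); print(tab)
  invisible(x)
}

#' Flatten a dyad series to a long per-trial table
#'
#' One row per trial per player with strategy, temperature, realized cost and
#' the action / observation / belief-mean coordinates as `u*`, `y*`, `x*`
#' columns. Belief covariances are not tabulated.
#'
#' @param x a `dyad_series`.
#' @param ... unused.
#' @export
as.data.frame.dyad_series <- function(x, ...) {
  out <- do.call(rbind, lapply(1:2, function(i) {
    p <- x$players[[i]]
    df <- data.frame(t = seq_len(x$n_trials), player = i, s = p$s,
                     lam = p$lam, cost = p$cost)
    cbind(df,
          stats::setNames(as.data.frame(p$u), paste0("u", seq_len(ncol(p$u)))),
          stats::setNames(as.data.frame(p$y), paste0("y", seq_len(ncol(p$y)))),
          stats::setNames(as.data.frame(p$x), paste0("x", seq_len(ncol(p$x)))))
  }))
  out[order(out$t, out$player), , drop = FALSE]
}

#' Per-epoch joint-strategy proportions
#'
#' Splits the series into consecutive epochs of `epoch_size` trials (a final
#' partial epoch is dropped) and tabulates the relative frequency of each
#' joint strategy pair per epoch.
#'
#' @param series a `dyad_series`.
#' @param epoch_size trials per epoch.
#' @return matrix (epochs x joint-strategy pairs, labels "s1-s2"); rows sum
#'   to 1.
#' @export
epoch_strategy_probabilities <- function(series, epoch_size) {
  n_ep <- series$n_trials %/% epoch_size
  if (n_ep < 1L) stop("series shorter than one epoch")
  labs1 <- series$config$game$specs[[1]]$strategies
  labs2 <- series$config$game$specs[[2]]$strategies
  pairs <- as.vector(outer(labs1, labs2, paste, sep = "-"))
  joint <- paste(series$players[[1]]$s, series$players[[2]]$s, sep = "-")
  out <- matrix(0, n_ep, length(pairs), dimnames = list(NULL, pairs))
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * epoch_size + 1L):(e * epoch_size)
    tab <- table(factor(joint[idx], levels = pairs))
    out[e, ] <- as.numeric(tab) / epoch_size
  }
  out
}

#' Jitter a parameter set for population simulations
#'
#' Draws each scalar parameter uniformly within a +-`jitter` fraction of its
#' baseline. Noise scales, the prior and the temperature are jittered
#' multiplicatively; the unit-bounded rate parameters (retention A, decay a)
#' are jittered on the complementary (1 - rate) scale, so that a +-10%
#' variation perturbs their time constants by +-10% instead of collapsing
#' the annealing horizon by orders of magnitude. Uses the current RNG state.
#'
#' @param params a [player_params()] with scalar parameters.
#' @param jitter fractional range (default 0.1, i.e. +-10%).
#' @return a jittered [player_params()].
#' @export
jitter_params <- function(params, jitter = 0.1) {
  jit <- function(v) v * stats::runif(1L, 1 - jitter, 1 + jitter)
  jit_rate <- function(v) 1 - (1 - v) * stats::runif(1L, 1 - jitter, 1 + jitter)
  player_params(Sigma_y = jit(params$Sigma_y),
                mu = params$mu * stats::runif(1L, 1 - jitter, 1 + jitter),
                P0 = jit(params$P0), A = jit_rate(params$A),
                Sigma_x = jit(params$Sigma_x), lambda1 = jit(params$lambda1),
                a = jit_rate(params$a), H = params$H, dim = params$dim)
}

#' Simulate a population of jittered dyads
#'
#' Repeats [run_session()] for `n_dyads` dyads whose player parameters are
#' independently jittered around the baselines in `config` (one jitter RNG
#' stream, one session seed per dyad, all derived from `seed`).
#'
#' @inheritParams run_session
#' @param n_dyads number of simulated dyads.
#' @param jitter fractional parameter jitter (default +-10%).
#' @return list of `dyad_series`.
#' @export
simulate_dyads <- function(config, n_dyads, n_trials, seed, jitter = 0.1) {
  streams <- .new_streams(seed, "jitter")
  lapply(seq_len(n_dyads), function(k) {
    cfg <- config
    cfg$params <- .with_stream(streams, "jitter", function()
      lapply(config$params, jitter_params, jitter = jitter))
    run_session(cfg, n_trials, seed = (seed + 7919L * k) %% 2147483647L)
  })
}
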