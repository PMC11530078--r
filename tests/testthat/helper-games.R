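# Shared fixtures: random positive-definite quadratic specs and small games.

random_pd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.5
}

random_spec <- function(n_own = 2L, n_other = 2L, strategies = "s1") {
  player_game_spec(
    strategies = strategies, n_own = n_own, n_other = n_other,
    Q_own = setNames(lapply(strategies, function(s) random_pd(n_own)), strategies),
    Q_cross = setNames(lapply(strategies, function(s)
      matrix(rnorm(n_own * n_other), n_own)), strategies),
    Q_other = setNames(lapply(strategies, function(s) {
      M <- matrix(rnorm(n_other^2), n_other); (M + t(M)) / 2
    }), strategies),
    r_own = setNames(lapply(strategies, function(s) rnorm(n_own)), strategies),
    r_other = setNames(lapply(strategies, function(s) rnorm(n_other)), strategies),
    z = setNames(lapply(strategies, function(s) rnorm(1)), strategies))
}

# term-by-term scalar-loop cost, independent of the matrix implementation
cost_scalar_loop <- function(spec, u1, u2, s) {
  b <- spec$blocks[[s]]
  tot <- b$z
  for (i in seq_along(u1)) for (j in seq_along(u1))
    tot <- tot + 0.5 * u1[i] * b$Q_own[i, j] * u1[j]
  for (i in seq_along(u1)) for (j in seq_along(u2))
    tot <- tot + u1[i] * b$Q_cross[i, j] * u2[j]
  for (i in seq_along(u2)) for (j in seq_along(u2))
    tot <- tot + 0.5 * u2[i] * b$Q_other[i, j] * u2[j]
  tot + sum(b$r_own * u1) + sum(b$r_other * u2)
}
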