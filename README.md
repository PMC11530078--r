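# dyadgame

Simulation and analysis of **dyadic sensorimotor joint action**: how two
people (or two model agents), each knowing only their own goal and sensing
their partner imperfectly, negotiate a coordinated behavior over repeated
trials of the same task.

The package is aimed at computational/motor neuroscientists who want to
(i) *simulate* joint-action scenarios trial by trial and (ii) *identify*
interpretable per-player parameters from action time series (their own, or
simulated).

## The model

Each trial of a two-player task is a **quadratic game**: player *i* pays

> J_i(u_i, u_-i, s_i) = ½ u_iᵀ R_ii(s_i) u_i + u_iᵀ R_i,-i(s_i) u_-i +
> ½ u_-iᵀ R_-i,-i(s_i) u_-i + r_iᵀ u_i + r_-iᵀ u_-i + z(s_i)

over continuous action vectors u and a discrete strategy s (e.g. which
target to commit to, or when to cross a via-point). With positive-definite
own blocks each joint strategy has a closed-form Nash equilibrium
u\* = −R⁻¹ r.

Players never see the game from above. Player *i* keeps a Gaussian
**partner model** N(x_i, P_i) over the partner's next action, updated each
trial from a noisy observation y_i = H u_-i + v, v ~ N(0, Σy), by a Kalman
step x′ = A{x + K(y − Hx)}, P′ = A(I − KH)PAᵀ + Σx. Given the belief, the
expected cost is quadratic, ½(u − u\*)ᵀ R_ii (u − u\*) + q(s, x, P), and
both strategy and action are drawn from the **Boltzmann policy**
∝ exp(−E{J}/λ): Pr(s) ∝ |R_ii(s)|^(−1/2) e^(−q(s)/λ) and
u | s ~ N(u\*(s, x), λ R_ii(s)⁻¹), with temperature annealing
λ(t+1) = a·λ(t). Iterated over trials this is fictitious play with a
Bayesian opponent model; one player is fully described by seven scalars
(Σy, μ, P0, A, Σx, λ1, a).

Two scenarios are built in:

* **Spatial Stag Hunt** — 1-D cursor task with a safe rabbit and a
  cooperative stag; calibrated from its cost matrix (w = 9/2, z_R = 5,
  z_S = 1 at target spacing 2).
* **Two via-point reaching (2-VP)** — planar reaches through player-specific
  via-points under a virtual spring coupling; trajectories parameterized by
  a 9-node polyharmonic spline, Bryson-rule weights, linear body dynamics,
  crossing time (early/middle/late) as the strategy.

Plus **metrics** for coordination (minimum via-point distance, E/M/L
strategy and collaboration classification, leadership index, learner flag)
and **maximum-likelihood identification** of the seven parameters from
action series.

## Worked example

Simulate a Stag Hunt dyad that believes its partner is predictable
(Σx = 0.1) but senses it poorly (Σy = 10), then identify player 1's
parameters back from the simulated series:

```r
library(dyadgame)

cfg    <- stag_hunt_session_config(Sigma_y = 10, Sigma_x = 0.1)
series <- run_session(cfg, 400, seed = 1)
series
#> Dyad series: 400 trials, seed 1
#> Joint-strategy counts:
#> rabbit-rabbit   rabbit-stag   stag-rabbit     stag-stag
#>            39            67            42           252

epoch_strategy_probabilities(series, 40)[c(1, 5, 10), ]
#>      rabbit-rabbit stag-rabbit rabbit-stag stag-stag
#> [1,]          0.00        0.00       0.000     1.000
#> [2,]          0.05        0.10       0.075     0.775
#> [3,]          0.25        0.05       0.050     0.650

fit <- fit_player(series$players[[1]]$u, series$players[[1]]$y,
                  cfg$game$specs[[1]], n_restarts = 4, seed = 2)
fit
#> Fit result: loglik = 319.444, R2 = 0.9375
#> Player parameters (1-dim partner action):
#>   Sigma_y=10.26123 mu=0.1302 P0=2.202343e-06 A=0.9864165
#>   Sigma_x=0.106766 lambda1=0.110276 a=0.998413
```

The dyad mostly hunts the stag but keeps drifting toward the rabbit as the
noisy partner estimate wanders — exactly the temporal variability that
makes the parameters identifiable: the fit recovers the generating values
(Σy = 10, A = 0.99, Σx = 0.1, λ1 = 0.1, a = 0.999) to within a few percent
and predicts the action series with R² ≈ 0.94 on this short run (≈ 0.97 at
the full 2000-trial length).

For the 2-VP game:

```r
cfg   <- viapoint_config("asymmetric")
game  <- viapoint_game(cfg)
equilibrium_path_orders(game, cfg)$orders
#> [1] "VP1-first" "VP2-first"
```

A command-line wrapper (`inst/cli/dyadgame`) exposes
`simulate` / `metrics` / `fit` / `sweep` over the same functions; see
`cli_main()`.

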