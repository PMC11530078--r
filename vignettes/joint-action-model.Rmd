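---
title: "Modeling the development of dyadic joint coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the development of dyadic joint coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadgame)
```

# The model

`dyadgame` simulates and analyzes pairs of agents (dyads) that repeat the
same sensorimotor task over many trials, each knowing their own goal but not
their partner's, and each receiving only noisy information about what the
partner just did. Three ingredients are combined per trial and per player:

1. **A quadratic game.** Player $i$'s task is a quadratic cost
   $J_i(u_i, u_{-i}, s_i)$ in both players' continuous action vectors, indexed
   by a discrete strategy $s_i$ (e.g. which order to visit targets in). With
   symmetric positive-definite own-curvature blocks each joint strategy pair
   has a unique Nash equilibrium, obtained in closed form by stacking the two
   first-order conditions (`nash_equilibrium()`).

2. **A Bayesian partner model.** Player $i$ carries a Gaussian belief
   $N(x_i, P_i)$ over the partner's next action. After each trial the player
   senses the partner's realized action through $y_i = H u_{-i} + v_i$,
   $v_i \sim N(0, \Sigma_y)$, and updates the belief with the trial-wise
   Kalman recursion
   $x_i' = A\{x_i + K(y_i - H x_i)\}$,
   $P_i' = A (I - K H) P_i A^\top + \Sigma_x$.
   The retention rate $A$ and the internal noise $\Sigma_x$ encode the prior
   belief that the partner is stationary versus erratic.

3. **Boltzmann action selection.** Given the belief, the expected cost is
   again quadratic in the own action
   ($\tfrac12 (u - u^*)^\top Q_{own} (u - u^*) + q(s, x, P)$, where $q$
   carries the uncertainty penalty $\tfrac12\mathrm{tr}(Q_{other} P)$), and
   both strategy and action are drawn from the Boltzmann density
   $\propto e^{-\bar J / \lambda}$: the strategy with probability
   $\propto |Q_{own}(s)|^{-1/2} e^{-q(s)/\lambda}$, the action from
   $N(u^*(s), \lambda Q_{own}(s)^{-1})$. The temperature anneals
   geometrically, $\lambda(t+1) = a\,\lambda(t)$. Because action variability
   scales with the inverse curvature, variability concentrates along
   task-irrelevant directions (a minimum-intervention signature), and the
   strategy rule extends quantal-response behavior to continuous games.

Iterating act → observe → update over trials is fictitious play with a
Kalman-filtered opponent model (`run_trial()`, `run_session()`). One player
is fully described by seven scalar parameters in the spherical-covariance
configuration: $\Sigma_y, \mu, P_0, A, \Sigma_x, \lambda_1, a$.

Two important restrictions are intentional. Moves are simultaneous within a
trial — a player's action can influence the partner only on *future* trials,
so there is no within-trial feedback control. And all own-curvature blocks
must be positive definite; competitive (zero-sum-like) games where they are
not are rejected at construction, because the Gaussian/Gaussian-mixture form
of the policy would no longer hold.

# Scenarios

## Spatial Stag Hunt

A 1-D workspace with a "rabbit" (safe, partner-independent) and a "stag"
(better, but only if both players commit). The curvature $w$ and offsets
$z_R, z_S$ are calibrated from the four corner costs
$(J(R,\cdot), J(R,\cdot), J(S,R), J(S,S)) = (5, 5, 10, 1)$ via
$z_R = J(R,\cdot)$, $z_S = J(S,S)$, $w = 2(J(S,R) - z_S)/|u_R - u_S|^2$,
giving $w = 9/2$ at spacing 2 (`stag_hunt_calibrate()`). Both (rabbit,
rabbit) and (stag, stag) are Nash equilibria of the built game.

Two block forms are provided. The default (`"partner_distance"`) is the
closed form the simulations use, whose stag branch expands to
$\tfrac{w}{2}(u_i - u_S)^2 + \tfrac{w}{2}(u_i - u_{-i})^2 + z_S$ — own
distance to the stag plus distance to the partner. The `"stag_distance"`
variant penalizes both players' distances to the stag instead. Off the
matrix corners the two differ (the partner-coupled form is the one "finally
set" for simulation, and its cross term is what makes trust matter); on the
corners they agree exactly, so corner-based checks cannot distinguish them.

**Target placement.** Only the spacing $|u_R - u_S| = 2$ is pinned down by
the calibration; the default places the targets symmetrically, $u_R = -1$,
$u_S = +1$, so that the baseline prior belief $\mu = 0$ is equidistant from
both. This matters dynamically: with the prior sitting *on* one target the
initial conditions pre-commit the dyad to it at the baseline temperature
($\lambda_1 = 0.1$), and the convergence map degenerates. With the unbiased
prior the belief uncertainty penalty $\tfrac12 w P$ is what arbitrates:
a predictable partner (low $\Sigma_x$, hence small steady-state $P$) makes
the stag branch cheaper in expectation; an erratic one (high $\Sigma_x$)
makes the rabbit safe. Simulations reproduce exactly that: stag-stag
emerges only under low $\Sigma_x$, fastest when $\Sigma_y$ is also low,
while high $\Sigma_x$ yields rabbit-rabbit regardless of $\Sigma_y$.

Baseline simulation conditions: $\mu = 0$, $P_0 = 10^{-6}$, $A = 0.99$,
$\lambda_1 = 0.1$, $a = 0.999$, $\Sigma_y, \Sigma_x \in \{0.1, 10\}$, 2000
trials (50 epochs of 40), eight dyads per cell with ±10% multiplicative
parameter jitter (jittered $A$ and $a$ are clamped at 1 to respect their
bounds). The package's convergence-map tests run 500 trials per cell — the
map is already stable there — to keep the default test run short.

## Two via-point (2-VP) reaching game

Two players make planar reaches between shared start and end points
(±5 cm on the x-axis), each crossing their *own* via-point, while a virtual
spring of stiffness $k$ couples their hands and both are told to keep the
interaction force small. Trajectories are parameterized by a cubic
polyharmonic spline with $M = 9$ nodes ($g(\tau)$ basis with linear term);
four node values are boundary-constrained ($p(0) = p(\Delta t) = p_{start}$,
$p(T - \Delta t) = p(T) = p_{end}$ with $\Delta t = 0.01$ s, pinning the
endpoints and flattening boundary velocity), leaving a 10-dimensional free
action per player (5 nodes × x/y). Position, velocity, acceleration and the
motor command $F_i = m\ddot p_i + b\dot p_i + k(p_i - p_{-i})$ are all
linear in the free nodes, so the cost

$$J_i = \tfrac12 w_1 \|p_i(\tau_i(s_i)) - VP_i\|^2 +
  \tfrac1{2N}\sum_\tau \left[ w_2\|p_i - p_{-i}\|^2 + r\|F_i\|^2 \right]$$

is exactly quadratic in the two action vectors (`viapoint_game()`), with
the crossing time $\tau_i(s_i)$ the three-valued strategy: early, middle or
late (0.32/0.5/0.68 of the movement for the asymmetric geometry;
0.38/0.5/0.62 for the symmetric one). Weights follow the Bryson rule,
$w_1 = 1/(2.5\,\mathrm{mm})^2$, $w_2 = 1/(2\,\mathrm{mm})^2$,
$r = 1/(1\,\mathrm{N})^2$. The time sum is averaged over a fixed grid of
$N = 100$ samples (matching 100 Hz sampling of a normalized 1 s movement);
including the boundary samples in the grid is deliberate.

**Equilibrium structure.** The task's equilibria are paths along which both
players cross both via-points in the same order — VP1-first or VP2-first;
with symmetric via-points the two orders are exact mirror images and have
identical cost (verified to 1e-9). Because three crossing-time labelings
realize each order (e.g. (E,M), (E,L), (M,L) all put VP1 first), the 3×3
strategy scan finds six stable pairs forming exactly these two classes;
`equilibrium_path_orders()` performs the grouping. This labeling redundancy
is a property of the fixed-crossing-time parameterization, not of the task.

**Dynamics parameters.** $m$, $b$, $k$ are not dictated by the task and were
fixed once at plausible rendering/arm values: $m = 1$ kg, $b = 5$ N·s/m,
$k = 30$ N/m. The stiffness is deliberately modest — consistent with
low-stiffness haptic rendering — and at much larger $k$ the scan begins to
stabilize degenerate same-crossing-time pairs (a lock-in artifact of very
strong coupling): the two-order structure above holds across the moderate
regime ($k \lesssim 50$ N/m at these $m, b$).

**Simulation defaults.** Spherical noises over the node coordinates ("all
nodes equally noisy"): the prior mean is the straight start-to-end path (a
naive "partner will go straight" expectation); $\Sigma_y$ encodes the
sensing condition — about $(0.5\,\mathrm{cm})^2 = 2.5\times10^{-5}$ m² per
node when the partner is fully visible, up to $(2\,\mathrm{cm})^2$ when only
haptic cues are available; $\Sigma_x = 2.5\times10^{-5}$ m²; $\lambda_1 = 1$
(action scatter of order $\sqrt{\lambda/Q} \approx$ a few mm at these
curvatures) with $a = 0.99$ over the ~100–240-trial horizons of this task.
Simulated populations reproduce the expected signatures: with more reliable
partner information the end-of-training distance to the partner's via-point
is smaller, and — while the coordination is still being negotiated —
leadership indices mark leading into the own via-point (negative) and
following into the partner's (positive), with stronger role separation
under noisier sensing; as a dyad converges on the equilibrium the
interaction force and with it the roles fade toward zero.

# Metrics

The metrics stage consumes tidy 100 Hz trajectory tables (trial, player, t,
x, y, Fx, Fy) — either recorded or produced by `viapoint_recordings()` — and
computes: Savitzky–Golay-smoothed kinematics (4th order, 370 ms window,
derivatives from the same local fit); minimum via-point distances MD and
their times TC; the per-trial E/M/L strategy with threshold $d = 0.02$ m
(strict inequalities); dyad classification (collaborative = complementary
orders E-L/L-E, cyclic = matching orders, non-collaborative otherwise);
12-trial-epoch collaboration probabilities; the learner flag (mean
final-epoch distance to the partner's via-point strictly below 0.02 m); and
the leadership index.

Two conventions deserved explicit decisions. The strategy rule as printed
does not cover a missed own via-point; those trials get an explicit
`invalid` label (treated as non-collaborative) rather than being silently
binned. And "power of the interaction force" is implemented as signed
mechanical power $F_{int}\cdot v$ — a leader moves against the coupling
spring (negative), a follower is dragged along (positive) — with a
squared-magnitude projection variant available behind the `signed` flag.
The index averages over the 300 ms window just before the crossing time.

# Identification

`fit_player()` estimates the seven parameters of one player from a trial
series by maximum likelihood. The partner-model filter is replayed over the
player's *sensory observation* series, and each observed own action is
scored under the implied Gaussian mixture
$\sum_s \Pr(s \mid x_t, P_t, \lambda_t)\, N(u_t;\ u^*(s, x_t),\
\lambda_t Q_{own}(s)^{-1})$ with $\lambda_t = \lambda_1 a^{t-1}$.
For simulated data the engine's logged observations are the natural input;
for recordings, where the private observations are unobservable, the
partner's actions are the plug-in (with $\Sigma_y$ still entering through
the Kalman gain). The observation-driven choice is what makes the fitted
belief track the same trajectory the player's belief actually followed;
with the plug-in, belief wander induced by sensory noise is unexplainable
by construction and the goodness of fit is bounded well below what the
generating model achieves.

Numerics: variances and the temperature are optimized in bounded log space
($[10^{-9}, 10^4]$ for variances, $[10^{-6}, 10^3]$ for $\lambda_1$), the
retention in logit space on $[0, 1]$ and the decay rate in logit space on
$[0.9, 1)$ — initial temperature and decay trade off along a ridge, so the
decay range is kept in the slow-annealing regime and the structured start
anneals by $e^{-2}$ over the series length. Optimization is multi-start
Nelder–Mead (a data-informed center start plus seeded random perturbations;
coarse pass, refinement of the best three, BFGS polish of the best two; 10
restarts by default, reproducible given the fit seed). Identifiability
requires persistent excitation: numerically constant series are reported as
degenerate rather than fitted, and in the Stag Hunt only the
predictable-partner/noisy-sensing cell (low $\Sigma_x$, high $\Sigma_y$)
produces enough temporal variability to pin the parameters down — there,
fits recover $\Sigma_y$, $A$, $\Sigma_x$ with a few percent median error
and predicted-action $R^2 \approx 0.97$ (per coordinate, averaged).

# What the synthetic data does and does not show

All tests run on data generated by the package's own engine under the
conditions above: noises are Gaussian and spherical, cost structures are
exactly known to the players, crossing times are fixed to three values, and
there is no within-trial coupling, fatigue, or learning of the cost itself.
Passing tests therefore demonstrate internal consistency of the machinery
(filter, policy, equilibria, metrics, likelihood) and recoverability of
parameters *under the model's own assumptions* — they cannot certify that
real dyads follow this model, and results reported for human recordings
(fit quality on real data, leadership–noise correlations, learner counts)
are out of reach without those recordings.

Problem sizes used by the test suite and the acceptance script were chosen
once: 500-trial, 8-dyad cells for the Stag Hunt convergence map; a
2000-trial dyad for the identification benchmark; 240-trial dyads (5 per
noise group, the full experimental protocol length and group size) for the
sensory-noise recovery ordering — shorter series leave $\Sigma_y$ on a
compensation ridge with $A$ and $\Sigma_x$ and the ordering statistic has
no power; 1000-trial series (6) for the recovery study.

# Known limitations

- Non-positive-definite (competitive) cost structures are rejected, not
  supported.
- The ML fitter covers the spherical/scalar parameter configuration with an
  identity sensory map; matrix-valued parameters simulate but do not fit.
- The cost structure itself (weights, geometry, crossing times) is assumed
  known per scenario and is not estimated.
- Group-level inferential statistics are out of scope; standard R tooling
  (`aov`, `chisq.test`, …) applies directly to the emitted metric tables.
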