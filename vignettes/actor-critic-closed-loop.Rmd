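---
title: "Closed-loop reinforcement learning with rate-neuron actor-critic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop reinforcement learning with rate-neuron actor-critic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(closedloop)
```

## The model

`closedloop` simulates autonomous agents built from networks of noisy rate
neurons that learn, in a closed loop with an environment, from reward alone.
Each unit follows the stochastic differential equation

$$\tau \dot z_i(t) = -z_i(t) + \mu_i + f\!\big(h_i(t) - \theta_i\big) + \xi_i(t),$$

with membrane time constant $\tau$, baseline $\mu_i$, input threshold
$\theta_i$, Gaussian white noise $\xi_i$ of amplitude $\sigma_\xi$, input
field $h_i(t) = \sum_j w_{ij}\, z_j(t - d_{ij})$ and activation $f$, either
linear or threshold-linear ($f(x) = \Theta(x)\,x$ with the strict Heaviside
$\Theta$).  Integration uses a stochastic exponential-Euler scheme on a fixed
grid: the leak is propagated exactly, the input is treated as piecewise
constant, and the noise increment has standard deviation
$\sigma_\xi \sqrt{(1 - e^{-2\,dt/\tau})/2}$, which makes the stationary
distribution of a free noisy unit independent of the step size (an
Ornstein-Uhlenbeck process with stationary s.d. $\sigma_\xi/\sqrt 2$).  This
convention is a deliberate choice of this package; any convention that is
not step-size invariant would entangle the physics of the model with the
numerical resolution.

The agent (see `build_agent()`) is an actor-critic:

* **Input layer.** Place cells encode the observation: Gaussian tuning
  curves on an even grid for continuous observations (`make_grid_layout()`,
  `encode()`), non-overlapping one-hot tuning for discrete state spaces
  (`encode_discrete()`).  The encoded activity drives threshold-linear input
  units as external input.
* **Critic.** A single linear unit whose activity $v(t)$ estimates the
  continuous-time value
  $V(t) = \int_t^\infty r(t')\, e^{-(t'-t)/\tau_r}\, dt'$,
  an exponentially discounted integral of future reward with discount time
  constant $\tau_r$.
* **Reward-prediction error (RPE).** A linear unit receiving the reward as
  external input plus two connections from the critic — one instantaneous
  with weight $1/d - 1/\tau_r$ and one delayed by $d$ with weight $-1/d$ —
  so that its activity approximates
  $\delta(t) = \dot v(t) + r(t) - v(t)/\tau_r$
  without computing a derivative explicitly.
* **Actor.** One threshold-linear unit per action in a winner-take-all
  (WTA) circuit (self-excitation, mutual inhibition) with Gaussian input
  noise driving exploration.  The most active unit is the selected action
  (`argmax_decode()`).

Both plastic projections (input→critic and input→actor) follow the same
Hebbian three-factor rule (`update_weight()`):

$$\Delta w_j = \eta\, \delta(t)\, x_j(t - \delta t)\,
  \Theta\!\big(z(t - \delta t) - \theta_{\text{post}}\big),$$

with the RPE as the global modulatory third factor, an optional eligibility
delay $\delta t$, and a lower weight bound so that every action always
receives at least minimal drive.

## Timing and the closed loop

`run_closed_loop()` couples the network (step `network_dt`, default 1 ms)
to the environment (stepped every `env_step_interval`, default 10 ms).
Between environment steps the observation, the reward — converted to a
constant rate $r(t) = R / \Delta$ so that values are on the scale of the
raw rewards — and the selected action are held constant (zero-order hold).
After a terminal step the environment is reset after an `episode_break`
(default 50 ms) during which the network relaxes with zero drive; the
terminal reward is delivered during the first interval of the break.
Plasticity remains enabled throughout, including the break: the learning
rule is part of the network, not of the task scheduler.

## Numerical choices that matter

**The RPE delay $d$ is small (2 ms), not one environment step.**  The
finite difference $(v(t) - v(t-d))/d$ is meant to approximate $\dot v$.
If $d$ spans a whole environment interval while the units filter sharp
(one-hot) input transitions with their membrane time constants, the delayed
sample is contaminated by rise transients and the resulting spurious TD
credit grows *with the value scale itself* — in our experiments state
values then inflate without bound.  With $d$ of a few milliseconds and fast
units ($\tau$ = 1–2 ms) the approximation is local, the learning rule's
fixed points match the self-consistent values, and a planted optimal policy
is stable under continued learning.  $d$ remains configurable for readers
who want to study that instability.

**Eligibility delay.**  With non-overlapping discrete tuning curves the
input activity switches sharply between environment steps, so at the moment
the prediction error for a transition is available, the pre- and
postsynaptic activities already encode the *next* state.  Evaluating them
$\delta t$ = one environment step in the past (`delta_t = 10` ms in the
FrozenLake preset) re-aligns credit with the state-action pair that caused
the transition.  Continuous tasks with overlapping tuning do not need it
(`delta_t = 0` in the MountainCar preset).

**Winner-take-all connectivity.**  `build_wta_weights()` places actions on
a line (ordered accelerations) or a ring (compass directions).  By default
only self-connections are excitatory and every other pair is inhibitory.
With excitatory nearest neighbours (available as `exc_range = 1`) a 3-unit
line cannot select exclusively: the middle unit receives excitation from
any winner and inhibition from nobody, so two units settle above any
sensible gate threshold.  Self-excitation is kept below 1 so that
threshold-linear activity remains bounded.

**Optimistic critic initialisation.**  Initial critic weights
(`critic_init`, FrozenLake preset 0.4, MountainCar preset 0.2) start above
the attainable state values.  Visited states relax toward their true values while rarely-visited
states keep their optimistic value, so transitions into fresh territory
carry a positive prediction error.  Without this, early punishment
experiences produce a pessimism trap: the agent learns to press against a
wall (paying only the small step punishment), its critic equilibrates to
that policy's value, the prediction error vanishes, and learning stops in a
suboptimal fixed point.

**Bounded pessimism and the anti-stagnation role of the critic floor.**
The critic weight floor (`w_min_critic`: -0.5 in the FrozenLake preset,
-0.15 in the MountainCar preset) bounds how negative a state value can
become.  Two distinct effects motivate it.  First, values far below the
largest one-off punishment are never informative, but they arise
transiently from punishment bursts under a bad early policy and then
suppress every action leading toward such states — including the ones
needed to discover the goal behind them; the floor keeps such states
recoverable.  Second, a policy that goes nowhere (e.g. pressing one
acceleration forever) is *self-consistent*: its value equilibrates at
`step_punishment * tau_r`, the prediction error vanishes, and learning
stops while exploration noise is too weak to overcome the learned
preference.  Setting the floor *above* that equilibrium leaves a stuck
policy with a permanent residual negative prediction error that steadily
erodes the active action until behaviour changes.  In the MountainCar
study this choice is what eliminates occasional multi-thousand-step
relapse episodes late in training.  A complementary saturation ceiling on
actor weights (`w_max_actor`) is available but unused by the presets.

**Exploration noise with the timescale of decisions.**  Actor input noise
is drawn afresh every `noise_hold` ms (default: one environment interval)
and held in between.  Noise redrawn every network step makes the WTA winner
flip *within* an environment step, so the eligibility-lagged credit
frequently lands on an action that was never actually played; holding the
noise over a decision interval aligns the exploration process with the
action grid.

**Separate learning rates.**  The actor rate `eta` (FrozenLake preset 0.3)
exceeds the critic rate `eta_critic` (0.1).  The critic integrates rare,
large punishment events and benefits from a slower, smoother estimate; the
actor must exploit value differences quickly once they exist.

## The environments as study conditions

Both benchmark tasks are generated internally; no external data are used.

* **MountainCar** uses the canonical classic-control constants (force
  0.001, gravity 0.0025, $x \in [-1.2, 0.6]$, $|\dot x| \le 0.07$, goal at
  $x = 0.5$, start drawn uniformly from $[-0.6, -0.4]$ at rest).  Reward
  shaping: -0.01 per step plus +1 on reaching the goal, because a network
  with excitatory-only input projections cannot represent a purely negative
  value landscape well.
* **FrozenLake** is the standard non-slippery 4×4 map
  (`SFFF/FHFH/FFFH/HFFG`), actions west/north/east/south, step punishment
  -0.01, hole punishment -0.2 with a teleport back to start (the episode
  continues), goal reward +1 (the episode ends).  The shortest path has 6
  moves, so the optimal reward per step is $1/6 \approx 0.16$ unshaped, or
  $(1 - 6 \times 0.01)/6 \approx 0.157$ with the step punishment included.
  The shaping magnitudes are configuration values; the learning-dependent
  checks are tolerance-based rather than exact.

What the generator deliberately does not emulate: slippery (stochastic)
transitions, partial observability, sensor noise, and continuous action
spaces.  Tests passing on these tasks therefore demonstrate closed-loop TD
learning with place-cell codes and WTA selection under clean, fully
observed dynamics — not robustness to the noise of real sensors.

## Convergence criteria

The phrases "close to optimal" and "converged" are made explicit:

* *FrozenLake*: performance at environment step $k$ is the average reward
  per step over the next 500 steps; the run has converged at the first $k$
  from which this moving average never again drops below 95% of the
  theoretical (shaped) optimum.  With the study conditions (16 one-hot
  place cells, 4-action ring WTA, eligibility delay of one environment
  step, 5 seeds) convergence lands at roughly 1,500–2,000 environment
  steps.
* *MountainCar*: performance is the per-episode total reward averaged over
  seeds, as a function of the episode index.  The tolerance band is 10% of
  the *learning range* — the best observed performance minus the naive
  first-episode performance — because the shaped optimum sits near zero,
  where a band proportional to the optimum itself would be degenerate.
  The study converges (enters and stays inside the band) after roughly
  7–11 episodes and is close to optimal from about episode 6 on.
  `run_experiment()` additionally reports a per-seed convergence episode
  under the same band.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full FrozenLake study
(5 seeds × 4,000 environment steps) and the full MountainCar study
(10 seeds × 15 episodes, capped at 15,000 environment steps per seed);
property-style tests use reduced problem sizes
(hundreds of steps, 10-unit networks) chosen so the whole suite documents
the science while staying convenient to run routinely.  All runs are
bit-reproducible given (configuration, seed): one master seed yields
deterministic per-run child seeds (`derive_seed()`).

## Known limitations

* Place-cell grids scale exponentially with observation dimensionality;
  the package is intended for low-dimensional observation spaces.
* The socket bridge serves one client in lockstep; the free-running
  asynchronous regime of a middleware-based setup is out of scope, and the
  four concurrent roles of such a wrapper (environment stepper, action
  subscriber, observation publisher, reward publisher) are multiplexed in
  one event loop.
* The Q-learning baseline is deliberately plain (no target network, no
  double/dueling variants): it is the comparison point, not the
  contribution.
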