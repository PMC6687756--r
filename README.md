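# closedloop

Closed-loop simulation of learning agents built from networks of noisy
rate neurons.

## The problem

Studying how neural circuits learn behavior requires *closed-loop*
simulation: the network receives sensory observations from an environment,
its activity is decoded into actions, the actions change the environment,
and the resulting reward drives plasticity that reshapes the network's own
responses. `closedloop` packages that whole cycle — neuron model, coding
adapters, learning rule, benchmark environments, loop driver, message
bridge, and a machine-learning baseline — so that a biologically motivated
learning architecture can be trained and evaluated on standard
reinforcement-learning benchmarks, entirely within R, with every run
bit-reproducible from one integer seed.

## The model

Rate units follow

τ ż_i = −z_i + μ_i + f(h_i − θ_i) + ξ_i,   h_i = Σ_j w_ij z_j(t − d_ij),

integrated with a stochastic exponential-Euler scheme whose noise
convention makes the stationary statistics step-size invariant.  The agent
is an actor-critic: place cells encode observations; a critic unit learns
the continuous-time value V(t) = ∫ r e^{−(t′−t)/τ_r} dt′; a
reward-prediction-error unit computes
δ(t) ≈ (1/d − 1/τ_r) v(t) − v(t−d)/d + r(t)
through one instantaneous and one delayed connection from the critic; actor
units in a winner-take-all circuit select actions.  Both plastic
projections use the same Hebbian three-factor rule

Δw_j = η δ(t) x_j(t − δt) Θ(z(t − δt) − θ_post),

with an eligibility delay δt for discrete state spaces and a minimal weight
so that no action is ever completely silenced.  A plain Q-learning baseline
(MLP function approximation, epsilon-greedy exploration, replay memory,
ADAM) is included for comparison.

Two benchmark environments are built in: **MountainCar** (continuous
states, canonical classic-control physics, shaped with a goal bonus) and
non-slippery 4×4 **FrozenLake** (discrete states, step and hole
punishments, unit goal reward).  See the vignette
(`vignettes/actor-critic-closed-loop.Rmd`) for the full model description
and the reasoning behind every default.

## Worked example

Train the actor-critic on FrozenLake for one seed and inspect what it
learned:

```r
library(closedloop)

env   <- frozen_lake()
agent <- build_agent(agent_config_frozenlake(), seed = 7)
log   <- run_closed_loop(agent, env,
                         loop_config(max_steps = 4000, seed = 7))
log
#> closed-loop episode log: 4000 env steps, 484 episodes, 64150 network steps
#>   mean episode reward: 0.8583

# reward per step over the next 500 steps, at each step
ma <- moving_average(log$steps$reward, 500)
opt <- fl_optimal_reward_per_step(env)          # (1 - 6*0.01)/6 = 0.1567
convergence_step(ma, 0.95 * opt)
#> [1] 1925

extract_policy_value(agent, 0:15)[13:16, ]
#>    state     value action
#> 13    12 0.4014126      2
#> 14    13 0.2773149      2
#> 15    14 0.9419930      2
#> 16    15 0.4007776      2
```

The log says the agent completed 484 episodes in 4,000 environment steps
(about 8.3 steps per episode, against an optimal 6, most of the excess
spent early).  The moving-average criterion reports that from environment
step 1,925 on, the agent's reward per step stayed at or above 95% of the
theoretical optimum — the policy is optimal from there.  The value map
shows the learned gradient toward the goal: state 14 (one move west of the
goal) is worth 0.94 and its preferred action (2 = east) walks into the
goal.  State 12 is a hole the agent never occupies (falling in teleports
it back to the start), so its value still sits at the optimistic initial
value 0.4 — only experienced states are revalued.

The full multi-seed studies live one level higher:

```r
summary <- run_experiment(experiment_config("frozenlake"), output_dir = "results")
summary$convergence_steps
#> [1] 1914 2117 2337  987 1634
summary$mean_convergence_step
#> [1] 1797.8
```

`run_experiment()` writes the learning curve (CSV + PNG), the per-seed
policy/value maps and a JSON summary into `results/`.

A command-line driver with `run` / `serve` / `plot` / `validate-config` /
`show-defaults` subcommands is installed under `inst/cli/closedloop.R`;
`serve` exposes an environment over a TCP socket speaking the package's
JSON message schema.

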