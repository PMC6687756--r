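#' Rate-neuron actor-critic agent
#'
#' The agent is a single rate network with four populations (see
#' \code{\link{rate-network}} for the unit dynamics):
#' \itemize{
#'   \item an \emph{input layer} of threshold-linear place cells driven by
#'     the encoded observation as external input;
#'   \item a \emph{critic} unit (linear) receiving plastic projections from
#'     the input layer; its activity is the value estimate v(t);
#'   \item a \emph{reward-prediction-error (RPE)} unit (linear) receiving
#'     the reward as external input plus two connections from the critic --
#'     one instantaneous with weight (1/d - 1/tau_r) and one delayed by d
#'     with weight -1/d -- so that its activity tracks the TD error of
#'     \code{\link{reward_prediction_error}};
#'   \item \emph{actor} units (threshold-linear), one per action, receiving
#'     plastic projections from the input layer plus recurrent
#'     winner-take-all connectivity (short-range excitation, long-range
#'     inhibition) and per-step Gaussian input noise that drives
#'     exploration.
#' }
#' Both plastic projections (input-to-critic and input-to-actor) are updated
#' every network step by the three-factor rule of
#' \code{\link{update_weight}} with the RPE unit's activity as the
#' modulatory factor; actor weights are bounded below by a minimal weight
#' so that at least one actor unit always receives drive.  The selected
#' action is the most active actor unit.
#'
#' @name agent
NULL

#' Configuration of an actor-critic agent
#'
#' All tunable constants of the architecture in one flat list.  Presets for
#' the two built-in benchmarks are provided by
#' \code{\link{agent_config_mountaincar}} and
#' \code{\link{agent_config_frozenlake}}.
#'
#' @param layout a \code{place_layout} for continuous observations, or the
#'   integer number of discrete states for one-hot encoding.
#' @param n_actions number of actor units (>= 2).
#' @param tau_input,tau_actor,tau_critic,tau_rpe membrane time constants (ms).
#' @param theta_actor input threshold of the actor units.
#' @param wta_exc,wta_inh,wta_metric,wta_exc_range winner-take-all
#'   recurrence: excitatory and inhibitory strengths, the distance metric
#'   (\code{"line"} or \code{"ring"}) and the excitation range (see
#'   \code{\link{build_wta_weights}}).
#' @param sigma_explore s.d. of the Gaussian input noise injected into the
#'   actor units (the exploration drive).
#' @param noise_hold interval (ms) over which one actor-noise draw is held
#'   (zero-order hold).  Holding the noise over one environment step keeps
#'   the winner stable within a step, so the eligibility-lagged credit
#'   lands on the action that was actually played; 0 redraws every network
#'   step.
#' @param eta,tau_r,d,delta_t TD constants, see \code{\link{td_params}}.
#' @param eta_critic learning rate of the input-to-critic projection
#'   (defaults to \code{eta}); a slower critic smooths value estimates over
#'   rare, large punishment events.
#' @param theta_post_actor postsynaptic gate threshold for the actor
#'   projection: only units clearly active (the WTA winner) are eligible.
#' @param theta_post_critic gate threshold for the critic projection; the
#'   default is far below any activity so critic learning is ungated and
#'   the value may become negative.
#' @param w_min_actor minimal weight of the input-to-actor projection.
#' @param w_max_actor saturation ceiling of the input-to-actor projection
#'   (default \code{Inf}).  Bounding how strongly a single action can
#'   dominate bounds the time needed to revise a committed policy after a
#'   perturbation; without it, occasional long relapse episodes occur late
#'   in training while an over-grown preference erodes.
#' @param w_min_critic lower weight bound of the input-to-critic projection
#'   (large and negative: values of punished states are negative).
#' @param w_init_jitter width of the uniform jitter added to initial
#'   plastic weights to break symmetry.
#' @param critic_init initial input-to-critic weight: an optimistic value
#'   (above the attainable state values) gives every transition into
#'   rarely-visited territory a positive prediction error, driving
#'   systematic exploration instead of premature policy collapse.
#' @param input_gain gain applied to the encoded observation before it
#'   drives the input layer.
#' @return A list of class \code{agent_config}.
#' @export
agent_config <- function(layout, n_actions,
                         tau_input = 2, tau_actor = 5, tau_critic = 5,
                         tau_rpe = 2,
                         theta_actor = 0,
                         wta_exc = 0.3, wta_inh = 1,
                         wta_metric = c("line", "ring"), wta_exc_range = 0,
                         sigma_explore = 0.3, noise_hold = 10,
                         eta = 0.05, eta_critic = NULL,
                         tau_r = 50, d = 10, delta_t = 0,
                         theta_post_actor = 0.05,
                         theta_post_critic = -1e6,
                         w_min_actor = 0.01, w_max_actor = Inf,
                         w_min_critic = -1e6,
                         w_init_jitter = 0.01, critic_init = 0.5,
                         input_gain = 1) {
  wta_metric <- match.arg(wta_metric)
  stopifnot(n_actions >= 2, sigma_explore >= 0, eta >= 0)
  if (is.null(eta_critic)) eta_critic <- eta
  structure(as.list(environment()), class = "agent_config")
}

#' Winner-take-all recurrent weights
#'
#' Actor units are arranged on a line or a ring, the distance reflecting
#' the similarity of the actions they encode.  Units within
#' \code{exc_range} of each other (by default only each unit with itself)
#' excite each other with \code{exc}; all more distant pairs inhibit each
#' other with \code{inh}.  The matrix is symmetric by construction.  With
#' the default self-only excitation a single winner suppresses every other
#' unit, which is what makes the selection exclusive; widening
#' \code{exc_range} to 1 lets neighbouring actions co-activate, at the
#' price of exclusivity for small circuits.
#'
#' @param n_actions number of actor units (>= 2).
#' @param exc excitatory strength (> 0).
#' @param inh inhibitory strength (> 0; entered with negative sign).
#' @param metric \code{"line"} (ordered actions) or \code{"ring"} (cyclic
#'   actions, e.g. the four compass directions).
#' @param exc_range largest distance still excitatory (default 0: self).
#' @return An \code{n_actions x n_actions} numeric matrix.
#' @export
build_wta_weights <- function(n_actions, exc, inh,
                              metric = c("line", "ring"), exc_range = 0) {
  metric <- match.arg(metric)
  if (n_actions < 2) stop("n_actions must be >= 2")
  stopifnot(exc > 0, inh > 0, exc_range >= 0)
  i <- matrix(seq_len(n_actions), n_actions, n_actions)
  j <- t(i)
  dist <- abs(i - j)
  if (metric == "ring") dist <- pmin(dist, n_actions - dist)
  ifelse(dist <= exc_range, exc, -inh)
}

#' Build an actor-critic agent
#'
#' Instantiates all populations, the plastic projections (uniform initial
#' weights at the floor plus a small jitter to break symmetry), the WTA
#' recurrence and the RPE wiring.  Deterministic given (config, seed).
#'
#' @param cfg an \code{agent_config}.
#' @param seed integer master seed for the weight jitter and the agent's
#'   exploration noise stream.
#' @return A mutable object of class \code{rl_agent}.
#' @export
build_agent <- function(cfg, seed = 1) {
  discrete <- is.numeric(cfg$layout) && length(cfg$layout) == 1
  n_in <- if (discrete) as.integer(cfg$layout) else nrow(cfg$layout$centers)
  n_a <- as.integer(cfg$n_actions)
  n <- n_in + n_a + 2L
  idx_in <- seq_len(n_in)
  idx_act <- n_in + seq_len(n_a)
  idx_critic <- n_in + n_a + 1L
  idx_rpe <- n_in + n_a + 2L

  params <- rate_params(
    n,
    tau = c(rep(cfg$tau_input, n_in), rep(cfg$tau_actor, n_a),
            cfg$tau_critic, cfg$tau_rpe),
    theta = c(rep(0, n_in), rep(cfg$theta_actor, n_a), 0, 0),
    activation = c(rep("threshold_linear", n_in + n_a), "linear", "linear")
  )

  td_actor <- td_params(eta = max(cfg$eta, .Machine$double.xmin),
                        tau_r = cfg$tau_r, d = cfg$d,
                        theta_post = cfg$theta_post_actor,
                        delta_t = cfg$delta_t)
  td_actor$eta <- cfg$eta   # eta = 0 supported: learning frozen
  td_critic <- td_actor
  td_critic$eta <- cfg$eta_critic
  td_critic$theta_post <- cfg$theta_post_critic

  set.seed(derive_seed(seed, "agent-init"))
  w0 <- matrix(0, n, n)
  # plastic feedforward projections, floor + jitter
  w0[idx_act, idx_in] <- cfg$w_min_actor +
    stats::runif(n_a * n_in, 0, cfg$w_init_jitter)
  w0[idx_critic, idx_in] <- cfg$critic_init +
    stats::runif(n_in, 0, cfg$w_init_jitter)
  # WTA recurrence among the actor units
  w0[idx_act, idx_act] <- build_wta_weights(n_a, cfg$wta_exc, cfg$wta_inh,
                                            cfg$wta_metric,
                                            cfg$wta_exc_range)
  # instantaneous critic -> RPE link
  w0[idx_rpe, idx_critic] <- 1 / cfg$d - 1 / cfg$tau_r
  plastic <- matrix(FALSE, n, n)
  plastic[idx_act, idx_in] <- TRUE
  plastic[idx_critic, idx_in] <- TRUE

  # delayed critic -> RPE link
  wd <- matrix(0, n, n)
  wd[idx_rpe, idx_critic] <- -1 / cfg$d

  dt <- 1
  max_delay <- max(cfg$d, cfg$delta_t)
  ag <- new.env(parent = emptyenv())
  ag$cfg <- cfg
  ag$discrete <- discrete
  ag$n_in <- n_in; ag$n_actions <- n_a
  ag$idx_in <- idx_in; ag$idx_act <- idx_act
  ag$idx_critic <- idx_critic; ag$idx_rpe <- idx_rpe
  ag$params <- params
  ag$td_actor <- td_actor; ag$td_critic <- td_critic
  ag$W0 <- weight_matrix(w0, delay = 0, plastic = plastic,
                         w_min = min(cfg$w_min_actor, cfg$w_min_critic))
  ag$Wd <- weight_matrix(wd, delay = cfg$d)
  ag$state <- network_state(numeric(n), dt = dt, max_delay = max_delay)
  ag$learning <- TRUE
  ag$lag_steps <- as.integer(round(cfg$delta_t / dt))
  ag$noise_hold_steps <- max(1L, as.integer(round(cfg$noise_hold / dt)))
  ag$noise_count <- 0L
  ag$noise <- numeric(n_a)
  class(ag) <- "rl_agent"
  ag
}

#' One update of an agent given the held observation and reward
#'
#' Generic so that scripted test agents can stand in for the neural agent
#' in \code{\link{run_closed_loop}}.
#'
#' @param agent the agent.
#' @param obs current observation (vector for continuous environments,
#'   0-based state index for discrete ones, \code{NULL} for no drive, e.g.
#'   during the between-episode break).
#' @param reward instantaneous reward rate held since the last environment
#'   step.
#' @param dt network time step (ms).
#' @return The 0-based index of the currently selected action.
#' @export
agent_step <- function(agent, obs, reward, dt = 1) UseMethod("agent_step")

#' @rdname agent_step
#' @export
agent_step.rl_agent <- function(agent, obs, reward, dt = 1) {
  cfg <- agent$cfg
  n <- agent$state$n
  x_place <- if (is.null(obs)) {
    numeric(agent$n_in)
  } else if (agent$discrete) {
    encode_discrete(obs, agent$n_in)
  } else {
    encode(obs, cfg$layout)
  }
  ext <- numeric(n)
  ext[agent$idx_in] <- cfg$input_gain * x_place
  if (cfg$sigma_explore > 0) {
    if (agent$noise_count %% agent$noise_hold_steps == 0L)
      agent$noise <- stats::rnorm(agent$n_actions, 0, cfg$sigma_explore)
    agent$noise_count <- agent$noise_count + 1L
    ext[agent$idx_act] <- agent$noise
  }
  ext[agent$idx_rpe] <- reward

  step_network(agent$state, agent$params, list(agent$W0, agent$Wd), ext, dt)

  z <- agent$state$z
  if (agent$learning && (cfg$eta > 0 || cfg$eta_critic > 0)) {
    delta <- z[agent$idx_rpe]
    zl <- state_lagged(agent$state, agent$lag_steps)
    x_pre <- zl[agent$idx_in]
    # input -> actor projection: gate on the (lagged) actor activity
    Wa <- agent$W0$w[agent$idx_act, agent$idx_in, drop = FALSE]
    Xp <- matrix(x_pre, agent$n_actions, agent$n_in, byrow = TRUE)
    Zp <- matrix(zl[agent$idx_act], agent$n_actions, agent$n_in)
    agent$W0$w[agent$idx_act, agent$idx_in] <-
      pmin(cfg$w_max_actor,
           update_weight(Wa, Xp, Zp, delta, agent$td_actor,
                         cfg$w_min_actor))
    # input -> critic projection
    Wc <- agent$W0$w[agent$idx_critic, agent$idx_in]
    agent$W0$w[agent$idx_critic, agent$idx_in] <-
      update_weight(Wc, x_pre, rep(zl[agent$idx_critic], agent$n_in),
                    delta, agent$td_critic, cfg$w_min_critic)
  }
  argmax_decode(z[agent$idx_act])
}

#' Current value estimate and RPE of an agent
#'
#' @param agent an \code{rl_agent}.
#' @return Named numeric vector with the critic and RPE unit activities.
#' @export
agent_signals <- function(agent) {
  z <- agent$state$z
  c(critic = z[agent$idx_critic], rpe = z[agent$idx_rpe])
}

#' Learned policy and value map over a set of states
#'
#' For each state, the value is the critic's feedforward drive (encoded
#' input activity times critic weights) and the preferred action is the
#' actor unit with the largest feedforward drive.  Purely read-only: no
#' dynamics are run and no learning occurs.
#'
#' @param agent an \code{rl_agent}.
#' @param states list of observations (or vector of 0-based state indices
#'   for discrete agents).
#' @return A data.frame with columns \code{state}, \code{value},
#'   \code{action}.
#' @export
extract_policy_value <- function(agent, states) {
  cfg <- agent$cfg
  if (agent$discrete && is.numeric(states)) states <- as.list(states)
  n_s <- length(states)
  value <- numeric(n_s)
  act <- integer(n_s)
  Wc <- agent$W0$w[agent$idx_critic, agent$idx_in]
  Wa <- agent$W0$w[agent$idx_act, agent$idx_in, drop = FALSE]
  for (k in seq_len(n_s)) {
    x <- if (agent$discrete) encode_discrete(states[[k]], agent$n_in)
         else encode(states[[k]], cfg$layout)
    x <- cfg$input_gain * x
    value[k] <- sum(Wc * x)
    act[k] <- argmax_decode(drop(Wa %*% x))
  }
  data.frame(state = seq_len(n_s) - 1L, value = value, action = act)
}

#' Scripted agent replaying a fixed action sequence
#'
#' Stands in for the neural agent in tests of the closed loop: at the k-th
#' environment step it plays \code{actions[k]} (the last action is repeated
#' once the sequence is exhausted).
#'
#' @param actions integer vector of 0-based actions.
#' @param steps_per_env network steps per environment step of the loop it
#'   will be run in.
#' @return An object of class \code{scripted_agent}.
#' @export
scripted_agent <- function(actions, steps_per_env = 1) {
  ag <- new.env(parent = emptyenv())
  ag$actions <- as.integer(actions)
  ag$steps_per_env <- as.integer(steps_per_env)
  ag$calls <- 0L
  class(ag) <- "scripted_agent"
  ag
}

#' @rdname agent_step
#' @export
agent_step.scripted_agent <- function(agent, obs, reward, dt = 1) {
  if (is.null(obs)) return(agent$actions[1])  # break phase: action unused
  agent$calls <- agent$calls + 1L
  k <- (agent$calls - 1L) %/% agent$steps_per_env + 1L
  agent$actions[min(k, length(agent$actions))]
}
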