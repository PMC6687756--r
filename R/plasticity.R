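#' Continuous-time temporal-difference learning with three-factor plasticity
#'
#' The critic unit should approximate the continuous-time value function
#'
#' \deqn{V(t) = \int_t^\infty r(t') e^{-(t' - t)/\tau_r} \, dt',}
#'
#' an exponentially discounted integral of future reward with discount time
#' constant \eqn{\tau_r}.  Gradient descent on the squared prediction error
#' \eqn{E = (V - z)^2 / 2}, with bootstrapping on the current value
#' estimate, yields a Hebbian three-factor rule
#'
#' \deqn{\Delta w_j = \eta\, \delta(t)\, x_j(t)\, \Theta(z(t) - \theta_{post}),}
#'
#' where the neuromodulatory third factor is the reward-prediction error
#' \eqn{\delta(t) = \dot v(t) + r(t) - v(t)/\tau_r}.  The derivative is
#' approximated with a finite difference over a delay \eqn{d}:
#'
#' \deqn{\delta(t) \approx (1/d - 1/\tau_r)\, v(t) - (1/d)\, v(t - d) + r(t),}
#'
#' which is realised in the network by two critic-to-RPE connections (one
#' instantaneous, one delayed by \eqn{d}).  For discrete environments with
#' non-overlapping input tuning, pre- and postsynaptic activities enter the
#' rule with a small eligibility delay \eqn{\delta t} so that plasticity
#' credits the state-action pair that caused the current reward.
#'
#' @name plasticity
NULL

#' Parameters of the TD learning machinery
#'
#' @param eta learning rate (> 0).
#' @param tau_r reward discount time constant in ms (> d).
#' @param d delay of the reward-prediction-error finite difference in ms
#'   (> 0, integer multiple of the network step).
#' @param theta_post postsynaptic gate threshold of the three-factor rule.
#' @param delta_t eligibility delay in ms (>= 0); 0 disables the trace.
#' @return An object of class \code{td_params}.
#' @export
td_params <- function(eta = 0.1, tau_r = 50, d = 10, theta_post = 0,
                      delta_t = 0) {
  stopifnot(eta > 0, d > 0, tau_r > d, delta_t >= 0)
  structure(list(eta = eta, tau_r = tau_r, d = d, theta_post = theta_post,
                 delta_t = delta_t),
            class = "td_params")
}

#' Discounted value of a reward trajectory (test oracle)
#'
#' Computes \eqn{V(t) = \int_t^\infty r(t') e^{-(t'-t)/\tau_r} dt'} on a
#' regular grid by backward recursion, treating the reward as piecewise
#' constant over each step (so a constant reward \code{c} gives exactly
#' \code{c * tau_r}).  The integral is truncated at the end of the
#' trajectory.  This is the target the critic learns to approximate; it is
#' used as a Monte-Carlo oracle in validation, not inside the learning rule.
#'
#' @param reward_traj numeric vector of rewards sampled every \code{dt} ms.
#' @param tau_r discount time constant in ms.
#' @param dt sampling interval in ms.
#' @return Numeric vector \code{V} of the same length.
#' @export
discounted_value <- function(reward_traj, tau_r, dt = 1) {
  n <- length(reward_traj)
  if (n == 0) stop("empty reward trajectory")
  stopifnot(tau_r > 0, dt > 0)
  a <- exp(-dt / tau_r)
  gain <- tau_r * (1 - a)   # integral of the kernel over one step
  v <- numeric(n)
  acc <- 0
  for (k in n:1) {
    acc <- reward_traj[k] * gain + a * acc
    v[k] <- acc
  }
  v
}

#' Squared prediction error of the critic
#'
#' @param V target value.
#' @param z critic activity.
#' @return \eqn{(V - z)^2 / 2}.
#' @export
td_objective <- function(V, z) {
  assert_finite(c(V, z), "inputs")
  0.5 * (V - z)^2
}

#' Reward-prediction error from delayed value samples
#'
#' Finite-difference approximation of \eqn{\dot v + r - v/\tau_r}:
#' \eqn{\delta = (1/d - 1/\tau_r) v(t) - (1/d) v(t-d) + r(t)}.  The
#' approximation is algebraically exact for values linear in time.
#'
#' @param v_now critic activity at time t.
#' @param v_delayed critic activity at time t - d.
#' @param r instantaneous reward (rate).
#' @param p a \code{td_params}.
#' @return The scalar reward-prediction error.
#' @export
reward_prediction_error <- function(v_now, v_delayed, r, p) {
  if (p$d <= 0) stop("d must be > 0")
  (1 / p$d - 1 / p$tau_r) * v_now - v_delayed / p$d + r
}

#' Three-factor weight update with a weight floor
#'
#' \eqn{w' = \max(w_{min},\ w + \eta\, \delta\, x_{pre}\,
#' \Theta(z_{post} - \theta_{post}))}.  Vectorised over \code{w} /
#' \code{x_pre} / \code{z_post}.  When an eligibility delay is in use, pass
#' the lagged activities obtained from \code{\link{delayed_traces}}.
#'
#' @param w current weight(s).
#' @param x_pre presynaptic activity (third factor gate applies per target).
#' @param z_post postsynaptic activity.
#' @param delta reward-prediction error (global modulatory factor).
#' @param p a \code{td_params}.
#' @param w_min lower bound on the weights.
#' @return Updated weight(s), never below \code{w_min}.
#' @export
update_weight <- function(w, x_pre, z_post, delta, p, w_min = -Inf) {
  pmax(w_min, w + p$eta * delta * x_pre * heaviside(z_post - p$theta_post))
}

#' Pre/post activities at the eligibility delay
#'
#' Returns the activities recorded exactly \code{delta_t} ms ago from an
#' activity history (a \code{network_state} ring buffer); \code{delta_t = 0}
#' returns the current values.
#'
#' @param state a \code{network_state}.
#' @param pre_idx,post_idx integer indices of the pre- and postsynaptic units.
#' @param delta_t eligibility delay in ms (integer multiple of the grid step).
#' @return List with \code{x_pre} and \code{z_post} vectors.
#' @export
delayed_traces <- function(state, pre_idx, post_idx, delta_t) {
  steps <- delta_t / state$dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("delta_t must be an integer multiple of dt")
  z <- state_lagged(state, round(steps))
  list(x_pre = z[pre_idx], z_post = z[post_idx])
}
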