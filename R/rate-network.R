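#' Rate-neuron populations integrated with a stochastic exponential-Euler
#' scheme
#'
#' The basic dynamical unit of the package is the noisy rate neuron
#'
#' \deqn{\tau \dot z_i(t) = -z_i(t) + \mu_i + f(h_i(t) - \theta_i) + \xi_i(t),}
#'
#' where \eqn{\tau} is the membrane time constant, \eqn{\mu_i} a baseline
#' activity, \eqn{f} the activation function (linear or threshold-linear),
#' \eqn{h_i(t) = \sum_j w_{ij} z_j(t - d_{ij})} the recurrent input field
#' (optionally with per-connection delays), \eqn{\theta_i} an input threshold
#' and \eqn{\xi_i} Gaussian white noise of amplitude \eqn{\sigma_\xi}.
#'
#' Integration is on a fixed grid of step \code{dt}: the leak is treated
#' exactly (exponential Euler), the input as piecewise constant, and the
#' noise increment is drawn so that the stationary distribution of a free
#' noisy neuron is step-size invariant (an Ornstein-Uhlenbeck process with
#' stationary s.d. \eqn{\sigma_\xi/\sqrt{2}}).
#'
#' @name rate-network
NULL

#' Per-neuron parameters of a rate population
#'
#' @param n number of neurons.
#' @param tau membrane time constant in ms (scalar or length-n, > 0).
#' @param mu baseline activity (scalar or length-n).
#' @param theta input threshold (scalar or length-n).
#' @param sigma_xi noise amplitude (scalar or length-n, >= 0).
#' @param activation \code{"linear"} or \code{"threshold_linear"} (scalar or
#'   length-n).
#' @return An object of class \code{rate_params}.
#' @export
rate_params <- function(n, tau = 10, mu = 0, theta = 0, sigma_xi = 0,
                        activation = "linear") {
  stopifnot(n >= 1)
  rep_n <- function(x) {
    if (length(x) == 1) rep(x, n) else {
      stopifnot(length(x) == n)
      x
    }
  }
  tau <- rep_n(tau); mu <- rep_n(mu); theta <- rep_n(theta)
  sigma_xi <- rep_n(sigma_xi)
  activation <- rep_n(activation)
  if (any(tau <= 0)) stop("tau must be > 0")
  if (any(sigma_xi < 0)) stop("sigma_xi must be >= 0")
  if (!all(activation %in% c("linear", "threshold_linear")))
    stop("unknown activation kind")
  structure(list(n = as.integer(n), tau = tau, mu = mu, theta = theta,
                 sigma_xi = sigma_xi, activation = activation,
                 relu = activation == "threshold_linear"),
            class = "rate_params")
}

#' Weight matrix with optional delays, plasticity mask and weight floor
#'
#' \code{w[i, j]} is the strength of the connection from source neuron
#' \code{j} to target neuron \code{i}.  Each connection can carry a
#' transmission delay (an integer multiple of the simulation step); entries
#' flagged plastic are clipped from below at \code{w_min} after every
#' update.
#'
#' @param w numeric matrix (targets x sources).
#' @param delay per-connection delay in ms; scalar or matrix of \code{dim(w)}.
#' @param plastic logical; scalar or matrix of \code{dim(w)}.
#' @param w_min lower bound applied to plastic entries.
#' @return An object of class \code{weight_matrix}.
#' @export
weight_matrix <- function(w, delay = 0, plastic = FALSE, w_min = -Inf) {
  w <- as.matrix(w)
  if (length(delay) == 1) delay <- matrix(delay, nrow(w), ncol(w))
  if (length(plastic) == 1) plastic <- matrix(plastic, nrow(w), ncol(w))
  stopifnot(all(dim(delay) == dim(w)), all(dim(plastic) == dim(w)),
            all(delay >= 0))
  if (any(w[plastic] < w_min))
    stop("plastic weights below w_min at construction")
  structure(list(w = w, delay = delay, plastic = plastic, w_min = w_min),
            class = "weight_matrix")
}

#' Network state with an activity history ring buffer
#'
#' The history buffer retains enough past activity vectors to serve the
#' largest configured delay; requesting a longer delay later is an error,
#' not a resize.  Before any step has been taken the pre-history is filled
#' with the initial activity.
#'
#' @param z0 initial activity vector.
#' @param dt simulation step in ms (> 0).
#' @param max_delay largest delay (ms) any connection or eligibility trace
#'   will ever request; must be an integer multiple of \code{dt}.
#' @return An object of class \code{network_state} (a mutable environment).
#' @export
network_state <- function(z0, dt = 1, max_delay = 0) {
  stopifnot(dt > 0, max_delay >= 0)
  steps <- max_delay / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("max_delay must be an integer multiple of dt")
  depth <- as.integer(round(steps)) + 1L
  st <- new.env(parent = emptyenv())
  st$z <- as.numeric(z0)
  st$n <- length(st$z)
  st$dt <- dt
  st$t <- 0
  st$depth <- depth
  st$history <- matrix(st$z, nrow = depth, ncol = st$n, byrow = TRUE)
  st$pos <- 1L  # row of history holding z(t)
  class(st) <- "network_state"
  st
}

#' Past activity of the network
#'
#' @param state a \code{network_state}.
#' @param lag_steps how many steps back (0 = current activity).
#' @return The activity vector recorded \code{lag_steps} steps ago.
#' @export
state_lagged <- function(state, lag_steps) {
  lag_steps <- as.integer(lag_steps)
  if (lag_steps < 0 || lag_steps >= state$depth)
    stop("requested delay exceeds history depth")
  row <- state$pos - lag_steps
  if (row < 1L) row <- row + state$depth
  state$history[row, ]
}

#' Heaviside step function
#'
#' Strict at the origin: \eqn{\Theta(x) = 1} iff \eqn{x > 0}, else 0
#' (including \eqn{x = 0}).
#'
#' @param x numeric vector of finite values.
#' @return 0/1 numeric vector.
#' @export
heaviside <- function(x) {
  assert_finite(x, "x")
  as.numeric(x > 0)
}

#' Activation functions of the rate units
#'
#' \code{"linear"} is the identity; \code{"threshold_linear"} ("relu") is
#' \eqn{f(x) = \Theta(x)\, x} with the strict Heaviside gate.
#'
#' @param x numeric vector.
#' @param kind \code{"linear"} or \code{"threshold_linear"}.
#' @return f(x).
#' @export
activation <- function(x, kind = c("linear", "threshold_linear")) {
  kind <- match.arg(kind)
  if (kind == "linear") x else heaviside(x) * x
}

#' Recurrent input field of a network
#'
#' Computes \eqn{h_i = \sum_j w_{ij} z_j(t - d_{ij})}, sampling delayed
#' presynaptic activity from the state's history buffer.
#'
#' @param weights a \code{weight_matrix} (targets x sources).
#' @param state a \code{network_state} whose activity has
#'   \code{ncol(weights$w)} entries.
#' @return Numeric vector of length \code{nrow(weights$w)}.
#' @export
input_field <- function(weights, state) {
  if (ncol(weights$w) != state$n)
    stop("weight matrix sources do not match network size")
  dly <- unique(as.vector(weights$delay))
  if (length(dly) == 1 && dly == 0) return(drop(weights$w %*% state$z))
  h <- numeric(nrow(weights$w))
  for (d in dly) {
    steps <- d / state$dt
    if (abs(steps - round(steps)) > 1e-9)
      stop("delays must be integer multiples of dt")
    zd <- state_lagged(state, round(steps))
    wd <- weights$w * (weights$delay == d)
    h <- h + drop(wd %*% zd)
  }
  h
}

#' Advance a rate network by one time step
#'
#' Exponential-Euler update of the rate dynamics: with
#' \eqn{u = \mu + f(h + e - \theta)} held constant over the step,
#' \eqn{z(t + dt) = u + (z(t) - u) e^{-dt/\tau}} plus, for noisy units, a
#' Gaussian increment of s.d.
#' \eqn{\sigma_\xi \sqrt{(1 - e^{-2 dt/\tau})/2}} so that the stationary
#' noise statistics do not depend on \code{dt}.  Draws come from R's global
#' RNG; seed it (\code{set.seed}) for reproducible trajectories.
#'
#' @param state a \code{network_state}; modified in place and returned.
#' @param params a \code{rate_params} for the whole network.
#' @param weights a \code{weight_matrix}, or \code{NULL} for unconnected
#'   units, or a list of \code{weight_matrix} objects whose input fields are
#'   summed (e.g. one instantaneous and one delayed pathway).
#' @param ext external input vector added to the field inside f (recycled).
#' @param dt time step in ms; defaults to the state's grid step and must
#'   equal it (the history buffer is laid out on that grid).
#' @return The updated \code{network_state}, invisibly.
#' @export
step_network <- function(state, params, weights = NULL, ext = 0,
                         dt = state$dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (abs(dt - state$dt) > 1e-12)
    stop("dt must match the grid step of the state")
  h <- numeric(state$n)
  if (!is.null(weights)) {
    if (inherits(weights, "weight_matrix")) weights <- list(weights)
    for (wm in weights) h <- h + input_field(wm, state)
  }
  x <- h + ext - params$theta
  f <- x
  r <- params$relu
  if (any(r)) f[r] <- f[r] * (f[r] > 0)
  u <- params$mu + f
  alpha <- exp(-dt / params$tau)
  z <- u + (state$z - u) * alpha
  s <- params$sigma_xi > 0
  if (any(s)) {
    z[s] <- z[s] + params$sigma_xi[s] *
      sqrt((1 - alpha[s]^2) / 2) * stats::rnorm(sum(s))
  }
  state$z <- z
  state$t <- state$t + dt
  pos <- state$pos + 1L
  if (pos > state$depth) pos <- 1L
  state$history[pos, ] <- z
  state$pos <- pos
  invisible(state)
}
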