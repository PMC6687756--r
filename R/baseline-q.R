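#' Q-learning baseline with MLP function approximation
#'
#' The comparison algorithm for the MountainCar benchmark: plain Q-learning
#' with a one-hidden-layer perceptron (rectifying-linear hidden units)
#' mapping the normalized observation to one estimated Q-value per action,
#' epsilon-greedy exploration, a uniform replay memory and the ADAM
#' optimizer.  No target network, no double/dueling extensions: the online
#' network provides both the prediction and the bootstrap target
#' \eqn{r + \gamma (1 - done) \max_{a'} Q(s', a')}.
#'
#' @name baseline-q
NULL

#' Initialize the Q-network parameters
#'
#' Weights are drawn from scaled Gaussians (He-style fan-in scaling) using
#' the global RNG; seed it for reproducible initialization.
#'
#' @param n_in observation dimension.
#' @param n_hidden hidden layer size.
#' @param n_actions number of output units.
#' @return List of class \code{q_net} with \code{W1, b1, W2, b2}.
#' @export
q_network <- function(n_in, n_hidden = 64, n_actions = 3) {
  structure(list(
    W1 = matrix(stats::rnorm(n_hidden * n_in, 0, sqrt(2 / n_in)),
                n_hidden, n_in),
    b1 = numeric(n_hidden),
    W2 = matrix(stats::rnorm(n_actions * n_hidden, 0, sqrt(2 / n_hidden)),
                n_actions, n_hidden),
    b2 = numeric(n_actions)), class = "q_net")
}

#' Q-learning hyperparameters
#'
#' @param gamma discount factor in (0, 1].
#' @param eps_start,eps_end,eps_decay epsilon-greedy schedule: epsilon
#'   decays exponentially from \code{eps_start} toward \code{eps_end} with
#'   rate \code{eps_decay} per episode.
#' @param lr ADAM learning rate.
#' @param beta1,beta2,eps_adam ADAM moment constants.
#' @param batch_size replay minibatch size.
#' @param capacity replay memory capacity.
#' @return List of class \code{q_learn_params}.
#' @export
q_learn_params <- function(gamma = 0.99, eps_start = 1, eps_end = 0.05,
                           eps_decay = 0.9, lr = 1e-3, beta1 = 0.9,
                           beta2 = 0.999, eps_adam = 1e-8,
                           batch_size = 64, capacity = 50000) {
  stopifnot(gamma > 0, gamma <= 1, eps_start >= 0, eps_start <= 1,
            eps_end >= 0, eps_end <= 1)
  structure(as.list(environment()), class = "q_learn_params")
}

#' Forward pass of the Q-network
#'
#' \code{hidden = max(0, W1 obs + b1)}; \code{q = W2 hidden + b2}.
#'
#' @param net a \code{q_net}.
#' @param obs numeric observation vector.
#' @return Numeric vector of Q-values, one per action.
#' @export
q_forward <- function(net, obs) {
  if (length(obs) != ncol(net$W1)) stop("observation dimension mismatch")
  hidden <- pmax(0, drop(net$W1 %*% obs) + net$b1)
  drop(net$W2 %*% hidden) + net$b2
}

#' Epsilon-greedy action selection
#'
#' @param q numeric vector of Q-values (non-empty).
#' @param epsilon exploration probability in [0, 1].
#' @return 0-based action index (uses the global RNG).
#' @export
epsilon_greedy <- function(q, epsilon) {
  if (length(q) == 0) stop("empty Q-value vector")
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(length(q), 1) - 1L
  } else {
    argmax_decode(q)
  }
}

#' Uniform replay memory
#'
#' Fixed-capacity circular buffer of transitions (s, a, r, s', done);
#' sampling is uniform over the stored entries.
#'
#' @param capacity maximal number of stored transitions.
#' @param n_obs observation dimension.
#' @return A mutable object of class \code{replay_buffer}.
#' @export
replay_buffer <- function(capacity, n_obs) {
  rb <- new.env(parent = emptyenv())
  rb$capacity <- as.integer(capacity)
  rb$s <- matrix(0, capacity, n_obs)
  rb$a <- integer(capacity)
  rb$r <- numeric(capacity)
  rb$s2 <- matrix(0, capacity, n_obs)
  rb$done <- logical(capacity)
  rb$size <- 0L
  rb$pos <- 0L   # next insertion slot - 1
  class(rb) <- "replay_buffer"
  rb
}

#' @rdname replay_buffer
#' @param rb a \code{replay_buffer}.
#' @param s,a,r,s2,done one transition.
#' @export
rb_add <- function(rb, s, a, r, s2, done) {
  rb$pos <- (rb$pos %% rb$capacity) + 1L
  rb$s[rb$pos, ] <- s
  rb$a[rb$pos] <- as.integer(a)
  rb$r[rb$pos] <- r
  rb$s2[rb$pos, ] <- s2
  rb$done[rb$pos] <- done
  rb$size <- min(rb$size + 1L, rb$capacity)
  invisible(rb)
}

#' @rdname replay_buffer
#' @param n minibatch size.
#' @export
rb_sample <- function(rb, n) {
  if (rb$size == 0L) stop("sampling from an empty replay buffer")
  idx <- sample.int(rb$size, n, replace = TRUE)
  list(s = rb$s[idx, , drop = FALSE], a = rb$a[idx], r = rb$r[idx],
       s2 = rb$s2[idx, , drop = FALSE], done = rb$done[idx])
}

#' Gradient of the batch TD loss
#'
#' Loss per transition: \eqn{(Q(s, a) - y)^2 / 2} with the bootstrap target
#' \eqn{y = r + \gamma (1 - done) \max_{a'} Q(s', a')} treated as a
#' constant (semi-gradient); only the taken action's output contributes.
#' Gradients are averaged over the batch.
#'
#' @param net a \code{q_net}.
#' @param batch a list as returned by \code{\link{rb_sample}}.
#' @param p a \code{q_learn_params}.
#' @return List with gradients \code{W1, b1, W2, b2} and the batch loss.
#' @export
q_gradient <- function(net, batch, p) {
  nb <- length(batch$a)
  g <- list(W1 = 0 * net$W1, b1 = 0 * net$b1,
            W2 = 0 * net$W2, b2 = 0 * net$b2)
  loss <- 0
  for (k in seq_len(nb)) {
    s <- batch$s[k, ]
    pre <- drop(net$W1 %*% s) + net$b1
    hidden <- pmax(0, pre)
    q <- drop(net$W2 %*% hidden) + net$b2
    a1 <- batch$a[k] + 1L
    y <- batch$r[k] +
      if (batch$done[k]) 0 else p$gamma * max(q_forward(net, batch$s2[k, ]))
    err <- q[a1] - y
    loss <- loss + 0.5 * err^2
    # backprop through the taken action only
    dq <- numeric(length(q)); dq[a1] <- err
    g$W2 <- g$W2 + outer(dq, hidden)
    g$b2 <- g$b2 + dq
    dh <- drop(t(net$W2) %*% dq) * (pre > 0)
    g$W1 <- g$W1 + outer(dh, s)
    g$b1 <- g$b1 + dh
  }
  g <- lapply(g, function(x) x / nb)
  g$loss <- loss / nb
  g
}

#' @noRd
adam_state <- function(net) {
  list(m = lapply(net[c("W1", "b1", "W2", "b2")], function(x) 0 * x),
       v = lapply(net[c("W1", "b1", "W2", "b2")], function(x) 0 * x),
       t = 0)
}

#' One ADAM update of the Q-network from a replay minibatch
#'
#' @param net a \code{q_net}.
#' @param batch minibatch from \code{\link{rb_sample}} (non-empty).
#' @param p a \code{q_learn_params}.
#' @param opt ADAM optimizer state (created internally if \code{NULL}).
#' @return List with the updated \code{net}, \code{opt} and batch
#'   \code{loss}.
#' @export
q_update <- function(net, batch, p, opt = NULL) {
  if (length(batch$a) == 0) stop("empty batch")
  if (is.null(opt)) opt <- adam_state(net)
  g <- q_gradient(net, batch, p)
  opt$t <- opt$t + 1
  for (nm in c("W1", "b1", "W2", "b2")) {
    opt$m[[nm]] <- p$beta1 * opt$m[[nm]] + (1 - p$beta1) * g[[nm]]
    opt$v[[nm]] <- p$beta2 * opt$v[[nm]] + (1 - p$beta2) * g[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - p$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - p$beta2^opt$t)
    net[[nm]] <- net[[nm]] - p$lr * mhat / (sqrt(vhat) + p$eps_adam)
  }
  list(net = net, opt = opt, loss = g$loss)
}

#' Train the Q-learning baseline on an environment
#'
#' Observations are normalized to [-1, 1] per dimension using the
#' environment's observation bounds before entering the MLP.  One gradient
#' update per environment step once the buffer holds a full batch.
#'
#' @param env environment with \code{env_reset}/\code{env_step} and an
#'   \code{obs_bounds} field.
#' @param p a \code{q_learn_params}.
#' @param n_episodes number of training episodes.
#' @param max_steps_per_episode episode step cap.
#' @param n_hidden hidden layer size.
#' @param seed integer seed.
#' @return List with the trained \code{net}, per-episode \code{rewards}
#'   and \code{steps}, and the normalization used.
#' @export
train_q_agent <- function(env, p = q_learn_params(), n_episodes = 100,
                          max_steps_per_episode = 1000, n_hidden = 64,
                          seed = 1) {
  set.seed(derive_seed(seed, "q-baseline"))
  lo <- vapply(env$obs_bounds, `[`, numeric(1), 1)
  hi <- vapply(env$obs_bounds, `[`, numeric(1), 2)
  normalize <- function(o) 2 * (o - lo) / (hi - lo) - 1
  n_obs <- length(lo)
  net <- q_network(n_obs, n_hidden, env$n_actions)
  opt <- NULL
  rb <- replay_buffer(p$capacity, n_obs)
  rewards <- numeric(n_episodes)
  steps <- integer(n_episodes)
  for (ep in seq_len(n_episodes)) {
    eps <- p$eps_end + (p$eps_start - p$eps_end) * p$eps_decay^(ep - 1)
    s <- normalize(env_reset(env))
    total <- 0
    for (st in seq_len(max_steps_per_episode)) {
      a <- epsilon_greedy(q_forward(net, s), eps)
      res <- env_step(env, a)
      s2 <- normalize(res$observation)
      rb_add(rb, s, a, res$reward, s2, res$done)
      total <- total + res$reward
      s <- s2
      if (rb$size >= p$batch_size) {
        upd <- q_update(net, rb_sample(rb, p$batch_size), p, opt)
        net <- upd$net; opt <- upd$opt
      }
      if (res$done) break
    }
    rewards[ep] <- total
    steps[ep] <- st
  }
  list(net = net, rewards = rewards, steps = steps,
       normalize = normalize, params = p, seed = seed)
}
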