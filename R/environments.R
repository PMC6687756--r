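#' Built-in benchmark environments
#'
#' Self-contained re-implementations of two classic reinforcement-learning
#' benchmarks behind a uniform \code{env_reset()} / \code{env_step()}
#' protocol returning \code{list(observation, reward, done)}.
#'
#' \strong{MountainCar}: an under-powered car in a valley must swing back
#' and forth to gain enough momentum to reach the goal on the right hill.
#' The canonical classic-control physics are pinned here: with action
#' \eqn{a \in \{0, 1, 2\}} (accelerate left / none / right),
#' \deqn{\dot x \leftarrow \dot x + 0.001 (a - 1) - 0.0025 \cos(3x),}
#' velocity clipped to \eqn{|\dot x| \le 0.07}, position to
#' \eqn{x \in [-1.2, 0.6]} (hitting the left wall zeroes the velocity);
#' the episode ends at \eqn{x \ge 0.5}.  Rewards are shaped: a small
#' punishment every step plus a bonus on reaching the goal, because an
#' actor-critic with purely excitatory input projections struggles to
#' represent a task with solely negative reinforcement.
#'
#' \strong{FrozenLake}: a 4x4 grid of start (S), frozen (F), hole (H) and
#' goal (G) tiles (standard map \code{SFFF/FHFH/FFFH/HFFG}), non-slippery:
#' moves are deterministic, off-grid moves leave the position unchanged.
#' Falling into a hole incurs a punishment and resets the agent to the
#' start \emph{without} ending the episode; reaching the goal pays +1 and
#' ends the episode; every step additionally costs a small punishment that
#' encourages exploration.
#'
#' @name environments
NULL

#' @rdname environments
#' @param env an environment object created by \code{\link{mountain_car}} or
#'   \code{\link{frozen_lake}}.
#' @export
env_reset <- function(env) UseMethod("env_reset")

#' @rdname environments
#' @param action integer action index (0-based).
#' @export
env_step <- function(env, action) UseMethod("env_step")

#' MountainCar environment with shaped rewards
#'
#' @param step_punishment reward added every step (default -0.01).
#' @param goal_bonus extra reward on reaching the goal position (default +1).
#' @param goal_x goal position (default 0.5).
#' @return A mutable environment object of class
#'   \code{c("mountain_car", "rl_env")}.  Start positions are drawn from the
#'   global RNG; seed it for reproducible episodes.
#' @export
mountain_car <- function(step_punishment = -0.01, goal_bonus = 1,
                         goal_x = 0.5) {
  e <- new.env(parent = emptyenv())
  e$x_min <- -1.2; e$x_max <- 0.6; e$v_max <- 0.07
  e$force <- 0.001; e$gravity <- 0.0025
  e$goal_x <- goal_x
  e$step_punishment <- step_punishment
  e$goal_bonus <- goal_bonus
  e$x <- -0.5; e$v <- 0
  e$cum_reward <- 0
  e$n_actions <- 3L
  e$obs_bounds <- list(c(e$x_min, e$x_max), c(-e$v_max, e$v_max))
  class(e) <- c("mountain_car", "rl_env")
  e
}

#' @export
env_reset.mountain_car <- function(env) {
  # classic uniform start near the trough, velocity zero
  env$x <- stats::runif(1, -0.6, -0.4)
  env$v <- 0
  c(env$x, env$v)
}

#' MountainCar transition
#'
#' @param env a \code{mountain_car} environment.
#' @param action 0 (accelerate left), 1 (no acceleration) or 2 (accelerate
#'   right).
#' @return \code{list(observation = c(x, v), reward, done)}.
#' @export
env_step.mountain_car <- function(env, action) {
  action <- as.integer(action)
  if (is.na(action) || action < 0 || action > 2) stop("invalid action")
  v <- env$v + env$force * (action - 1) - env$gravity * cos(3 * env$x)
  v <- max(-env$v_max, min(env$v_max, v))
  x <- env$x + v
  if (x < env$x_min) { x <- env$x_min; v <- 0 }
  if (x > env$x_max) x <- env$x_max
  done <- x >= env$goal_x
  reward <- env$step_punishment + if (done) env$goal_bonus else 0
  env$x <- x; env$v <- v
  env$cum_reward <- env$cum_reward + reward
  list(observation = c(x, v), reward = reward, done = done)
}

#' FrozenLake 4x4 grid world (non-slippery)
#'
#' States are indexed row-major from 0 at the top-left; actions are
#' \code{0 = west, 1 = north, 2 = east, 3 = south}.
#'
#' @param map character vector of 4 rows over \{S, F, H, G\}; the default is
#'   the standard map.
#' @param step_punishment reward added every step (default -0.01).
#' @param hole_punishment additional reward for falling into a hole
#'   (default -0.2; the agent is reset to S without ending the episode).
#' @param goal_reward reward for reaching the goal (default +1; ends the
#'   episode).
#' @return A mutable environment object of class
#'   \code{c("frozen_lake", "rl_env")}.
#' @export
frozen_lake <- function(map = c("SFFF", "FHFH", "FFFH", "HFFG"),
                        step_punishment = -0.01, hole_punishment = -0.2,
                        goal_reward = 1) {
  tiles <- unlist(strsplit(map, ""))
  side <- length(map)
  stopifnot(length(tiles) == side * nchar(map[1]),
            all(tiles %in% c("S", "F", "H", "G")),
            sum(tiles == "S") == 1, sum(tiles == "G") == 1)
  e <- new.env(parent = emptyenv())
  e$tiles <- tiles
  e$nrow <- side
  e$ncol <- nchar(map[1])
  e$n_states <- length(tiles)
  e$start <- which(tiles == "S") - 1L
  e$goal <- which(tiles == "G") - 1L
  e$pos <- e$start
  e$cum_reward <- 0
  e$n_actions <- 4L
  e$step_punishment <- step_punishment
  e$hole_punishment <- hole_punishment
  e$goal_reward <- goal_reward
  e$slippery <- FALSE
  class(e) <- c("frozen_lake", "rl_env")
  e
}

#' @export
env_reset.frozen_lake <- function(env) {
  env$pos <- env$start
  env$pos
}

#' @noRd
fl_move <- function(env, pos, action) {
  row <- pos %/% env$ncol
  col <- pos %% env$ncol
  if (action == 0L) col <- col - 1L        # west
  else if (action == 1L) row <- row - 1L   # north
  else if (action == 2L) col <- col + 1L   # east
  else row <- row + 1L                     # south
  if (row < 0 || row >= env$nrow || col < 0 || col >= env$ncol) pos
  else row * env$ncol + col
}

#' FrozenLake transition
#'
#' Deterministic when non-slippery: a pure function of (position, action).
#' Entering a hole adds the hole punishment and teleports the agent back to
#' the start; entering the goal pays the goal reward and ends the episode;
#' every step adds the step punishment.
#'
#' @param env a \code{frozen_lake} environment.
#' @param action 0 = west, 1 = north, 2 = east, 3 = south.
#' @return \code{list(observation = state index, reward, done)}.
#' @export
env_step.frozen_lake <- function(env, action) {
  action <- as.integer(action)
  if (is.na(action) || action < 0 || action > 3) stop("invalid action")
  new_pos <- fl_move(env, env$pos, action)
  tile <- env$tiles[new_pos + 1L]
  reward <- env$step_punishment
  done <- FALSE
  if (tile == "H") {
    reward <- reward + env$hole_punishment
    new_pos <- env$start
  } else if (tile == "G") {
    reward <- reward + env$goal_reward
    done <- TRUE
  }
  env$pos <- new_pos
  env$cum_reward <- env$cum_reward + reward
  list(observation = new_pos, reward = reward, done = done)
}

#' Shortest path from start to goal on a FrozenLake map
#'
#' Breadth-first search over non-hole tiles with 4-neighbourhood moves.
#'
#' @param env a \code{frozen_lake} environment.
#' @return The number of moves on the shortest S-to-G path.
#' @export
shortest_path_length <- function(env) {
  dist <- rep(NA_integer_, env$n_states)
  dist[env$start + 1L] <- 0L
  queue <- env$start
  while (length(queue) > 0) {
    pos <- queue[1]; queue <- queue[-1]
    if (pos == env$goal) return(dist[pos + 1L])
    for (a in 0:3) {
      np <- fl_move(env, pos, a)
      if (env$tiles[np + 1L] != "H" && is.na(dist[np + 1L])) {
        dist[np + 1L] <- dist[pos + 1L] + 1L
        queue <- c(queue, np)
      }
    }
  }
  stop("goal not reachable from start")
}

#' BFS-optimal action sequence on a FrozenLake map
#'
#' Reconstructs one shortest S-to-G action sequence (ties broken toward the
#' lowest action index).  Useful as a scripted optimal agent in tests.
#'
#' @param env a \code{frozen_lake} environment.
#' @return Integer vector of actions of length
#'   \code{shortest_path_length(env)}.
#' @export
optimal_action_sequence <- function(env) {
  dist <- rep(NA_integer_, env$n_states)
  prev <- rep(NA_integer_, env$n_states)
  prev_a <- rep(NA_integer_, env$n_states)
  dist[env$start + 1L] <- 0L
  queue <- env$start
  while (length(queue) > 0) {
    pos <- queue[1]; queue <- queue[-1]
    for (a in 0:3) {
      np <- fl_move(env, pos, a)
      if (np != pos && env$tiles[np + 1L] != "H" && is.na(dist[np + 1L])) {
        dist[np + 1L] <- dist[pos + 1L] + 1L
        prev[np + 1L] <- pos
        prev_a[np + 1L] <- a
        queue <- c(queue, np)
      }
    }
  }
  if (is.na(dist[env$goal + 1L])) stop("goal not reachable from start")
  actions <- integer(0)
  pos <- env$goal
  while (pos != env$start) {
    actions <- c(prev_a[pos + 1L], actions)
    pos <- prev[pos + 1L]
  }
  actions
}
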