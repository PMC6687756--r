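#' Closed-loop driver
#'
#' Couples an agent and an environment on two time grids: the network
#' evolves every \code{network_dt} ms while the environment is stepped only
#' every \code{env_step_interval} ms.  Between environment steps the
#' observation, the reward (as a constant rate) and the selected action are
#' held (zero-order hold).  When an episode ends the environment is reset
#' after a break of \code{episode_break} ms during which the network keeps
#' evolving with zero observation drive; the terminal reward is delivered
#' during the first environment interval of the break so the network
#' experiences it, after which the reward is zero.  Plasticity remains
#' enabled throughout.
#'
#' @name closed-loop
NULL

#' Configuration of a closed-loop run
#'
#' @param network_dt network integration step (ms).
#' @param env_step_interval interval between environment steps (ms); must be
#'   an integer multiple of \code{network_dt}.
#' @param episode_break pause after each episode (ms, >= 0) during which the
#'   network relaxes with zero drive before the environment is reset.
#' @param max_steps stop after this many environment steps (may be
#'   \code{Inf} if \code{max_episodes} is finite).
#' @param max_episodes stop after this many completed episodes.
#' @param seed integer seed; the run is bit-reproducible given
#'   (agent config, loop config, seed).
#' @param record_activities if \code{TRUE}, store critic and RPE unit
#'   activities at every environment step in the log.
#' @return A list of class \code{loop_config}.
#' @export
loop_config <- function(network_dt = 1, env_step_interval = 10,
                        episode_break = 50, max_steps = Inf,
                        max_episodes = Inf, seed = 1,
                        record_activities = TRUE) {
  ratio <- env_step_interval / network_dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("env_step_interval must be an integer multiple of network_dt")
  stopifnot(network_dt > 0, episode_break >= 0,
            is.finite(max_steps) || is.finite(max_episodes))
  structure(list(network_dt = network_dt,
                 env_step_interval = env_step_interval,
                 episode_break = episode_break,
                 max_steps = max_steps, max_episodes = max_episodes,
                 seed = seed, record_activities = record_activities),
            class = "loop_config")
}

#' Run an agent in an environment
#'
#' Seeds the global RNG from \code{cfg$seed}, then repeats: advance the
#' network for one environment interval while holding the current
#' observation and reward, read out the selected action, and step the
#' environment.  Returns a complete, seed-reproducible log.
#'
#' @param agent an object with an \code{\link{agent_step}} method.
#' @param env an environment with \code{env_reset}/\code{env_step} methods.
#' @param cfg a \code{loop_config}.
#' @return An object of class \code{episode_log}: list with
#'   \code{steps} (data.frame: t, episode, action, reward, and observation /
#'   activity columns), \code{episodes} (data.frame: episode, n_steps,
#'   total_reward), \code{n_env_steps}, \code{n_network_steps},
#'   \code{n_break_steps}, \code{env_cum_reward}, \code{seed} and a
#'   \code{config_hash} identifying the loop configuration.
#' @export
run_closed_loop <- function(agent, env, cfg) {
  stopifnot(inherits(cfg, "loop_config"))
  set.seed(derive_seed(cfg$seed, "closed-loop"))
  spe <- as.integer(round(cfg$env_step_interval / cfg$network_dt))
  n_break <- as.integer(round(cfg$episode_break / cfg$network_dt))
  cap <- if (is.finite(cfg$max_steps)) as.integer(cfg$max_steps) else 4096L
  t_v <- numeric(cap); ep_v <- integer(cap); act_v <- integer(cap)
  rew_v <- numeric(cap); obs_l <- vector("list", cap)
  critic_v <- numeric(cap); rpe_v <- numeric(cap)
  grow <- function(k) {
    if (k <= cap) return(invisible())
    cap2 <- cap * 2L
    length(t_v) <<- cap2; length(ep_v) <<- cap2; length(act_v) <<- cap2
    length(rew_v) <<- cap2; length(obs_l) <<- cap2
    length(critic_v) <<- cap2; length(rpe_v) <<- cap2
    cap <<- cap2
  }
  episodes <- list()
  n_env <- 0L; n_net <- 0L; n_brk <- 0L
  episode <- 1L
  ep_steps <- 0L; ep_reward <- 0
  if (cfg$max_episodes == 0 ||
      (is.finite(cfg$max_steps) && cfg$max_steps == 0)) {
    return(finish_log(list(), list(), 0L, 0L, 0L, env, cfg))
  }
  obs <- env_reset(env)
  held_reward <- 0
  action <- 0L
  repeat {
    for (k in seq_len(spe)) {
      action <- agent_step(agent, obs, held_reward, cfg$network_dt)
      n_net <- n_net + 1L
    }
    res <- env_step(env, action)
    n_env <- n_env + 1L
    ep_steps <- ep_steps + 1L
    ep_reward <- ep_reward + res$reward
    grow(n_env)
    t_v[n_env] <- n_net * cfg$network_dt
    ep_v[n_env] <- episode
    act_v[n_env] <- action
    rew_v[n_env] <- res$reward
    obs_l[[n_env]] <- obs
    if (cfg$record_activities && inherits(agent, "rl_agent")) {
      sig <- agent_signals(agent)
      critic_v[n_env] <- sig[["critic"]]
      rpe_v[n_env] <- sig[["rpe"]]
    }
    held_reward <- res$reward / cfg$env_step_interval
    obs <- res$observation
    if (res$done) {
      episodes[[episode]] <- c(episode = episode, n_steps = ep_steps,
                               total_reward = ep_reward)
      # break: zero drive; terminal reward held for one interval
      if (n_break > 0) {
        for (k in seq_len(n_break)) {
          agent_step(agent, NULL, if (k <= spe) held_reward else 0,
                     cfg$network_dt)
          n_net <- n_net + 1L
          n_brk <- n_brk + 1L
        }
      }
      held_reward <- 0
      if (episode >= cfg$max_episodes) break
      episode <- episode + 1L
      ep_steps <- 0L; ep_reward <- 0
      obs <- env_reset(env)
    }
    if (n_env >= cfg$max_steps) break
  }
  if (ep_steps > 0 && (length(episodes) < episode)) {
    episodes[[episode]] <- c(episode = episode, n_steps = ep_steps,
                             total_reward = ep_reward, incomplete = 1)
  }
  steps <- list(t = t_v[seq_len(n_env)], episode = ep_v[seq_len(n_env)],
                action = act_v[seq_len(n_env)],
                reward = rew_v[seq_len(n_env)], obs = obs_l[seq_len(n_env)],
                critic = critic_v[seq_len(n_env)],
                rpe = rpe_v[seq_len(n_env)])
  finish_log(steps, episodes, n_env, n_net, n_brk, env, cfg)
}

#' @noRd
finish_log <- function(steps, episodes, n_env, n_net, n_brk, env, cfg) {
  if (n_env > 0) {
    obs_mat <- do.call(rbind, lapply(steps$obs, function(o) as.numeric(o)))
    colnames(obs_mat) <- paste0("obs", seq_len(ncol(obs_mat)))
    step_df <- data.frame(t = steps$t, episode = steps$episode,
                          action = steps$action, reward = steps$reward,
                          obs_mat, critic = steps$critic, rpe = steps$rpe)
  } else {
    step_df <- data.frame(t = numeric(0), episode = integer(0),
                          action = integer(0), reward = numeric(0))
  }
  ep_df <- if (length(episodes) > 0) {
    as.data.frame(do.call(rbind, lapply(episodes, function(e) {
      e[c("episode", "n_steps", "total_reward")]
    })))
  } else {
    data.frame(episode = numeric(0), n_steps = numeric(0),
               total_reward = numeric(0))
  }
  structure(list(steps = step_df, episodes = ep_df,
                 n_env_steps = n_env, n_network_steps = n_net,
                 n_break_steps = n_brk,
                 env_cum_reward = env$cum_reward, seed = cfg$seed,
                 config_hash = derive_seed(0, paste(
                   vapply(cfg, function(x) paste(format(x), collapse = ","),
                          character(1)), collapse = ";"))),
            class = "episode_log")
}

#' @export
print.episode_log <- function(x, ...) {
  cat("closed-loop episode log:", x$n_env_steps, "env steps,",
      nrow(x$episodes), "episodes,", x$n_network_steps, "network steps\n")
  if (nrow(x$episodes) > 0) {
    cat("  mean episode reward:",
        signif(mean(x$episodes$total_reward), 4), "\n")
  }
  invisible(x)
}

#' Write an episode log to disk
#'
#' Per-step records go to a CSV file, per-episode summaries and run
#' metadata to a JSON file next to it.
#'
#' @param log an \code{episode_log}.
#' @param path basename (without extension) for the two output files.
#' @return Invisibly, the two file paths.
#' @export
write_episode_log <- function(log, path) {
  csv <- paste0(path, "_steps.csv")
  js <- paste0(path, "_summary.json")
  utils::write.csv(log$steps, csv, row.names = FALSE)
  jsonlite::write_json(
    list(episodes = log$episodes, n_env_steps = log$n_env_steps,
         n_network_steps = log$n_network_steps,
         n_break_steps = log$n_break_steps,
         env_cum_reward = log$env_cum_reward, seed = log$seed),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
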