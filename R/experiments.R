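#' End-to-end benchmark experiments
#'
#' Reproducible multi-seed training runs of the two built-in benchmarks
#' (and the Q-learning comparison), with learning-curve aggregation,
#' convergence detection and, for the discrete task, the learned policy
#' and value map.
#'
#' Performance is summarized the way the two tasks are usually reported:
#' per-episode total reward for MountainCar (mean and s.d. across seeds),
#' and for FrozenLake the average reward per environment step over the
#' next 500 steps, as a function of the step at which the window starts.
#'
#' @name experiments
NULL

#' Default configuration of a benchmark experiment
#'
#' Returns the complete set of parameters defining the study conditions of
#' one experiment; every entry can be overridden via \code{...}.
#'
#' @param experiment \code{"frozenlake"}, \code{"mountaincar"} or
#'   \code{"mountaincar_q"}.
#' @param ... named overrides of individual defaults.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(experiment = c("frozenlake", "mountaincar",
                                             "mountaincar_q"), ...) {
  experiment <- match.arg(experiment)
  cfg <- switch(experiment,
    frozenlake = list(
      experiment = "frozenlake",
      n_seeds = 5, seed = 1,
      max_steps = 4000, max_episodes = Inf,
      network_dt = 1, env_step_interval = 10, episode_break = 50,
      step_punishment = -0.01, hole_punishment = -0.2, goal_reward = 1,
      window = 500, optimal_fraction = 0.95,
      agent = agent_config_frozenlake()),
    mountaincar = list(
      experiment = "mountaincar",
      n_seeds = 10, seed = 1,
      max_steps = 15000, max_episodes = 15,
      network_dt = 1, env_step_interval = 10, episode_break = 50,
      step_punishment = -0.01, goal_bonus = 1,
      convergence_tolerance = 0.1,
      agent = agent_config_mountaincar()),
    mountaincar_q = list(
      experiment = "mountaincar_q",
      n_seeds = 10, seed = 1,
      n_episodes = 60, max_steps_per_episode = 1000,
      step_punishment = -0.01, goal_bonus = 1,
      n_hidden = 64, q_params = q_learn_params())
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "experiment_config")
}

#' Preset agent configuration for FrozenLake
#'
#' 16 non-overlapping (one-hot) place cells, a 4-unit winner-take-all actor
#' on a ring (the four compass directions are cyclically adjacent), and an
#' eligibility delay of one environment step so that plasticity credits the
#' state-action pair that produced the current reward despite the sharp
#' input transitions of the discrete task.
#'
#' @param ... overrides passed to \code{\link{agent_config}}.
#' @return An \code{agent_config}.
#' @export
agent_config_frozenlake <- function(...) {
  defaults <- list(layout = 16, n_actions = 4, wta_metric = "ring",
                   tau_input = 1, tau_actor = 2, tau_critic = 2,
                   tau_rpe = 1,
                   wta_exc = 0.1, wta_inh = 1,
                   sigma_explore = 0.15, noise_hold = 10,
                   eta = 0.3, eta_critic = 0.1,
                   tau_r = 200, d = 2, delta_t = 10,
                   theta_post_actor = 0.15, w_min_actor = 0.01,
                   w_min_critic = -0.5, critic_init = 0.4)
  args <- utils::modifyList(defaults, list(...))
  do.call(agent_config, args)
}

#' Preset agent configuration for MountainCar
#'
#' 25 place cells on an even 5x5 grid over the position-velocity plane
#' (Gaussian tuning, width equal to the grid spacing) and a 3-unit
#' winner-take-all actor on a line (the ordered accelerations left / none /
#' right); no eligibility delay, since the overlapping tuning curves carry
#' the recent past implicitly.
#'
#' @param ... overrides passed to \code{\link{agent_config}}.
#' @return An \code{agent_config}.
#' @export
agent_config_mountaincar <- function(...) {
  layout <- make_grid_layout(list(c(-1.2, 0.6), c(-0.07, 0.07)),
                             n_per_dim = 5, width_scale = 1)
  defaults <- list(layout = layout, n_actions = 3, wta_metric = "line",
                   tau_input = 1, tau_actor = 2, tau_critic = 2,
                   tau_rpe = 1,
                   wta_exc = 0.1, wta_inh = 1,
                   sigma_explore = 0.25, noise_hold = 50,
                   eta = 0.1, eta_critic = 0.05,
                   tau_r = 500, d = 2, delta_t = 0,
                   theta_post_actor = 0.15, w_min_actor = 0.01,
                   w_min_critic = -0.15, critic_init = 0.2)
  args <- utils::modifyList(defaults, list(...))
  do.call(agent_config, args)
}

#' Theoretical optimal reward per step on a FrozenLake map
#'
#' With a shortest S-to-G path of L moves, an agent cycling the optimal
#' path collects the goal reward every L steps, so the optimal reward per
#' step is \code{goal_reward / L} (about 0.16 on the standard map), or
#' \code{(goal_reward + L * step_punishment) / L} when the shaping
#' punishment is charged to the agent.
#'
#' @param env a \code{frozen_lake} environment.
#' @param shaped include the per-step punishment (default TRUE).
#' @return Optimal reward per environment step.
#' @export
fl_optimal_reward_per_step <- function(env, shaped = TRUE) {
  L <- shortest_path_length(env)
  if (shaped) (env$goal_reward + L * env$step_punishment) / L
  else env$goal_reward / L
}

#' First index at which a performance curve enters and stays near optimum
#'
#' Returns the first index k such that \code{curve[k:length(curve)]} never
#' drops below \code{threshold} again, or \code{NA_integer_} ("not
#' converged") if the curve never enters or does not stay.
#'
#' @param curve numeric performance series (higher is better).
#' @param threshold the performance level that counts as optimal.
#' @return Integer index into \code{curve}, or \code{NA_integer_}.
#' @export
convergence_step <- function(curve, threshold) {
  if (length(curve) == 0) stop("empty curve")
  ok <- curve >= threshold
  if (!ok[length(ok)]) return(NA_integer_)
  # last position of a failure, +1
  bad <- which(!ok)
  if (length(bad) == 0) 1L else max(bad) + 1L
}

#' Run a multi-seed benchmark experiment
#'
#' Executes \code{n_seeds} independent trainings (seeds derived
#' deterministically from \code{cfg$seed}), aggregates the learning curves
#' and, for FrozenLake, extracts the learned policy and value map of the
#' final agent of each seed.
#'
#' @param cfg an \code{experiment_config}.
#' @param output_dir optional directory; if given, per-seed logs (CSV),
#'   the summary (JSON) and learning-curve figures (PNG + CSV) are written
#'   there.
#' @param verbose print per-seed progress.
#' @return A list of class \code{run_summary}; contents depend on the
#'   experiment (see the vignette).
#' @export
run_experiment <- function(cfg, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- switch(cfg$experiment,
                frozenlake = run_experiment_frozenlake(cfg, verbose),
                mountaincar = run_experiment_mountaincar(cfg, verbose),
                mountaincar_q = run_experiment_mountaincar_q(cfg, verbose))
  out$config <- cfg
  class(out) <- "run_summary"
  if (!is.null(output_dir)) write_run_summary(out, output_dir)
  out
}

#' @noRd
run_experiment_frozenlake <- function(cfg, verbose = FALSE) {
  logs <- vector("list", cfg$n_seeds)
  maps <- vector("list", cfg$n_seeds)
  curves <- vector("list", cfg$n_seeds)
  conv <- integer(cfg$n_seeds)
  env0 <- frozen_lake(step_punishment = cfg$step_punishment,
                      hole_punishment = cfg$hole_punishment,
                      goal_reward = cfg$goal_reward)
  optimum <- fl_optimal_reward_per_step(env0)
  threshold <- cfg$optimal_fraction * optimum
  for (s in seq_len(cfg$n_seeds)) {
    seed_s <- derive_seed(cfg$seed, paste0("frozenlake-", s))
    env <- frozen_lake(step_punishment = cfg$step_punishment,
                       hole_punishment = cfg$hole_punishment,
                       goal_reward = cfg$goal_reward)
    agent <- build_agent(cfg$agent, seed = seed_s)
    lcfg <- loop_config(network_dt = cfg$network_dt,
                        env_step_interval = cfg$env_step_interval,
                        episode_break = cfg$episode_break,
                        max_steps = cfg$max_steps,
                        max_episodes = cfg$max_episodes, seed = seed_s)
    log <- run_closed_loop(agent, env, lcfg)
    curve <- moving_average(log$steps$reward, cfg$window)
    logs[[s]] <- log
    curves[[s]] <- curve
    conv[s] <- convergence_step(curve, threshold)
    maps[[s]] <- extract_policy_value(agent, 0:(env$n_states - 1))
    if (verbose)
      message("seed ", s, ": converged at env step ", conv[s])
  }
  cmat <- do.call(rbind, curves)
  col_sd <- if (nrow(cmat) > 1) apply(cmat, 2, stats::sd)
            else rep(0, ncol(cmat))
  list(experiment = "frozenlake",
       logs = logs, curves = curves, policy_value = maps,
       curve_mean = colMeans(cmat), curve_sd = col_sd,
       optimum = optimum, threshold = threshold,
       convergence_steps = conv,
       mean_convergence_step = mean(conv))
}

#' @noRd
run_experiment_mountaincar <- function(cfg, verbose = FALSE) {
  logs <- vector("list", cfg$n_seeds)
  rewards <- list()
  for (s in seq_len(cfg$n_seeds)) {
    seed_s <- derive_seed(cfg$seed, paste0("mountaincar-", s))
    env <- mountain_car(step_punishment = cfg$step_punishment,
                        goal_bonus = cfg$goal_bonus)
    agent <- build_agent(cfg$agent, seed = seed_s)
    lcfg <- loop_config(network_dt = cfg$network_dt,
                        env_step_interval = cfg$env_step_interval,
                        episode_break = cfg$episode_break,
                        max_steps = cfg$max_steps,
                        max_episodes = cfg$max_episodes, seed = seed_s)
    log <- run_closed_loop(agent, env, lcfg)
    logs[[s]] <- log
    rewards[[s]] <- log$episodes$total_reward
    if (verbose)
      message("seed ", s, ": episode rewards ",
              paste(signif(rewards[[s]], 3), collapse = " "))
  }
  n_ep <- min(lengths(rewards))
  rmat <- do.call(rbind, lapply(rewards, `[`, seq_len(n_ep)))
  best <- max(rmat)
  # convergence: reward stays within tol of the best observed episode.
  # tol is a fraction of the learning range (best minus the naive
  # first-episode performance): with the shaped rewards the best episode
  # sits near zero, so a band relative to |best| alone would be
  # degenerate on this scale.
  range <- best - mean(rmat[, 1])
  tol <- cfg$convergence_tolerance * max(1, range)
  conv <- apply(rmat, 1, function(r) convergence_step(r, best - tol))
  list(experiment = "mountaincar",
       logs = logs, reward_matrix = rmat,
       reward_mean = colMeans(rmat),
       reward_sd = if (nrow(rmat) > 1) apply(rmat, 2, stats::sd)
                   else rep(0, ncol(rmat)),
       best_episode_reward = best,
       convergence_threshold = best - tol,
       convergence_episode = conv,
       mean_convergence_episode = mean(conv))
}

#' @noRd
run_experiment_mountaincar_q <- function(cfg, verbose = FALSE) {
  rewards <- list()
  for (s in seq_len(cfg$n_seeds)) {
    seed_s <- derive_seed(cfg$seed, paste0("mountaincar-q-", s))
    env <- mountain_car(step_punishment = cfg$step_punishment,
                        goal_bonus = cfg$goal_bonus)
    set.seed(seed_s)
    fit <- train_q_agent(env, cfg$q_params, n_episodes = cfg$n_episodes,
                         max_steps_per_episode = cfg$max_steps_per_episode,
                         n_hidden = cfg$n_hidden, seed = seed_s)
    rewards[[s]] <- fit$rewards
    if (verbose) message("seed ", s, ": final reward ",
                         signif(utils::tail(fit$rewards, 1), 3))
  }
  rmat <- do.call(rbind, rewards)
  list(experiment = "mountaincar_q",
       reward_matrix = rmat,
       reward_mean = colMeans(rmat),
       reward_sd = if (nrow(rmat) > 1) apply(rmat, 2, stats::sd)
                   else rep(0, ncol(rmat)))
}

#' Write a run summary (CSV series, JSON summary, PNG figures)
#'
#' Every plotted series is also written as CSV so each figure can be
#' re-derived from text files.
#'
#' @param summary a \code{run_summary}.
#' @param output_dir directory to create/write into.
#' @return Invisibly, the paths written.
#' @export
write_run_summary <- function(summary, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(output_dir, f)
  if (summary$experiment == "frozenlake") {
    df <- data.frame(step = seq_along(summary$curve_mean),
                     mean = summary$curve_mean, sd = summary$curve_sd)
    utils::write.csv(df, p("learning_curve.csv"), row.names = FALSE)
    grDevices::png(p("learning_curve.png"), 800, 500)
    plot(df$step, df$mean, type = "l", col = "darkorange", lwd = 2,
         xlab = "environment step", ylab = "reward per step (next 500)",
         main = "FrozenLake learning curve",
         ylim = range(c(df$mean - df$sd, df$mean + df$sd, summary$optimum)))
    graphics::polygon(c(df$step, rev(df$step)),
                      c(df$mean - df$sd, rev(df$mean + df$sd)),
                      col = grDevices::adjustcolor("darkorange", 0.25),
                      border = NA)
    graphics::abline(h = summary$optimum, col = "gray40", lty = 2)
    grDevices::dev.off()
    pv <- do.call(rbind, lapply(seq_along(summary$policy_value), \(s)
      cbind(seed = s, summary$policy_value[[s]])))
    utils::write.csv(pv, p("policy_value_map.csv"), row.names = FALSE)
    js <- list(mean_convergence_step = summary$mean_convergence_step,
               convergence_steps = summary$convergence_steps,
               optimum = summary$optimum, threshold = summary$threshold)
  } else {
    df <- data.frame(episode = seq_along(summary$reward_mean),
                     mean = summary$reward_mean, sd = summary$reward_sd)
    utils::write.csv(df, p("learning_curve.csv"), row.names = FALSE)
    grDevices::png(p("learning_curve.png"), 800, 500)
    plot(df$episode, df$mean, type = "b", col = "darkorange", lwd = 2,
         xlab = "episode", ylab = "total reward per episode",
         main = paste(summary$experiment, "learning curve"))
    graphics::arrows(df$episode, df$mean - df$sd, df$episode,
                     df$mean + df$sd, angle = 90, code = 3, length = 0.03,
                     col = "darkorange")
    grDevices::dev.off()
    js <- list(reward_mean = summary$reward_mean,
               reward_sd = summary$reward_sd)
    if (!is.null(summary$mean_convergence_episode))
      js$mean_convergence_episode <- summary$mean_convergence_episode
  }
  jsonlite::write_json(js, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read an experiment configuration from JSON or YAML
#'
#' The file holds named overrides of \code{\link{experiment_config}}
#' defaults; nested \code{agent} entries override the preset agent
#' configuration.
#'
#' @param path path to a .json or .yaml/.yml file with at least an
#'   \code{experiment} entry.
#' @return An \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(raw$experiment)) stop("config must name an 'experiment'")
  experiment <- raw$experiment
  raw$experiment <- NULL
  agent_over <- raw$agent
  raw$agent <- NULL
  cfg <- do.call(experiment_config, c(list(experiment = experiment), raw))
  if (!is.null(agent_over)) {
    maker <- switch(experiment,
                    frozenlake = agent_config_frozenlake,
                    mountaincar = agent_config_mountaincar,
                    stop("agent overrides not supported for ", experiment))
    cfg$agent <- do.call(maker, agent_over)
  }
  cfg
}

#' Validate an experiment configuration
#'
#' @param cfg an \code{experiment_config}.
#' @return Invisibly \code{TRUE}; errors describe the first violated
#'   constraint.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!cfg$experiment %in% c("frozenlake", "mountaincar", "mountaincar_q"))
    stop("unknown experiment")
  stopifnot(cfg$n_seeds >= 1, cfg$seed == round(cfg$seed))
  if (!is.null(cfg$agent)) {
    ratio <- cfg$env_step_interval / cfg$network_dt
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("env_step_interval must be a multiple of network_dt")
    if (cfg$agent$d %% cfg$network_dt != 0)
      stop("RPE delay d must be a multiple of network_dt")
  }
  invisible(TRUE)
}
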