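# Actor-critic wiring: WTA circuit, construction, policy read-out

test_that("WTA weights: self/neighbour excitation, distal inhibition,
          symmetry", {
  w <- build_wta_weights(3, exc = 0.3, inh = 1, metric = "line")
  expect_equal(diag(w), rep(0.3, 3))
  expect_equal(w[1, 3], -1)   # maximally distant on a line
  expect_equal(w[1, 2], -1)   # self-only excitation by default
  # neighbour excitation when the range is widened
  w1 <- build_wta_weights(3, exc = 0.3, inh = 1, metric = "line",
                          exc_range = 1)
  expect_equal(w1[1, 2], 0.3)
  expect_equal(w1[1, 3], -1)
  # ring metric: first and last are neighbours
  wr <- build_wta_weights(4, exc = 0.2, inh = 0.9, metric = "ring",
                          exc_range = 1)
  expect_equal(wr[1, 4], 0.2)
  expect_equal(wr[1, 3], -0.9)
  # symmetry for all sizes up to 6, both metrics
  for (n in 2:6) for (m in c("line", "ring")) {
    wm <- build_wta_weights(n, exc = 0.4, inh = 1.2, metric = m)
    expect_equal(wm, t(wm))
  }
  expect_error(build_wta_weights(1, 1, 1), "n_actions")
})

test_that("agent construction: shapes, determinism, weight floors", {
  cfg <- agent_config_mountaincar()
  ag <- build_agent(cfg, seed = 42)
  expect_equal(dim(ag$W0$w[ag$idx_act, ag$idx_in]), c(3L, 25L))
  expect_length(ag$W0$w[ag$idx_critic, ag$idx_in], 25)
  expect_true(all(ag$W0$w[ag$idx_act, ag$idx_in] >= cfg$w_min_actor))
  # same (cfg, seed) -> identical initial weights
  ag2 <- build_agent(cfg, seed = 42)
  expect_identical(ag$W0$w, ag2$W0$w)
  ag3 <- build_agent(cfg, seed = 43)
  expect_false(identical(ag$W0$w, ag3$W0$w))
  # RPE wiring: one instantaneous and one delayed critic link
  expect_equal(ag$W0$w[ag$idx_rpe, ag$idx_critic], 1 / cfg$d - 1 / cfg$tau_r)
  expect_equal(ag$Wd$w[ag$idx_rpe, ag$idx_critic], -1 / cfg$d)
})

test_that("frozen learning (eta = 0) leaves weights untouched", {
  cfg <- agent_config_frozenlake(eta = 0, eta_critic = 0)
  ag <- build_agent(cfg, seed = 1)
  w_before <- ag$W0$w
  set.seed(2)
  for (k in 1:200) agent_step(ag, sample(0:15, 1), -0.001)
  expect_identical(ag$W0$w, w_before)
})

test_that("exploration: with floor weights every action is tried", {
  cfg <- agent_config_frozenlake(eta = 0, eta_critic = 0)
  ag <- build_agent(cfg, seed = 3)
  set.seed(4)
  acts <- integer(1000)
  for (k in 1:1000) acts[k] <- agent_step(ag, 0L, 0)
  expect_setequal(unique(acts), 0:3)
})

test_that("WTA follows a dominant feedforward drive", {
  cfg <- agent_config_frozenlake(eta = 0, eta_critic = 0)
  ag <- build_agent(cfg, seed = 5)
  # hand-set a strong input -> actor column for action 2 at state 7
  ag$W0$w[ag$idx_act, ag$idx_in][, 8] <- 0.05
  ag$W0$w[ag$idx_act, ag$idx_in][3, 8] <- 2
  set.seed(6)
  acts <- integer(50)
  for (k in 1:50) {
    for (j in 1:10) a <- agent_step(ag, 7L, 0)
    acts[k] <- a
  }
  expect_gt(mean(acts == 2L), 0.9)
})

test_that("WTA exclusivity and persistence under constant drive", {
  for (n_actions in c(3, 4)) {
    cfg <- agent_config(layout = 4, n_actions = n_actions,
                        tau_actor = 2, wta_exc = 0.1, wta_inh = 1,
                        wta_metric = if (n_actions == 4) "ring" else "line",
                        sigma_explore = 0, eta = 0, eta_critic = 0,
                        theta_post_actor = 0.05)
    ag <- build_agent(cfg, seed = 7)
    # distinct constant feedforward drives, no noise
    drives <- 0.2 + 0.1 * seq_len(n_actions)
    ag$W0$w[ag$idx_act, ag$idx_in][, 1] <- drives
    winners <- integer(300)
    for (k in 1:300) winners[k] <- agent_step(ag, 0L, 0)
    # after settling, exactly one unit above the postsynaptic gate
    z_act <- ag$state$z[ag$idx_act]
    expect_equal(sum(z_act > cfg$theta_post_actor), 1)
    expect_equal(which.max(z_act), n_actions)  # largest drive wins
    # the winner persists over at least 100 consecutive steps
    expect_true(all(winners[200:300] == n_actions - 1L))
  }
})

test_that("policy/value read-out has no side effects and follows weights", {
  cfg <- agent_config_frozenlake(eta = 0, eta_critic = 0)
  ag <- build_agent(cfg, seed = 8)
  Wa <- ag$W0$w[ag$idx_act, ag$idx_in]
  # uniform weights -> uniform value map, tie-ruled policy
  ag$W0$w[ag$idx_act, ag$idx_in] <- 0.1
  ag$W0$w[ag$idx_critic, ag$idx_in] <- 0.25
  pv <- extract_policy_value(ag, 0:15)
  expect_equal(pv$value, rep(0.25, 16))
  expect_equal(pv$action, rep(0L, 16))       # lowest-index tie rule
  # hand-crafted preference: "east" in state 0
  ag$W0$w[ag$idx_act, ag$idx_in][3, 1] <- 5
  pv <- extract_policy_value(ag, 0:15)
  expect_equal(pv$action[1], 2L)
  # read-out did not alter weights or state
  z_before <- ag$state$z
  extract_policy_value(ag, 0:15)
  expect_identical(ag$state$z, z_before)
})

test_that("no plasticity without reward-prediction error", {
  # zero rewards, zero critic weights -> RPE unit silent -> delta = 0
  cfg <- agent_config_frozenlake(critic_init = 0, w_init_jitter = 0,
                                 sigma_explore = 0)
  ag <- build_agent(cfg, seed = 9)
  w_before <- ag$W0$w
  for (k in 1:300) agent_step(ag, (k %/% 10) %% 16, 0)
  expect_equal(max(abs(ag$W0$w - w_before)), 0)
})
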