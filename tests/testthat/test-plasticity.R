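# Continuous-time TD machinery: value oracle, RPE, three-factor rule

test_that("discounted value oracle: closed forms and quadrature", {
  tau_r <- 50
  expect_equal(discounted_value(rep(0, 100), tau_r), rep(0, 100))
  # constant reward c -> V = c * tau_r (piecewise-constant integration
  # is exact for constant rewards, up to end-of-trajectory truncation)
  V <- discounted_value(rep(2, 5000), tau_r, dt = 1)
  expect_equal(V[1], 2 * tau_r * (1 - exp(-5000 / tau_r)), tolerance = 1e-9)
  expect_equal(V[1], 2 * tau_r, tolerance = 1e-6)
  # exponentially decaying reward r(t) = e^(-t/a): compare against
  # adaptive-quadrature oracle of the defining integral
  a <- 30; dt <- 0.01
  tgrid <- seq(0, 400, by = dt)
  r <- exp(-tgrid / a)
  V <- discounted_value(r, tau_r, dt = dt)
  oracle <- integrate(function(u) exp(-u / a) * exp(-u / tau_r),
                      0, 400, rel.tol = 1e-10)$value
  expect_equal(V[1], oracle, tolerance = 1e-3)
  expect_error(discounted_value(numeric(0), tau_r), "empty")
})

test_that("TD objective is the half squared prediction error", {
  expect_equal(td_objective(1, 1), 0)
  expect_equal(td_objective(2, 0), 2)
  set.seed(2)
  for (k in 1:20) {
    v <- rnorm(1); z <- rnorm(1)
    expect_gte(td_objective(v, z), 0)
    expect_equal(td_objective(v, z), 0.5 * (v - z)^2)
  }
})

test_that("reward-prediction error: self-consistency and exactness on ramps", {
  p <- td_params(eta = 0.1, tau_r = 50, d = 5)
  v0 <- 1.3
  # constant value at its self-consistent level: delta = 0
  expect_equal(reward_prediction_error(v0, v0, v0 / p$tau_r, p), 0)
  # zero value: delta = r
  expect_equal(reward_prediction_error(0, 0, 0.7, p), 0.7)
  # linear ramp v(t) = a t: the finite difference is algebraically exact,
  # delta = a + r - a t / tau_r
  a <- 0.02; r <- 0.5
  for (t in c(10, 20, 100)) {
    v_now <- a * t; v_del <- a * (t - p$d)
    expect_equal(reward_prediction_error(v_now, v_del, r, p),
                 a + r - a * t / p$tau_r, tolerance = 1e-12)
  }
  expect_error(td_params(d = 0), "d > 0")
})

test_that("finite-difference RPE converges to the exact TD signal as d -> dt", {
  # smooth analytic value v(t) = sin(t / 30): delta should approach
  # v'(t) + r - v(t)/tau_r
  tau_r <- 80; r <- 0.2; dt <- 1
  p <- td_params(tau_r = tau_r, d = dt)
  for (t in c(15, 40, 90)) {
    v <- function(u) sin(u / 30)
    exact <- cos(t / 30) / 30 + r - v(t) / tau_r
    approx <- reward_prediction_error(v(t), v(t - dt), r, p)
    expect_lt(abs(approx - exact) / abs(exact), 1e-2)
  }
})

test_that("three-factor update: gating, zero-delta no-op, weight floor", {
  p <- td_params(eta = 0.5, tau_r = 50, d = 10, theta_post = 0.1)
  # postsynaptic gate closed (z <= theta_post): exact no-op
  expect_equal(update_weight(0.3, x_pre = 1, z_post = 0.1, delta = 1, p), 0.3)
  expect_equal(update_weight(0.3, x_pre = 1, z_post = 0.05, delta = 1, p), 0.3)
  # zero RPE: exact no-op
  expect_equal(update_weight(0.3, x_pre = 1, z_post = 1, delta = 0, p), 0.3)
  # open gate: Hebbian step eta * delta * x_pre
  expect_equal(update_weight(0.3, 0.5, 1, -0.2, p), 0.3 - 0.5 * 0.2 * 0.5)
  # an update that would cross the floor lands exactly on w_min
  expect_equal(update_weight(0.05, 1, 1, -10, p, w_min = 0.01), 0.01)
  # vectorised over synapses
  w <- c(0.2, 0.2, 0.2)
  out <- update_weight(w, x_pre = c(1, 0, 1), z_post = c(1, 1, 0),
                       delta = 0.1, p, w_min = 0)
  expect_equal(out, c(0.2 + 0.05, 0.2, 0.2))
})

test_that("delayed traces return activities recorded delta_t earlier", {
  st <- network_state(c(0, 0), dt = 1, max_delay = 6)
  p <- rate_params(2, tau = 2, activation = "linear")
  ramp <- numeric(0)
  for (k in 1:10) {
    step_network(st, p, ext = c(k / 10, -k / 10))
    ramp <- rbind(ramp, st$z)
  }
  # delta_t = 0 is the identity
  tr <- delayed_traces(st, 1, 2, delta_t = 0)
  expect_equal(tr$x_pre, st$z[1])
  expect_equal(tr$z_post, st$z[2])
  # delta_t = k dt reaches k rows back
  for (k in 1:5) {
    tr <- delayed_traces(st, 1, 2, delta_t = k)
    expect_equal(tr$x_pre, ramp[10 - k, 1])
    expect_equal(tr$z_post, ramp[10 - k, 2])
  }
  expect_error(delayed_traces(st, 1, 2, delta_t = 7), "history depth")
  expect_error(delayed_traces(st, 1, 2, delta_t = 0.5), "multiple")
})

test_that("iterated critic updates drive the value to r * tau_r on a
          frozen one-state task", {
  # single state (x = 1), constant reward rate; v = w tracks the critic
  # drive directly.  The self-consistent value is v* = r * tau_r.
  p <- td_params(eta = 0.05, tau_r = 50, d = 10, theta_post = -1e6)
  r <- 0.01
  v_star <- r * p$tau_r
  gaps <- sapply(1:10, function(rep) {
    set.seed(rep)
    w <- runif(1, -0.2, 0.2)
    gap <- abs(w - v_star)
    for (k in 1:8000) {
      delta <- reward_prediction_error(w, w, r, p) +
        rnorm(1, 0, 1e-3)  # small disturbance, averaged out
      w <- update_weight(w, 1, 1, delta, p)
    }
    c(gap, abs(w - v_star))
  })
  # expected gap shrinks strongly over the run, averaged over repetitions
  expect_lt(mean(gaps[2, ]), 0.1 * mean(gaps[1, ]))
})
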