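# Unit dynamics: exponential-Euler integration of noisy rate neurons

test_that("heaviside is strict at the origin", {
  expect_equal(heaviside(1.0), 1)
  expect_equal(heaviside(-1.0), 0)
  expect_equal(heaviside(0.0), 0)
  expect_equal(heaviside(c(-2, 0, 1e-300)), c(0, 0, 1))
  expect_error(heaviside(NaN), "non-finite")
  expect_error(heaviside(Inf), "non-finite")
})

test_that("activation kinds: identity and rectification", {
  expect_equal(activation(-2, "threshold_linear"), 0)
  expect_equal(activation(3, "threshold_linear"), 3)
  expect_equal(activation(-2, "linear"), -2)
  expect_equal(activation(0, "threshold_linear"), 0)
  expect_error(activation(1, "sigmoid"))
  expect_error(rate_params(2, activation = "sigmoid"), "unknown activation")
})

test_that("input_field matches a brute-force double-loop sum", {
  set.seed(7)
  w <- matrix(rnorm(16), 4, 4)
  z <- rnorm(4)
  st <- network_state(z, dt = 1)
  h <- input_field(weight_matrix(w), st)
  oracle <- sapply(1:4, function(i) sum(w[i, ] * z))
  expect_equal(h, oracle, tolerance = 1e-12)
  # degenerate cases
  expect_equal(input_field(weight_matrix(w), network_state(rep(0, 4))),
               rep(0, 4))
  expect_equal(input_field(weight_matrix(diag(4)), st), z)
  expect_error(input_field(weight_matrix(matrix(1, 2, 3)), st), "sources")
})

test_that("delayed input field returns activity recorded delay/dt steps ago", {
  st <- network_state(0, dt = 1, max_delay = 5)
  p <- rate_params(1, tau = 3, activation = "linear")
  zs <- numeric(12)
  for (k in 1:12) {
    step_network(st, p, ext = 1)
    zs[k] <- st$z
  }
  for (lag in 0:5) {
    expect_equal(state_lagged(st, lag), zs[12 - lag])
  }
  w_delayed <- weight_matrix(matrix(1, 1, 1), delay = 4)
  expect_equal(input_field(w_delayed, st), zs[8])
  expect_error(state_lagged(st, 6), "history depth")
})

test_that("noise-free linear dynamics follow the analytic ODE solution", {
  # free decay from z(0) = 1: z(t) = exp(-t / tau)
  tau <- 10
  st <- network_state(1, dt = 1)
  p <- rate_params(1, tau = tau, activation = "linear")
  for (k in 1:50) step_network(st, p)
  expect_equal(st$z, exp(-50 / tau), tolerance = 1e-10)
  # constant external drive c: z(t) = c (1 - exp(-t/tau)), fixed point c
  cdrive <- 2.5
  st <- network_state(0, dt = 1)
  for (k in 1:30) step_network(st, p, ext = cdrive)
  expect_equal(st$z, cdrive * (1 - exp(-30 / tau)), tolerance = 1e-8)
  for (k in 1:1000) step_network(st, p, ext = cdrive)
  expect_equal(st$z, cdrive, tolerance = 1e-9)
})

test_that("exponential Euler agrees with a 100x finer forward-Euler oracle", {
  set.seed(11)
  n <- 10
  w <- matrix(rnorm(n * n, sd = 0.2 / sqrt(n)), n, n)
  z0 <- rnorm(n)
  tau <- 10; theta <- 0.1
  p <- rate_params(n, tau = tau, theta = theta,
                   activation = "threshold_linear")
  st <- network_state(z0, dt = 0.1)
  wm <- weight_matrix(w)
  for (k in 1:1000) step_network(st, p, wm)
  # forward-Euler oracle at dt/100, plain R
  dt_f <- 0.001
  z <- z0
  for (k in seq_len(100 / dt_f)) {
    h <- drop(w %*% z)
    f <- pmax(0, h - theta)
    z <- z + dt_f / tau * (-z + f)
  }
  expect_lt(max(abs(st$z - z)) / max(abs(z)), 1e-3)
})

test_that("noise statistics are dt-invariant (OU stationary variance)", {
  sigma <- 2
  sd_at_dt <- function(dt, seed, n = 150000) {
    set.seed(seed)
    st <- network_state(0, dt = dt)
    p <- rate_params(1, tau = 10, sigma_xi = sigma, activation = "linear")
    zs <- numeric(n)
    for (k in 1:n) {
      step_network(st, p)
      zs[k] <- st$z
    }
    sd(zs[-(1:1000)])
  }
  s1 <- sd_at_dt(1, seed = 5)
  s2 <- sd_at_dt(0.5, seed = 6)
  # OU closed form for the matched-increment convention: sd = sigma/sqrt(2)
  expect_lt(abs(s1 - sigma / sqrt(2)) / (sigma / sqrt(2)), 0.05)
  expect_lt(abs(s1 - s2) / s1, 0.05)
})

test_that("plastic weights below the floor are rejected at construction", {
  expect_error(weight_matrix(matrix(-1, 2, 2), plastic = TRUE, w_min = 0),
               "w_min")
  wm <- weight_matrix(matrix(-1, 2, 2), plastic = FALSE, w_min = 0)
  expect_true(all(wm$w == -1))
})

test_that("history buffer rejects delays beyond its configured depth", {
  st <- network_state(c(0, 0), dt = 1, max_delay = 2)
  wm <- weight_matrix(matrix(0.5, 2, 2), delay = 5)
  expect_error(input_field(wm, st), "history depth")
  expect_error(network_state(0, dt = 1, max_delay = 1.5), "multiple")
})
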