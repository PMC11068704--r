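test_that("model specifications are well-formed and unknown names fail", {
  for (name in c("morris_lecar", "fhn", "fhn3d", "wang")) {
    m <- neuron_model(name)
    expect_gt(m$dt, 0)
    expect_lt(m$current_interval[1], m$current_interval[2])
    expect_true(all(m$noisy_params %in% names(m$params)))
    expect_false(anyDuplicated(m$state_names) > 0)
    expect_gt(m$training_duration, 0)
  }
  expect_error(neuron_model("hodgkin1952"), "valid names")
  expect_equal(neuron_model("morris_lecar")$state_names, c("v", "w"))
  expect_equal(neuron_model("wang")$state_names, c("v", "h", "n"))
  expect_equal(neuron_model("wang")$current_interval, c(-3, 3))
})

test_that("right-hand side is a pure function and rejects bad input", {
  m <- neuron_model("morris_lecar")
  s <- c(-30, 0.2)
  expect_identical(model_rhs(m, s, 45), model_rhs(m, s, 45))
  expect_error(model_rhs(m, c(NA, 0.2), 45), "finite")
  expect_error(model_rhs(m, c(-30, 0.2, 0.1), 45), "entries")
})

test_that("FitzHugh-Nagumo derivative vanishes at a numerically located equilibrium", {
  m <- neuron_model("fhn")
  p <- as.list(m$params)
  i_app <- 0.04  # quiescent regime
  # oracle: on the w-nullcline w = v/gamma, the v-nullcline residual is
  # scalar in v; root-find it, then check the full vector field
  res <- function(v) v * (v - p$a) * (1 - v) - v / p$gamma + i_app
  v_eq <- stats::uniroot(res, c(-0.5, 0.4), tol = 1e-14)$root
  eq <- c(v_eq, v_eq / p$gamma)
  expect_lt(max(abs(model_rhs(m, eq, i_app))), 1e-10)
})

test_that("explicit Euler reproduces the closed-form recurrence for linear systems", {
  # dv/dt = -v, v0 = 1, dt = 0.1: one step gives 0.9, m steps (1 - dt)^m
  path <- euler_path(function(x, i) -x, 1, numeric(50), dt = 0.1)
  expect_equal(path[2, 1], 0.9)
  expect_equal(path[, 1], 0.9^(0:49), tolerance = 1e-14)
  # zero right-hand side: constant trajectory
  path0 <- euler_path(function(x, i) c(0, 0), c(2, -1), numeric(10), dt = 0.5)
  expect_true(all(path0[, 1] == 2 & path0[, 2] == -1))
})

test_that("compiled integrators agree with the R right-hand side for one step", {
  probes <- list(morris_lecar = c(-25, 0.15), fhn = c(0.4, 0.1),
                 fhn3d = c(0.4, 0.1, 0.15), wang = c(-50, 0.5, 0.2))
  currents <- c(morris_lecar = 45, fhn = 0.08, fhn3d = 0.06, wang = 1)
  for (name in names(probes)) {
    m <- neuron_model(name)
    x0 <- probes[[name]]
    tr <- integrate_neuron(m, rep(currents[[name]], 2), x0 = x0)
    manual <- x0 + m$dt * model_rhs(m, x0, currents[[name]])
    expect_equal(unname(tr$states[2, ]), unname(manual), tolerance = 1e-13)
  }
})

test_that("Euler spiking period matches an adaptive reference integration within 2%", {
  m <- neuron_model("fhn")
  i_const <- 0.08
  x0 <- resting_state(m, m$current_interval[1])
  n <- round(3000 / m$dt)
  tr <- integrate_neuron(m, rep(i_const, n), x0 = x0)
  sp_e <- detect_spikes(tr$states[round(n / 3):n, 1], m$dt)
  p <- as.list(m$params)
  rhs_ode <- function(t, y, parms) {
    list(c(y[1] * (y[1] - p$a) * (1 - y[1]) - y[2] + i_const,
           p$eps * (y[1] - p$gamma * y[2])))
  }
  ref <- deSolve::lsoda(x0, seq(0, 3000, by = m$dt), rhs_ode, NULL,
                        rtol = 1e-10, atol = 1e-12)
  sp_r <- detect_spikes(ref[round(n / 3):n, 2], m$dt)
  per_e <- mean(interspike_intervals(sp_e))
  per_r <- mean(interspike_intervals(sp_r))
  expect_gt(length(sp_e), 5)
  expect_lt(abs(per_e - per_r) / per_r, 0.02)
})

test_that("constant currents below the physiological interval are quiescent, mid-interval currents spike", {
  below <- c(morris_lecar = 10, fhn = 0.03, fhn3d = 0.02, wang = -2)
  inside <- c(morris_lecar = 50, fhn = 0.08, fhn3d = 0.06, wang = 1.5)
  dur <- c(morris_lecar = 3000, fhn = 2000, fhn3d = 5000, wang = 800)
  for (name in names(below)) {
    m <- neuron_model(name)
    x0 <- resting_state(m, m$current_interval[1])
    n <- round(dur[[name]] / m$dt)
    skipn <- round(n / 3)
    trq <- integrate_neuron(m, rep(below[[name]], n), x0 = x0)
    vq <- trq$states[skipn:n, 1]
    # quiescent: no large-amplitude threshold crossings
    expect_lt(diff(range(vq)), if (name %in% c("morris_lecar", "wang")) 20 else 0.4)
    trs <- integrate_neuron(m, rep(inside[[name]], n), x0 = x0)
    sp <- detect_spikes(trs$states[skipn:n, 1], m$dt)
    isis <- interspike_intervals(sp)
    expect_gte(length(sp), 2)
    # sustained regular spiking: stable interspike intervals
    expect_lt(stats::sd(isis) / mean(isis), 0.2)
  }
})

test_that("parameter noise is reproducible, bounded and vanishes at xi_bar = 0", {
  m <- neuron_model("morris_lecar")
  i_app <- rep(45, 2000)
  x0 <- resting_state(m, 20)
  clean <- integrate_neuron(m, i_app, x0 = x0)
  noisy0 <- integrate_neuron(perturb_parameters(m, 0), i_app, x0 = x0,
                             seed = 5)
  expect_identical(clean$states, noisy0$states)
  n1 <- integrate_neuron(perturb_parameters(m, 0.01), i_app, x0 = x0,
                         seed = 5)
  n2 <- integrate_neuron(perturb_parameters(m, 0.01), i_app, x0 = x0,
                         seed = 5)
  expect_identical(n1$states, n2$states)
  n3 <- integrate_neuron(perturb_parameters(m, 0.01), i_app, x0 = x0,
                         seed = 6)
  expect_false(identical(n1$states, n3$states))
  expect_error(perturb_parameters(m, -0.1), "non-negative")
})

test_that("realized parameter perturbations are uniform within the stated 1% bound", {
  # recover the per-step multiplicative factors on a and gamma from
  # single Euler steps of the FitzHugh-Nagumo model at a known state
  m <- perturb_parameters(neuron_model("fhn"), 0.01)
  p <- as.list(m$params)
  v0 <- 0.4; w0 <- 0.1; i0 <- 0.08
  set.seed(99)
  n_rep <- 2000
  xi_a <- numeric(n_rep); xi_g <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tr <- integrate_neuron(m, rep(i0, 2), x0 = c(v0, w0))
    dv <- (tr$states[2, 1] - v0) / m$dt
    dw <- (tr$states[2, 2] - w0) / m$dt
    a_real <- v0 - (dv + w0 - i0) / (v0 * (1 - v0))
    g_real <- (v0 - dw / p$eps) / w0
    xi_a[r] <- a_real / p$a - 1
    xi_g[r] <- g_real / p$gamma - 1
  }
  expect_true(all(abs(xi_a) <= 0.01 + 1e-9))
  expect_true(all(abs(xi_g) <= 0.01 + 1e-9))
  expect_gt(stats::ks.test(xi_a, "punif", -0.01, 0.01)$p.value, 0.01)
  expect_gt(stats::ks.test(xi_g, "punif", -0.01, 0.01)$p.value, 0.01)
})

test_that("divergent integrations abort with the step index", {
  m <- neuron_model("fhn")
  err <- tryCatch(integrate_neuron(m, rep(1e5, 100), x0 = c(0, 0)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "diverged")
  expect_match(err, "at step")
})
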