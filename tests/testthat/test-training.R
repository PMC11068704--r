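make_toy_traj <- function(n = 400, n_state = 2, seed = 3) {
  set.seed(seed)
  states <- matrix(cumsum(rnorm(n * n_state, sd = 0.1)), n, n_state)
  colnames(states) <- c("v", "w", "y")[seq_len(n_state)]
  structure(list(t = (seq_len(n) - 1) * 0.05, states = states,
                 i_app = runif(n), dt = 0.05, model_name = "toy",
                 xi_bar = 0, seed = seed),
            class = "trajectory")
}

test_that("one-step datasets have the contracted layout in both paradigms", {
  tr <- make_toy_traj(100)
  d1 <- build_dataset(tr, "full_state")
  expect_equal(ncol(d1$X), 3)           # v, w, i_app
  expect_equal(ncol(d1$Y), 2)
  expect_equal(nrow(d1$X), 99)
  # row m pairs (state, current) at m with the state at m+1
  expect_equal(unname(d1$X[10, ]), unname(c(tr$states[10, ], tr$i_app[10])))
  expect_equal(unname(d1$Y[10, ]), unname(tr$states[11, ]))

  d2 <- build_dataset(tr, "voltage", n_lags = 4)
  expect_equal(ncol(d2$X), 5)           # 4 voltage lags + current
  expect_equal(ncol(d2$Y), 1)
  expect_equal(nrow(d2$X), 96)
  expect_equal(unname(d2$X[1, ]),
               c(tr$states[4:1, 1], tr$i_app[4]))
  expect_equal(unname(d2$Y[1, 1]), unname(tr$states[5, 1]))
  expect_error(build_dataset(tr, "voltage", n_lags = 0), "n_lags")

  tiny <- make_toy_traj(2)
  expect_equal(nrow(build_dataset(tiny, "full_state")$X), 1)
})

test_that("planted weights are recovered exactly on a well-conditioned frame", {
  set.seed(12)
  f <- wavelet_frame(1, 2, 0, "quadratic", identity_inputs = 1,
                     bounds = rbind(0, 1))   # J = 3, independent columns
  X <- matrix(runif(200), ncol = 1)
  G <- design_matrix(f, X)
  sigma_star <- c(0.5, -1.2, 2)
  Y <- matrix(G %*% sigma_star, ncol = 1)
  fit <- fit_wavenet(f, list(X = X, Y = Y), mu = 0)
  expect_equal(unname(fit$weights[, 1]), sigma_star, tolerance = 1e-8)
  expect_lt(max(abs(predict(fit, list(X = X)) - Y)), 1e-8)
  expect_lt(fit$train_mse[[1]], 1e-16)
})

test_that("the chunked regularized solve matches a dense oracle on random instances", {
  set.seed(13)
  f <- wavelet_frame(2, 3, 1, "quadratic", identity_inputs = 1:2,
                     bounds = rbind(c(0, 0), c(1, 1)))  # J = 38
  for (rep in 1:3) {
    X <- matrix(runif(400), 200, 2)
    Y <- cbind(runif(200), rnorm(200))
    fit <- fit_wavenet(f, list(X = X, Y = Y), mu = 2e-16, chunk_rows = 37)
    # independent dense route: full design matrix + base solve()
    G <- design_matrix(f, X)
    A <- crossprod(G)
    gamma <- 2e-16 * max(eigen(A, symmetric = TRUE,
                               only.values = TRUE)$values)
    sigma_ref <- solve(A + diag(gamma, ncol(G)), crossprod(G, Y))
    expect_lt(max(abs(fit$weights - sigma_ref)) / max(abs(sigma_ref)), 1e-8)
  }
})

test_that("fitted weights are invariant to the accumulation chunk size", {
  set.seed(14)
  f <- wavelet_frame(2, 3, 1, "bicubic", identity_inputs = 1,
                     bounds = rbind(c(0, 0), c(1, 1)))
  X <- matrix(runif(600), 300, 2)
  Y <- matrix(sin(4 * X[, 1]) + X[, 2], ncol = 1)
  fits <- lapply(c(7, 64, 300), function(cr)
    fit_wavenet(f, list(X = X, Y = Y), chunk_rows = cr))
  ref <- fits[[3]]$weights
  for (fit in fits[1:2])
    expect_lt(max(abs(fit$weights - ref)) / max(abs(ref)), 1e-12)
})

test_that("training error is monotone in the regularizer and weights shrink to zero", {
  set.seed(15)
  f <- wavelet_frame(1, 3, 1, "quadratic", identity_inputs = 1,
                     bounds = rbind(0, 1))
  X <- matrix(runif(250), ncol = 1)
  Y <- matrix(cos(6 * X[, 1]), ncol = 1)
  mus <- c(1e-12, 1e-6, 1e-2, 1, 100)
  mses <- vapply(mus, function(m)
    fit_wavenet(f, list(X = X, Y = Y), mu = m)$train_mse[[1]], numeric(1))
  expect_true(all(diff(mses) >= -1e-12))
  big <- fit_wavenet(f, list(X = X, Y = Y), mu = 1e9)
  expect_lt(max(abs(big$weights)), 1e-6)
})

test_that("the joint multioutput fit equals separate per-output fits", {
  set.seed(16)
  f <- wavelet_frame(2, 2, 1, "quadratic", identity_inputs = 1:2,
                     bounds = rbind(c(0, 0), c(1, 1)))
  X <- matrix(runif(300), 150, 2)
  Y <- cbind(a = X[, 1]^2, b = cos(3 * X[, 2]))
  joint <- fit_wavenet(f, list(X = X, Y = Y))
  for (j in 1:2) {
    single <- fit_wavenet(f, list(X = X, Y = Y[, j, drop = FALSE]))
    expect_equal(unname(joint$weights[, j]), unname(single$weights[, 1]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate fits fail with actionable errors", {
  f <- wavelet_frame(1, 3, 1, "quadratic", identity_inputs = 1,
                     bounds = rbind(0, 1))
  X <- matrix(rep(0.5, 50), ncol = 1)   # rank-deficient design
  Y <- matrix(rnorm(50), ncol = 1)
  expect_error(fit_wavenet(f, list(X = X, Y = Y), mu = 0), "mu > 0")
  expect_error(fit_wavenet(f, list(X = matrix(c(NA, 1), 2, 1),
                                   Y = matrix(1:2, 2, 1))), "finite")
})
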