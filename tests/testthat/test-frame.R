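test_that("scaling functions match their piecewise form and vanish at support edges", {
  fam <- scaling_family("quadratic")
  expect_equal(eval_scaling(fam, 0), 0)
  expect_equal(eval_scaling(fam, 1), 0)
  # middle piece at unrescaled argument 1.5 (x = 0.5 on the unit interval)
  expect_equal(eval_scaling(fam, 0.5), 0.75)
  # partition of unity on the unrescaled integer lattice
  expect_equal(eval_scaling(fam, 0.5 / 3) + eval_scaling(fam, 1.5 / 3) +
                 eval_scaling(fam, 2.5 / 3), 1)
  expect_equal(eval_scaling(fam, c(-0.2, 1.4)), c(0, 0))
  bic <- scaling_family("bicubic")
  expect_equal(eval_scaling(bic, 0.5), 2 / 3)  # cubic B-spline peak
  expect_equal(sum(fam$p), 2)
  expect_equal(sum(bic$p), 2)
})

test_that("the two-scale refinement identity holds for both spline families", {
  for (nm in c("quadratic", "bicubic")) {
    fam <- scaling_family(nm)
    u <- seq(-1, fam$d + 1, by = 1e-3)
    lhs <- fam$raw(u)
    rhs <- 0
    for (n in seq_along(fam$p) - 1)
      rhs <- rhs + fam$p[n + 1] * fam$raw(2 * u - n)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("displaced scaling functions sit at the prescribed centers", {
  x <- seq(0, 1, by = 1e-4)
  for (nm in c("quadratic", "bicubic")) {
    for (ns in c(3, 5)) {
      for (k in 0:(ns - 1)) {
        v <- displaced_scaling(nm, k, ns, x)
        expect_lt(abs(x[which.max(v)] - (1 - k / (ns - 1))), 2e-4)
      }
    }
  }
  # restriction to the unit interval
  expect_equal(displaced_scaling("quadratic", 1, 3, c(-0.5, 1.5)), c(0, 0))
  expect_error(displaced_scaling("quadratic", 3, 3, 0.5), "outside")
  # n_scaling = 1 degenerates to the undisplaced rescaled function
  expect_equal(displaced_scaling("quadratic", 0, 1, 0.4),
               eval_scaling("quadratic", 0.4))
})

test_that("wavelets obey the dilation/translation law and are zero-mean", {
  x <- seq(0, 1, by = 1e-3)
  # r = 0, n = 0 is the mother wavelet itself
  expect_equal(frame_wavelet("quadratic", 1, 0, 0, 3, x),
               mother_wavelet("quadratic", 1, 3, x))
  # r = 1, n = 0 is sqrt(2) * psi(2x)
  expect_equal(frame_wavelet("quadratic", 1, 1, 0, 3, x),
               sqrt(2) * mother_wavelet("quadratic", 1, 3, 2 * x,
                                        restrict = FALSE) *
                 as.numeric(x >= 0 & x <= 1))
  # alternating interscale sum makes the unrestricted mother zero-mean
  for (nm in c("quadratic", "bicubic")) {
    fam <- scaling_family(nm)
    expect_equal(sum((-1)^(seq_along(fam$p) - 1) * fam$p), 0)
    for (k in c(0, 2)) {
      u <- seq(-1, 3, by = 5e-5)
      v <- mother_wavelet(nm, k, 3, u, restrict = FALSE)
      expect_lt(abs(sum(v) * 5e-5), 1e-8)  # quadrature of piecewise poly
    }
  }
  expect_error(frame_wavelet("quadratic", 0, 1, 2, 3, 0.5), "translation")
  expect_error(frame_wavelet("quadratic", 0, -1, 0, 3, 0.5), "resolution")
})

test_that("frame enumeration reproduces the printed level structure", {
  # smallest case: identity + scaling + mother wavelet
  f <- wavelet_frame(1, 1, 1, "quadratic", identity_inputs = 1)
  expect_equal(frame_size(f), 3)
  expect_equal(nrow(frame_wavelons(f)), 3)
  # three inputs, three superpositions
  f3 <- wavelet_frame(3, 3, 2, "quadratic")
  expect_equal(frame_level_size(f3, "scaling"), 27)
  expect_equal(frame_level_size(f3, 0), 189)
  expect_equal(frame_level_size(f3, 1), 702)
  w <- frame_wavelons(f3)
  expect_equal(sum(w$level == "scaling"), 27)
  expect_equal(sum(w$level == "0"), 189)
  expect_equal(sum(w$level == "1"), 702)
  expect_false(anyDuplicated(w$label) > 0)
})

test_that("enumeration length equals the closed-form count for randomized specs", {
  set.seed(4)
  for (i in 1:12) {
    ni <- sample(1:4, 1); ns <- sample(1:5, 1); nr <- sample(0:2, 1)
    nid <- sample(0:ni, 1)
    f <- wavelet_frame(ni, ns, nr, sample(c("quadratic", "bicubic"), 1),
                       identity_inputs = if (nid) seq_len(nid) else integer())
    expect_equal(nrow(frame_wavelons(f)), frame_size(f))
  }
})

test_that("design matrices have the contracted shape and identity columns", {
  set.seed(8)
  X <- matrix(runif(60, 1, 3), 20, 3)
  f <- wavelet_frame(3, 3, 1, "bicubic", identity_inputs = c(1, 3),
                     bounds = rbind(rep(1, 3), rep(3, 3)))
  G <- design_matrix(f, X)
  expect_equal(dim(G), c(20L, frame_size(f)))
  expect_equal(G[, 1], (X[, 1] - 1) / 2)
  expect_equal(G[, 2], (X[, 3] - 1) / 2)
  expect_error(design_matrix(f, X[, 1:2]), "columns")
})

test_that("chunked design-matrix construction is identical to monolithic", {
  set.seed(9)
  X <- matrix(runif(303), 101, 3)
  f <- wavelet_frame(3, 4, 1, "quadratic", identity_inputs = 1:2,
                     bounds = rbind(rep(0, 3), rep(1, 3)))
  G_full <- design_matrix(f, X)
  starts <- seq(1, nrow(X), by = 17)
  G_chunked <- do.call(rbind, lapply(starts, function(s) {
    rows <- s:min(s + 16, nrow(X))
    design_matrix(f, X[rows, , drop = FALSE])
  }))
  expect_identical(G_full, G_chunked)
})

test_that("all product activations vanish outside the unit box under the support restriction", {
  f <- wavelet_frame(2, 3, 1, "quadratic", identity_inputs = 1,
                     bounds = rbind(c(0, 0), c(1, 1)))
  X_out <- rbind(c(1.5, 0.5), c(0.5, -0.2), c(2, 2))
  G <- suppressWarnings(design_matrix(f, X_out, oob = "zero"))
  expect_true(all(G[, -1] == 0))      # every tensor-product column
  expect_equal(G[, 1], X_out[, 1])    # identity stays linear
  expect_warning(design_matrix(f, X_out, oob = "zero"), "outside")
})

test_that("superposed scaling functions reproduce constants away from the edges", {
  # with N_S = d + 1 the displaced copies are integer translates of the
  # B-spline, so they partition unity on the interior
  x <- seq(0.26, 0.74, by = 1e-3)
  for (cfg in list(list(nm = "quadratic", ns = 4, lo = 0.2, hi = 0.8),
                   list(nm = "bicubic", ns = 5, lo = 0.26, hi = 0.74))) {
    xs <- seq(cfg$lo, cfg$hi, by = 1e-3)
    tot <- 0
    for (k in 0:(cfg$ns - 1))
      tot <- tot + displaced_scaling(cfg$nm, k, cfg$ns, xs)
    expect_lt(max(abs(tot - 1)), 1e-12)
  }
})
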