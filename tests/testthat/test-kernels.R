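test_that("sweep retention is 1 at the selected site and decays monotonically", {
  expect_equal(sweep_retention(0, s = 0.05, Ne = 1e4), 1)

  # algebraic inversion: y = 0.5 where (r/s) ln(4 Ne s) = ln 2
  s <- 0.05; Ne <- 1e4
  r_half <- s * log(2) / log(4 * Ne * s)
  expect_equal(sweep_retention(r_half, s, Ne), 0.5)

  # direct evaluation, frozen from 30-digit arithmetic
  expect_equal(sweep_retention(1e-4, 0.05, 1e4), 0.9849131592259058,
               tolerance = 1e-12)

  r <- 10^seq(-6, -2, length.out = 30)
  expect_true(all(diff(sweep_retention(r, s, Ne)) < 0))

  expect_error(sweep_retention(1e-4, s = 1e-6, Ne = 1e4), "4\\*Ne\\*s")
})

test_that("standing-phase coalescence obeys its limits", {
  expect_equal(standing_phase_coalescence(0.001, g = 0.01, t = 0, Ne = 1e4), 0)
  expect_equal(standing_phase_coalescence(0, g = 0.01, t = 1e12, Ne = 1e4), 1)
  # unbounded time at r > 0: competing exponentials
  kappa <- 1 / (2 * 1e4 * 0.01)
  r <- 2e-3
  expect_equal(standing_phase_coalescence(r, 0.01, 1e12, 1e4),
               kappa / (kappa + 2 * r))
})

test_that("independent kernel inflates only selected diagonals", {
  F0 <- test_coancestry(6)
  sel <- c(1, 3, 5)

  expect_equal(kernel_independent(F0, y = 0, sel), F0)

  F1 <- F0; F1[1, 1] <- 0.1
  expect_equal(kernel_independent(F1, y = 1, sel)[1, 1], 1)

  F2 <- F0; F2[3, 3] <- 0.2
  expect_equal(kernel_independent(F2, y = 0.5, sel)[3, 3], 0.25 + 0.75 * 0.2)

  Fp <- kernel_independent(F0, y = 0.7, sel)
  off_mask <- row(F0) != col(F0)
  expect_equal(Fp[off_mask], F0[off_mask])
  expect_equal(diag(Fp)[c(2, 4, 6)], diag(F0)[c(2, 4, 6)])
})

test_that("standing kernel matches its stated limits", {
  F0 <- test_coancestry(6)
  sel <- c(1, 3, 5)

  expect_equal(kernel_standing(F0, y = 0, p_coal = 0.5, p_shared = 0.5, sel), F0)

  Fp <- kernel_standing(F0, y = 1, p_coal = 1, p_shared = 0.3, sel)
  expect_equal(diag(Fp)[sel], rep(1, 3))

  # g -> 0 (kappa -> infinity): p_shared -> 1, selected off-diagonals take
  # the independent-mode diagonal form y^2 + (1 - y^2) F
  y <- 0.6
  Fp <- kernel_standing(F0, y = y, p_coal = 1, p_shared = 1, sel)
  expect_equal(Fp[1, 3], y^2 + (1 - y^2) * F0[1, 3])

  # source population's diagonal takes the independent-sweep form
  Fp <- kernel_standing(F0, y = y, p_coal = 0.4, p_shared = 0.2, sel,
                        source = 3)
  expect_equal(Fp[3, 3], y^2 + (1 - y^2) * F0[3, 3])
  expect_equal(Fp[1, 1],
               y^2 * (0.4 + 0.6 * F0[1, 1]) + (1 - y^2) * F0[1, 1])
})

test_that("standing within-population coalescence never drops below the shared probability", {
  # diag >= selected off-diag keeps the model covariance PSD-consistent,
  # including at t = 0 where both coalescence probabilities coincide
  # (requires a coancestry whose diagonal dominates its rows, as drift
  # coancestries do)
  F0 <- test_coancestry(6)
  diag(F0) <- diag(F0) + 0.02
  sel <- c(1, 3, 5)
  for (t in c(0, 5, 100, 1e4)) {
    for (r in c(0, 1e-4, 1e-3)) {
      Fp <- convmode:::single_mode_cov(F0, r, "standing",
                                       full_params(t = t, g = 0.001),
                                       sel, Ne = 1e4)
      for (i in sel) for (j in setdiff(sel, i)) {
        expect_gte(Fp[i, i] - Fp[i, j], -1e-12)
      }
      # the operative likelihood matrix (with sampling noise) stays PSD
      ev <- eigen(Fp + diag(1 / 10, 6), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})

test_that("migration kernel creates source-recipient coancestry that grows with m", {
  F0 <- test_coancestry(6)
  sel <- c(1, 3, 5)

  expect_equal(kernel_migration(F0, y = 0, q = 0, sel, source = 1), F0)

  # r = 0: q = y = 1, recipient and source share the haplotype fully
  Fp <- kernel_migration(F0, y = 1, q = 1, sel, source = 1)
  expect_equal(Fp[3, 1], 1)
  expect_equal(Fp[3, 5], 1)  # recipient-recipient

  # larger m (shorter migration delay) strictly increases recipient-source
  # coancestry at fixed r > 0
  r <- 5e-4; s <- 0.05; Ne <- 1e4
  y <- sweep_retention(r, s, Ne)
  vals <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 1), function(m) {
    convmode:::single_mode_cov(F0, r, "migration",
                               full_params(s = s, m = m, source = 1),
                               sel, Ne)[3, 1]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(
    convmode:::single_mode_cov(F0, r, "migration",
                               full_params(m = 0), sel, Ne),
    "must be > 0"
  )
})

test_that("all kernels return to neutrality at large distance, stay symmetric and bounded", {
  F0 <- test_coancestry(6)
  sel <- c(1, 3, 5)
  Ne <- 1e4
  modes <- c("independent", "standing", "standing_source", "migration")
  params <- full_params(s = 0.05, m = 0.01, t = 100, g = 0.01, source = 3)
  r_far <- 1  # y < 1e-12 here by a wide margin
  r_grid <- c(0, 10^seq(-6, -1, length.out = 12))

  for (mode in modes) {
    expect_lt(
      max(abs(convmode:::single_mode_cov(F0, r_far, mode, params, sel, Ne) - F0)),
      1e-10
    )
    prev_added <- Inf
    for (r in r_grid) {
      Fp <- convmode:::single_mode_cov(F0, r, mode, params, sel, Ne)
      expect_symmetric(Fp, tol = 1e-14)
      expect_true(all(Fp >= min(F0) - 1e-9 & Fp <= 1 + 1e-9))
      # non-selected rows/columns untouched
      nonsel <- setdiff(1:6, sel)
      expect_equal(Fp[nonsel, ], F0[nonsel, ])
      added <- max(diag(Fp)[sel] - diag(F0)[sel])
      expect_lte(added, prev_added + 1e-12)
      prev_added <- added
    }
  }
})

test_that("a single-group mixed kernel reproduces the single-mode kernel bitwise", {
  F0 <- test_coancestry(6)
  sel <- c(1, 3, 5)
  params <- full_params(source = 3)
  for (mode in c("independent", "standing", "standing_source", "migration")) {
    for (r in c(0, 1e-4, 1e-3)) {
      expect_identical(
        kernel_multi(F0, r, params, sets = list(sel), modes = mode, Ne = 1e4),
        convmode:::single_mode_cov(F0, r, mode, params, sel, Ne = 1e4)
      )
    }
  }
})

test_that("mixed-mode groups are modeled as independent convergence events", {
  F0 <- test_coancestry(6)
  params <- full_params(source = 1)
  r <- 1e-4
  Fp <- kernel_multi(F0, r, params, sets = list(c(1, 3), 5),
                     modes = c("standing_source", "independent"), Ne = 1e4)
  Fstd <- convmode:::single_mode_cov(F0, r, "standing_source", params,
                                     c(1, 3), 1e4)
  Find <- convmode:::single_mode_cov(F0, r, "independent", params, 5, 1e4)
  expect_identical(Fp[c(1, 3), c(1, 3)], Fstd[c(1, 3), c(1, 3)])
  expect_identical(Fp[5, 5], Find[5, 5])
  # cross-group entries keep the neutral coancestry
  expect_identical(Fp[1, 5], F0[1, 5])
  expect_identical(Fp[3, 5], F0[3, 5])

  expect_error(
    kernel_multi(F0, r, params, sets = list(c(1, 3), 5),
                 modes = c("teleportation", "independent"), Ne = 1e4),
    "unknown mode"
  )
})
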