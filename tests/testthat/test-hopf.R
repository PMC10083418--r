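test_that("characteristic coefficients follow their closed forms", {
  lin <- base_lin()
  cf <- characteristic_coeffs(lin)   # uncoupled node
  expect_equal(cf$B1, -lin$tr0, tolerance = 1e-12)
  expect_equal(cf$B1, 1.86434, tolerance = 1e-5)
  expect_equal(cf$B2, -0.27133, tolerance = 1e-4)
  expect_equal(cf$B3, 4)            # a*b*c^2
  expect_equal(cf$p, cf$B1^2 - 2 * cf$B2, tolerance = 1e-12)
  expect_equal(cf$q, cf$B2^2 - cf$B3^2, tolerance = 1e-12)

  # zero eigenvalues neutralize arbitrary diffusion
  cf2 <- characteristic_coeffs(lin, diffusion_params(0.3, 7), 0, 0)
  expect_equal(cf2[c("B1", "B2", "B3")], cf[c("B1", "B2", "B3")])

  # diffusion shifts match the printed formulas
  dd <- diffusion_params(du_R = 0.1, du_E = 0.2, dv_R = 0.5, dv_E = 0.7)
  cf3 <- characteristic_coeffs(lin, dd, -2, -3)
  expect_equal(cf3$B1, -lin$tr0 - (0.2 + 0.7) * (-3) - (0.1 + 0.5) * (-2),
               tolerance = 1e-12)
  expect_equal(cf3$B2,
               (0.7 * -3 + 0.5 * -2 + lin$a22) *
                 (0.2 * -3 + 0.1 * -2 + lin$a11), tolerance = 1e-12)

  # |B2| < |B3| if and only if q < 0
  expect_identical(cf$q < 0, abs(cf$B2) < abs(cf$B3))
})

test_that("the Hopf crossing solves the transcendental equation", {
  hp <- solve_hopf(characteristic_coeffs(base_lin()))
  expect_true(hp$exists)
  expect_equal(hp$omega0, 1.5680651, tolerance = 1e-6)
  expect_equal(hp$tau0, 0.5226623, tolerance = 1e-6)
  expect_equal(hp$dRe_dtau, 1.0012409, tolerance = 1e-6)

  # the crossing is a genuine root of the characteristic equation
  lam <- complex(imaginary = hp$omega0)
  expect_lt(characteristic_root_residual(hp$coeffs, lam, hp$tau0), 1e-9)
  # conjugate symmetry of the residual
  expect_equal(characteristic_root_residual(hp$coeffs, Conj(lam), hp$tau0),
               characteristic_root_residual(hp$coeffs, lam, hp$tau0),
               tolerance = 1e-12)
  # simultaneous cosine/sine conditions
  cf <- hp$coeffs
  expect_equal(cf$B3 * cos(hp$omega0 * hp$tau0), hp$omega0^2 - cf$B2,
               tolerance = 1e-9)
  expect_equal(cf$B3 * sin(hp$omega0 * hp$tau0), cf$B1 * hp$omega0,
               tolerance = 1e-9)
  # delay branches are spaced by 2*pi/omega0 and start at the smallest
  expect_equal(diff(hp$tau_list), rep(2 * pi / hp$omega0, 3),
               tolerance = 1e-12)
  expect_gt(hp$tau0, 0)

  # trivial residual identity at the origin
  expect_equal(characteristic_root_residual(cf, 0 + 0i, 0),
               abs(cf$B2 + cf$B3), tolerance = 1e-12)
})

test_that("non-existence cases are reported as values, not errors", {
  # B3 = 0 makes q = B2^2 >= 0
  hp <- solve_hopf(mk_coeffs(B1 = 2, B2 = -1, B3 = 0))
  expect_false(hp$exists)
  expect_match(hp$reason, "q")
  # p <= 0 regime
  hp <- solve_hopf(mk_coeffs(B1 = 0.1, B2 = 3, B3 = 4))
  expect_false(hp$exists)
  expect_match(hp$reason, "p")
})

test_that("the transversality formula matches root continuation", {
  set.seed(2024)
  n_done <- 0
  while (n_done < 100) {
    cf <- rand_crossing_coeffs()
    hp <- solve_hopf(cf)
    if (!hp$exists) next
    expect_lt(characteristic_root_residual(
      cf, complex(imaginary = hp$omega0), hp$tau0), 1e-9)
    fd <- fd_transversality(cf, hp)
    expect_equal(hp$dRe_dtau, fd, tolerance = 1e-4)
    # closed-form complex derivative agrees in its real part
    expect_equal(Re(hp$dlambda_dtau), hp$dRe_dtau, tolerance = 1e-10)
    n_done <- n_done + 1
  }
})

test_that("no characteristic root crosses before tau0", {
  # independent check by direct integration of the linear delayed
  # 2-variable mode: decay below tau0, growth above
  lin <- base_lin()
  hp <- solve_hopf(characteristic_coeffs(lin))
  J0 <- matrix(c(lin$a11, lin$a21, 0, lin$a22), 2, 2)
  J1 <- matrix(c(0, 0, lin$a12, 0), 2, 2)
  lin_dde <- function(tau, t_end = 60, dt = 0.002) {
    n <- ceiling(t_end / dt)
    m <- ceiling(tau / dt)
    X <- matrix(0, 2, n + m + 1)
    X[, seq_len(m + 1)] <- c(1e-3, 1e-3)    # constant history
    for (k in (m + 1):(n + m)) {
      X[, k + 1] <- X[, k] + dt * (J0 %*% X[, k] + J1 %*% X[, k - m])
    }
    sqrt(sum(X[, n + m + 1]^2))
  }
  a0 <- sqrt(2) * 1e-3
  expect_lt(lin_dde(0.5 * hp$tau0), a0)
  expect_lt(lin_dde(0.9 * hp$tau0), a0)
  expect_gt(lin_dde(1.1 * hp$tau0), a0)
})

test_that("per-mode thresholds over a spectrum agree with the scalar solver", {
  lin <- base_lin()
  dd <- diffusion_params(0.01, 8)

  # all-zero spectrum: every mode reproduces the single-node threshold
  R0 <- generate_layer(3, 0, seed = 1)
  hs <- tau0_over_spectrum(lin, dd, product_spectrum(R0, R0))
  single <- solve_hopf(characteristic_coeffs(lin))
  expect_true(all(hs$table$exists))
  expect_equal(hs$table$tau0, rep(single$tau0, 9), tolerance = 1e-12)
  expect_equal(hs$tau0_min, single$tau0)

  # seeded layers: each row recomputable with the scalar solver
  R <- generate_layer(8, 0.3, seed = 21)
  E <- generate_layer(8, 0.3, seed = 22)
  ps <- product_spectrum(R, E)
  hs <- tau0_over_spectrum(lin, dd, ps)
  for (i in seq(1, nrow(hs$table), by = 7)) {
    ref <- solve_hopf(characteristic_coeffs(lin, dd, ps$pairs$lambda_R[i],
                                            ps$pairs$lambda_E[i]))
    expect_equal(hs$table$exists[i], ref$exists)
    if (ref$exists) expect_equal(hs$table$tau0[i], ref$tau0)
  }
  # the global minimum only ranges over modes that admit a crossing
  if (any(!hs$table$exists))
    expect_true(all(is.na(hs$table$tau0[!hs$table$exists])))
  expect_equal(hs$tau0_min, min(hs$table$tau0[hs$table$exists]))
})
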