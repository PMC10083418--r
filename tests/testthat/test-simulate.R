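test_that("the homogeneous equilibrium is a fixed point of the coupled system", {
  m <- base_model()
  # uncoupled node, long horizon
  tr <- fhn_simulate(m, config = sim_config(t_end = 100, save_every = 100))
  expect_lt(max(abs(tr$u - m$equilibria$u_star)), 1e-8)
  expect_lt(max(abs(tr$v - m$equilibria$v_star)), 1e-8)
  # small product network with diffusion: L * constant = 0
  layers <- list(R = generate_layer(5, 0.4, seed = 1),
                 E = generate_layer(4, 0.4, seed = 2))
  tr <- fhn_simulate(m, layers, diffusion_params(0.01, 8),
                     sim_config(t_end = 20, dt = 0.01))
  expect_lt(max(abs(tr$u - m$equilibria$u_star)), 1e-8)
  expect_equal(tr$n_nodes, 20L)
})

test_that("the deterministic integrator agrees with an adaptive reference", {
  skip_if_not_installed("deSolve")
  m <- base_model()
  cfg <- sim_config(t_end = 10, dt = 0.005, init = "perturbed",
                    perturb_amp = 0.5, seed = 4, save_every = 200)
  tr <- fhn_simulate(m, config = cfg)
  rhs <- function(t, y, p) {
    list(c(2 * (y[1] - y[1]^3 / 3 - y[2] + 0.7),
           2 * (y[1] - y[2] + 1)))
  }
  ref <- deSolve::ode(y = c(tr$u[1, 1], tr$v[1, 1]), times = tr$times,
                      func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(as.vector(tr$u), unname(ref[, 2]), tolerance = 1e-6)
  expect_equal(as.vector(tr$v), unname(ref[, 3]), tolerance = 1e-6)
})

test_that("halving the step barely moves the deterministic terminal state", {
  m <- base_model()
  layers <- list(R = generate_layer(4, 0.5, seed = 8),
                 E = generate_layer(4, 0.5, seed = 9))
  run <- function(dt) {
    tr <- fhn_simulate(m, layers, diffusion_params(0.01, 10),
                       sim_config(t_end = 30, dt = dt, init = "perturbed",
                                  seed = 5, save_every = 10000))
    c(tr$u[, ncol(tr$u)], tr$v[, ncol(tr$v)])
  }
  s1 <- run(0.01)
  s2 <- run(0.005)
  expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 1e-4)
})

test_that("delayed and stochastic paths are reproducible and well-formed", {
  m <- base_model()
  cfg <- sim_config(t_end = 20, dt = 0.005, tau = 0.6, init = "perturbed",
                    seed = 11)
  t1 <- fhn_simulate(m, config = cfg)
  t2 <- fhn_simulate(m, config = cfg)
  expect_identical(t1$u, t2$u)          # bit-identical under a fixed seed

  cfgn <- sim_config(t_end = 5, dt = 0.005, noise = 1e-3, seed = 12)
  n1 <- fhn_simulate(m, config = cfgn)
  n2 <- fhn_simulate(m, config = cfgn)
  expect_identical(n1$u, n2$u)
  cfg0 <- cfgn; cfg0$noise <- 0
  n0 <- fhn_simulate(m, config = cfg0)
  expect_false(identical(n1$u, n0$u))   # the noise path actually differs
  expect_lt(max(abs(n1$u - n0$u)), 0.1) # ... but only by the noise scale

  # changing t_end must not change the perturbation draw (substreams)
  a <- fhn_simulate(m, config = sim_config(t_end = 1, init = "perturbed",
                                           seed = 13))
  b <- fhn_simulate(m, config = sim_config(t_end = 2, init = "perturbed",
                                           seed = 13))
  expect_identical(a$u[, 1], b$u[, 1])
})

test_that("a delay beyond the Hopf threshold sustains oscillation", {
  m <- base_model()
  tr <- fhn_simulate(m, config = sim_config(t_end = 150, tau = 0.6,
                                            init = "perturbed", seed = 3,
                                            save_every = 50))
  us <- m$equilibria$u_star
  tail_dev <- max(abs(tr$u[, tr$times > 100] - us))
  expect_gt(tail_dev, 10 * 0.01)   # far beyond the initial perturbation
  # the sustained signal is periodic: dominant discrete frequency peak
  sig <- tr$u[1, tr$times > 75] - mean(tr$u[1, tr$times > 75])
  sp <- Mod(fft(sig))^2
  sp <- sp[2:(length(sp) %/% 2)]
  expect_gt(max(sp) / sum(sp), 0.3)
})

test_that("pattern matrices sort rows without changing column content", {
  m <- base_model()
  layers <- list(R = generate_layer(4, 0.5, seed = 8),
                 E = generate_layer(4, 0.5, seed = 9))
  tr <- fhn_simulate(m, layers, diffusion_params(0.01, 10),
                     sim_config(t_end = 10, dt = 0.01, init = "perturbed",
                                seed = 6))
  ms <- pattern_matrix(tr, sort_nodes = TRUE)
  mu <- pattern_matrix(tr, sort_nodes = FALSE)
  expect_identical(dim(ms), dim(mu))
  for (j in c(1, ncol(ms)))
    expect_equal(sort(ms[, j]), sort(mu[, j]))
  # constant trajectory: sorting is the identity (stable tie-break)
  trc <- fhn_simulate(m, layers, diffusion_params(0.01, 10),
                      sim_config(t_end = 1, dt = 0.01))
  expect_identical(attr(pattern_matrix(trc), "order"),
                   seq_len(trc$n_nodes))
})

test_that("the synchrony index separates coherent from independent signals", {
  mk_traj <- function(u) {
    structure(list(times = seq_len(ncol(u)) - 1, u = u, v = u * 0,
                   config = sim_config(t_end = ncol(u)),
                   n_nodes = nrow(u)),
              class = "fhn_trajectory")
  }
  tt <- seq(0, 20, 0.05)
  # identical oscillations across nodes
  u_sync <- matrix(rep(sin(tt), each = 30), nrow = 30)
  expect_equal(synchrony_index(mk_traj(u_sync), range(tt)), 1)
  # independent equal-power signals: the variance ratio gives ~ 1/2
  set.seed(20)
  u_iid <- matrix(rnorm(100 * 2000), nrow = 100)
  s <- synchrony_index(mk_traj(u_iid), c(0, 1999))
  expect_equal(s, 0.5, tolerance = 0.02)
  # constant input warns and returns 1
  expect_warning(s1 <- synchrony_index(mk_traj(matrix(1, 5, 50)), c(0, 49)),
                 "constant")
  expect_equal(s1, 1)
})

test_that("simulated pattern onset matches the spectral prediction", {
  m <- base_model()
  lin <- linearize(m)
  # clearly unstable fixture (dense spectrum, Dv far above threshold)
  layers <- list(R = generate_layer(20, 0.1, seed = 31),
                 E = generate_layer(20, 0.1, seed = 32))
  dd <- diffusion_params(0.01, 10)
  ta <- classify_spectrum(lin, dd, product_spectrum(layers$R, layers$E))
  expect_true(ta$any_unstable)
  grown <- amplitude_growth_test(m, layers, dd,
                                 sim_config(t_end = 300, dt = 0.01,
                                            init = "perturbed", seed = 33,
                                            save_every = 1000))
  expect_true(as.logical(grown))

  # empty network cannot destabilize; perturbation decays
  layers0 <- list(R = generate_layer(5, 0, seed = 1),
                  E = generate_layer(5, 0, seed = 1))
  ta0 <- classify_spectrum(lin, dd, product_spectrum(layers0$R, layers0$E))
  expect_false(ta0$any_unstable)
  g0 <- amplitude_growth_test(m, layers0, dd,
                              sim_config(t_end = 50, dt = 0.01,
                                         init = "perturbed", seed = 34,
                                         save_every = 1000))
  expect_false(as.logical(g0))

  # zero perturbation never "grows"
  gz <- amplitude_growth_test(m, layers0, dd,
                              sim_config(t_end = 5, dt = 0.01,
                                         init = "perturbed",
                                         perturb_amp = 0, seed = 35))
  expect_false(as.logical(gz))
})

test_that("blow-up is reported with the divergence time", {
  m <- base_model()
  # a grossly unstable explicit step (dt far beyond the stability limit)
  layers <- list(R = generate_layer(6, 1, seed = 1),
                 E = generate_layer(6, 1, seed = 1))
  expect_error(
    fhn_simulate(m, layers, diffusion_params(5, 50),
                 sim_config(t_end = 20, dt = 0.5, init = "perturbed")),
    "diverged")
})
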