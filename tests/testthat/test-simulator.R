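eq2 <- endemic_equilibrium(g2)
eq_state <- sivs_state(eq2$S_star, eq2$I_star, eq2$V_star, 0)

test_that("single-step update matches the printed discretization", {
  # the endemic equilibrium is a fixed point of the noiseless system
  p0 <- with_pars(g2, theta = 0)
  st <- milstein_step(eq_state, p0, dt = 1, h = 1.7)
  expect_equal(unclass(st), unclass(eq_state), tolerance = 1e-12)
  # Milstein m-update at m = 0, h = 0: m' = -theta^2 * dt / 2
  st2 <- milstein_step(sivs_state(1, 0.1, 1, 0), g2, dt = 1, h = 0)
  expect_equal(st2[["m"]], -0.005, tolerance = 1e-14)
  # exact_ou scheme with h = 0 decays exponentially instead
  st3 <- milstein_step(sivs_state(1, 0.1, 1, 0.3), g2, dt = 1, h = 0,
                       scheme = "exact_ou")
  expect_equal(st3[["m"]], 0.3 * exp(-0.7), tolerance = 1e-14)
  # I = 0 is invariant: every I-term carries a factor I
  st4 <- milstein_step(sivs_state(1, 0, 1, 0.1), g2, dt = 0.5, h = 1)
  expect_equal(st4[["I"]], 0)
})

test_that("simulation is deterministic given the seed and paths derive seeds", {
  cfg <- sim_config(dt = 0.02, n_steps = 400, seed = 9)
  tr1 <- simulate_path(eq_state, g2, cfg)
  tr2 <- simulate_path(eq_state, g2, cfg)
  expect_identical(tr1$S, tr2$S)
  expect_identical(tr1$m, tr2$m)
  # ensemble path j reproduces a single path run with seed + j - 1
  ens <- simulate_ensemble(eq_state, g2,
                           sim_config(dt = 0.02, n_steps = 400, n_paths = 3,
                                      seed = 9))
  tr3 <- simulate_path(eq_state, g2, sim_config(dt = 0.02, n_steps = 400,
                                                seed = 11))
  expect_identical(ens$I[, 1], tr1$I)
  expect_identical(ens$I[, 3], tr3$I)
})

test_that("noiseless dynamics converge to the endemic equilibrium", {
  p0 <- with_pars(g2, theta = 0)
  tr <- simulate_path(sivs_state(1.5, 0.2, 2.0, 0), p0,
                      sim_config(dt = 0.01, n_steps = 30000, seed = 1))
  n <- length(tr$times)
  expect_lt(max(abs(c(tr$S[n], tr$I[n], tr$V[n]) -
                    c(eq2$S_star, eq2$I_star, eq2$V_star))), 1e-3)
})

test_that("discrete total population respects the invariant-region bound", {
  tr <- simulate_path(sivs_state(0.6, 0.7, 2.5, 0), g2,
                      sim_config(dt = 0.01, n_steps = 20000, seed = 4))
  N <- tr$S + tr$I + tr$V
  expect_lte(max(N), max(N[1], g2$A / g2$eta) + 1e-9)
  # starting above A/eta the total is still bounded by its initial value
  tr2 <- suppressWarnings(simulate_path(sivs_state(2, 2, 2, 0), g2,
                          sim_config(dt = 0.01, n_steps = 5000, seed = 4)))
  N2 <- tr2$S + tr2$I + tr2$V
  expect_lte(max(N2), N2[1] + 1e-9)
})

test_that("deterministic terminal error shrinks linearly in dt", {
  p0 <- with_pars(g2, theta = 0)
  terminal <- function(dt) {
    tr <- simulate_path(sivs_state(1.0, 0.5, 2.0, 0), p0,
                        sim_config(dt = dt, n_steps = round(50 / dt), seed = 1))
    n <- length(tr$times)
    c(tr$S[n], tr$I[n], tr$V[n])
  }
  d1 <- max(abs(terminal(0.2) - terminal(0.1)))
  d2 <- max(abs(terminal(0.1) - terminal(0.05)))
  expect_lt(d2, d1)
  expect_gt(d1 / d2, 1.5)   # first-order scheme: halving dt halves the error
  expect_lt(d1 / d2, 3)
})

test_that("clamp policies handle negative excursions", {
  # violent transmission plus a coarse step drives S negative in one update
  pbad <- with_pars(g2, beta = 8)
  init <- sivs_state(0.5, 0.8, 0.5, 0)
  tr <- simulate_path(init, pbad, sim_config(dt = 1, n_steps = 3, seed = 2))
  expect_gt(tr$clamped, 0)
  expect_true(all(tr$S >= 0 & tr$I >= 0 & tr$V >= 0))
  expect_error(
    simulate_path(init, pbad, sim_config(dt = 1, n_steps = 3, seed = 2,
                                         clamp_policy = "reject")),
    "negative compartment at step")
  # a diverging coarse-step run aborts with the offending step index
  expect_error(
    simulate_path(init, pbad, sim_config(dt = 1, n_steps = 50, seed = 2)),
    "non-finite state at step")
})

test_that("an ensemble of one path reduces to simulate_path", {
  cfg <- sim_config(dt = 0.05, n_steps = 100, n_paths = 1, seed = 3)
  ens <- simulate_ensemble(eq_state, g2, cfg)
  tr <- simulate_path(eq_state, g2, cfg)
  expect_identical(as.vector(ens$S), tr$S)
  expect_identical(as.vector(ens$m), tr$m)
})
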