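lin2 <- linearize(g2)
cc2 <- characteristic_coefficients(lin2)

test_that("linearization coefficients follow their closed forms", {
  expect_equal(c(lin2$a11, lin2$a12, lin2$a13, lin2$a14,
                 lin2$a21, lin2$a31, lin2$a33, lin2$a44),
               c(1.36, 0.25, 0.2, 0.448148, 0.66, 0.6, 0.3, 0.7),
               tolerance = 1e-6)
  # a12 = beta*S* - gamma = eta + epsilon, independent of the equilibrium
  for (pars in sample_persistent_params(4, seed = 21)) {
    li <- linearize(pars)
    expect_equal(li$a12, pars$eta + pars$epsilon, tolerance = 1e-12)
    expect_equal(li$a12,
                 pars$beta * li$equilibria$S_star - pars$gamma,
                 tolerance = 1e-12)
    # du2 has no u2 term: A[2,2] = 0 by construction
    expect_identical(li$A_matrix[2, 2], 0)
  }
  expect_equal(lin2$G_matrix, diag(c(0, 0, 0, 0.1)))
})

test_that("characteristic coefficients and Hurwitz flag are consistent", {
  expect_equal(c(cc2$b1, cc2$b2, cc2$b3), c(1.66, 0.453, 0.0495),
               tolerance = 1e-10)
  expect_equal(c(cc2$c1, cc2$c2, cc2$c3, cc2$c4),
               c(2.36, 1.615, 0.3666, 0.03465), tolerance = 1e-10)
  expect_equal(cc2$b1 * cc2$b2 - cc2$b3, 0.70248, tolerance = 1e-10)
  expect_true(cc2$hurwitz)
  # sign conditions agree with an eigenvalue solve, here and for random draws
  expect_true(all(Re(cc2$eigenvalues) < 0))
  for (pars in sample_persistent_params(4, seed = 8)) {
    cc <- characteristic_coefficients(linearize(pars))
    expect_identical(cc$hurwitz, all(Re(cc$eigenvalues) < 0))
  }
})

test_that("Lyapunov solve satisfies its defining equation", {
  ly <- solve_lyapunov(lin2)
  A <- lin2$A_matrix
  G2 <- lin2$G_matrix %*% lin2$G_matrix
  expect_lt(max(abs(G2 + A %*% ly$Sigma + ly$Sigma %*% t(A))), 1e-10)
  expect_equal(ly$Sigma, t(ly$Sigma), tolerance = 1e-12)
  expect_true(ly$positive_definite)
  # the decoupled OU row forces Sigma[4,4] = theta^2/(2k)
  expect_equal(ly$Sigma[4, 4], 0.1^2 / 1.4, tolerance = 1e-12)
  # theta = 0: no forcing, Sigma = 0
  ly0 <- solve_lyapunov(linearize(with_pars(g2, theta = 0)))
  expect_equal(max(abs(ly0$Sigma)), 0, tolerance = 1e-14)
})

test_that("Sigma scales exactly as theta^2", {
  ly1 <- solve_lyapunov(linearize(g2))
  ly2 <- solve_lyapunov(linearize(with_pars(g2, theta = 0.2)))
  expect_equal(ly2$Sigma, 4 * ly1$Sigma, tolerance = 1e-12)
})

test_that("transformation chain reproduces the Lyapunov solution", {
  ch <- sigma_transform_chain(lin2)
  ly <- solve_lyapunov(lin2)
  expect_lt(max(abs(ch$Sigma - ly$Sigma)), 1e-8)
  expect_identical(ch$a7_variant, "proof")
  # the theorem-statement a7 does not reproduce the oracle
  expect_lt(ch$oracle_discrepancy[["proof"]], 1e-10)
  expect_gt(ch$oracle_discrepancy[["theorem"]], 1e-4)
  # B is in companion form with top row (-c1, -c2, -c3, -c4)
  expect_equal(ch$B[1, ], -c(cc2$c1, cc2$c2, cc2$c3, cc2$c4),
               tolerance = 1e-10)
  expect_equal(ch$B[2:4, ], cbind(diag(3), 0), tolerance = 1e-10)
  # positive-definiteness determinant condition on the quartic coefficients
  expect_gt(cc2$c1 * cc2$c2 * cc2$c3 - cc2$c3^2 - cc2$c1^2 * cc2$c4, 0)
  expect_true(ch$positive_definite)
})

test_that("marginal densities reproduce the Gaussian prefactor algebra", {
  eq <- endemic_equilibrium(g2)
  # diagonals of a previously reported stationary covariance (x 1e-2)
  marg <- marginal_densities(c(0.0706, 0.2391, 0.0870) * 1e-2, eq)
  expect_equal(marg$S$prefactor, 15.01332, tolerance = 1e-3)
  expect_equal(marg$I$prefactor, 8.15787, tolerance = 1e-3)
  expect_equal(marg$V$prefactor, 13.52366, tolerance = 1e-3)
  expect_equal(marg$I$mean, eq$I_star)
  for (m in marg) {
    expect_equal(m$prefactor * sqrt(2 * pi * m$variance), 1, tolerance = 1e-12)
    expect_equal(m$exp_coeff * 2 * m$variance, 1, tolerance = 1e-12)
  }
  expect_error(marginal_densities(c(-1, 1, 1) * 1e-3, eq), "positive")
  expect_error(marginal_densities(solve_lyapunov(lin2),
                                  endemic_equilibrium(g1)),
               "endemic equilibrium")
})

test_that("joint density has Gaussian normalisation and symmetry", {
  ly <- solve_lyapunov(lin2)
  # value at the mode
  expect_equal(density_at(c(0, 0, 0, 0), ly),
               (2 * pi)^-2 / sqrt(det(ly$Sigma)), tolerance = 1e-12)
  u <- c(0.01, -0.02, 0.015, 0.03)
  expect_equal(density_at(u, ly), density_at(-u, ly), tolerance = 1e-12)
  # log-density difference equals the quadratic form, computed independently
  q <- drop(u %*% solve(ly$Sigma) %*% u)
  expect_equal(log(density_at(u, ly)) - log(density_at(rep(0, 4), ly)),
               -q / 2, tolerance = 1e-10)
  # Monte-Carlo normalisation via importance sampling from N(0, 4 Sigma)
  set.seed(1)
  L <- chol(4 * ly$Sigma)
  Z <- matrix(rnorm(4e4), ncol = 4) %*% L
  w <- density_at(Z, ly) / density_at(Z %*% diag(0.5, 4),
                                      ly) * 2^4  # q(z) = phi_Sigma(z/2)/2^4
  expect_equal(mean(w), 1, tolerance = 0.05)
})

test_that("chain equals Lyapunov across random persistent parameter sets", {
  for (pars in sample_persistent_params(6, seed = 14)) {
    lin <- linearize(pars)
    ly <- solve_lyapunov(lin)
    ch <- sigma_transform_chain(lin)
    expect_lt(max(abs(ch$Sigma - ly$Sigma)), 1e-8)
    expect_equal(ly$Sigma[4, 4], pars$theta^2 / (2 * pars$k),
                 tolerance = 1e-12)
    expect_true(ly$positive_definite)
  }
})

test_that("long stochastic runs reproduce the Lyapunov covariance", {
  # small-noise linearization check: empirical covariance of one long
  # exact-OU path around P* approaches Sigma (diagonals within 25%)
  pars <- with_pars(g2, theta = 0.02)
  eq <- endemic_equilibrium(pars)
  tr <- simulate_path(sivs_state(eq$S_star, eq$I_star, eq$V_star, 0), pars,
                      sim_config(dt = 0.1, n_steps = 5e5, seed = 42,
                                 scheme = "exact_ou"))
  sel <- tr$times > 1000
  emp <- stats::cov(cbind(tr$S[sel], tr$I[sel], tr$V[sel], tr$m[sel]))
  Sig <- solve_lyapunov(linearize(pars))$Sigma
  expect_lt(max(abs(diag(emp) - diag(Sig)) / diag(Sig)), 0.25)
})
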