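test_that("case fractions integrate the pause-site pmf over spacing multiples", {
  ref <- truncated_gaussian_pmf(50, 25^2, 17, 200)
  q <- q_fractions(ref, s_p = 50)
  expect_equal(sum(q), 1)
  expect_equal(1 - q[1], 0.54, tolerance = 0.005)       # >= 2 RNAPs possible
  expect_equal(round(100 * q[3], 1), 2.4)               # >= 3 RNAPs possible
  narrow <- truncated_gaussian_pmf(50, 25^2, 17, 120)
  expect_equal(q_fractions(narrow, s_p = 120), c(1, 0, 0))
  expect_error(q_fractions(ref, s_p = 4, R = 3), "support")
})

test_that("closed-form case occupancies equal the birth-death linear solve", {
  expect_equal(phi_case(1, 1, 1), 1 / 2)
  expect_equal(phi_case(1, 1, 2), 1 / 3)
  expect_equal(phi_case(1, 1, 3), 1 / 4)
  expect_equal(phi_case(1, 2, 2), 1 / 7)
  set.seed(31)
  for (i in 1:8) {
    a <- runif(1, 0.05, 10); b <- runif(1, 0.05, 10)
    for (r in 1:5)
      expect_equal(phi_case(a, b, r), birth_death_top_state(a, b, r),
                   tolerance = 1e-10)
  }
  expect_error(phi_case(0, 0, 1), "zero")
})

test_that("mixture occupancy interpolates the cases and reduces to the two-state model", {
  expect_equal(phi_mixture(2, 3, c(1, 0, 0)), 2 / 5)
  expect_equal(phi_mixture(1, 1, c(0, 1, 0)), 1 / 3)
  expect_equal(phi_mixture(1, 1, c(0.5, 0.5, 0)), 5 / 12)
  # q_1 -> 1 limit approaches the single-RNAP formula continuously
  a <- 0.7; b <- 1.3
  for (eps in c(0.1, 0.01, 1e-4, 1e-8)) {
    q <- c(1 - eps, eps / 2, eps / 2)
    expect_lt(abs(phi_mixture(a, b, q) - a / (a + b)), eps)
  }
})

test_that("alpha/phi recovery round-trips the forward steric map", {
  sol <- solve_alpha_phi(0.5, 1, q = c(1, 0, 0))
  expect_equal(sol$phi, 0.5)
  expect_equal(sol$alpha, 1)
  # omega -> 0: no hindrance
  sol0 <- solve_alpha_phi(1e-8, 1, q = c(1, 0, 0))
  expect_equal(sol0$alpha, 1e-8, tolerance = 1e-6)
  expect_lt(sol0$phi, 1e-6)
  # saturation
  sat <- solve_alpha_phi(1.2, 1, q = c(1, 0, 0))
  expect_true("saturated" %in% sat$flags)
  expect_true(is.na(sat$alpha))

  set.seed(41)
  for (i in 1:20) {
    alpha <- runif(1, 0.05, 8); beta <- runif(1, 0.05, 8)
    q <- c(runif(1), runif(1), runif(1)); q <- q / sum(q)
    phi <- phi_mixture(alpha, beta, q)
    omega <- (1 - phi) * alpha
    if (omega >= beta) next
    sol <- solve_alpha_phi(omega, beta, q)
    expect_equal(sol$alpha, alpha, tolerance = 1e-6)
    expect_equal(sol$phi, phi, tolerance = 1e-8)
    # omega never exceeds beta at a valid solution
    expect_lte(omega, beta)
  }
})

test_that("steric EM recovers occupancy in the single-RNAP regime", {
  # simulator with k = 45 < s_p = 50: pure case 1, phi = alpha/(alpha+beta)
  occ <- simulate_cells(simulation_config(
    n_cells = 1200, total_time = 15, alpha_zeta = 1, beta_zeta = 1,
    pause_mode = "fixed", pause_mean = 45, seed = 55))
  lam <- calibrate_lambda(occ)
  omega_true <- empirical_effective_initiation_rate(occ)
  # lambda_scale such that omega*zeta = chi*zeta/lambda is on the
  # simulated scale: chi ~ 0.049 corresponds to omega_true events/min
  lam_eff <- 0.049 * 2000 / omega_true
  set.seed(5)
  phis <- replicate(12, {
    p <- sample_reads(occ, read_sampler_config(lam, 600))
    chi <- p$gene_body_sum / p$gene_body_len
    st <- suppressWarnings(
      fit_steric(p, chi, steric_config(s_p = 50, zeta = 2000,
                                       lambda_scale = lam_eff)))
    st$estimate$phi
  })
  expect_lt(abs(mean(phis) - empirical_landing_pad_occupancy(occ)), 0.1)

  # uninformative data: prior pulls phi toward its mode 1/2;
  # strong no-pause data pushes phi toward 0
  set.seed(6)
  flat <- gene_profile("g", rpois(200, 5), rpois(1, 5 * 19800), 19800)
  chi <- flat$gene_body_sum / flat$gene_body_len
  stf <- suppressWarnings(fit_steric(flat, chi,
                                     steric_config(zeta = 2000,
                                                   lambda_scale = 2000)))
  if (!is.null(stf$estimate)) expect_lt(stf$estimate$phi, 0.5)
})

test_that("escape-rate estimates are stable across plausible RNAP spacings", {
  # one variable-pause equilibrium run, refit under s_p = 33 / 50 / 70 nt;
  # beta*zeta should stay within a factor ~2 of the simulated 1 event/min
  # (covers the multi-RNAP stacking bias plus Monte-Carlo error at this
  # reduced scale)
  occ <- simulate_cells(simulation_config(
    n_cells = 1000, total_time = 12, alpha_zeta = 1, beta_zeta = 1,
    pause_mode = "variable", seed = 66))
  lam <- calibrate_lambda(occ)
  lam_eff <- 0.049 * 2000 / empirical_effective_initiation_rate(occ)
  set.seed(9)
  p <- sample_reads(occ, read_sampler_config(lam, 500))
  chi <- p$gene_body_sum / p$gene_body_len
  for (sp in c(33, 50, 70)) {
    st <- suppressWarnings(
      fit_steric(p, chi, steric_config(s_p = sp, zeta = 2000,
                                       lambda_scale = lam_eff)))
    expect_gt(st$estimate$beta_zeta, 0.5, label = paste("s_p =", sp))
    expect_lt(st$estimate$beta_zeta, 2.0, label = paste("s_p =", sp))
  }
})

test_that("half-life follows the pause-transit construction", {
  expect_equal(half_life(1, k_bar = 1, zeta = log(2)), 1)
  expect_equal(half_life(0.0005, k_bar = 50, zeta = 2000),
               log(2) * 2049 / 2000)
  b <- c(0.001, 0.01, 0.1, 1)
  expect_true(all(diff(half_life(b)) < 0))
  expect_error(half_life(0), "positive")
})
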