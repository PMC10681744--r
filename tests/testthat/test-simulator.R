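test_that("degenerate and invalid configurations are handled", {
  occ <- small_sim(alpha_zeta = 0, n_cells = 50, total_time = 2)
  expect_length(occ$position, 0)
  expect_equal(empirical_landing_pad_occupancy(occ), 0)
  expect_equal(empirical_effective_initiation_rate(occ), 0)
  expect_error(simulation_config(dt = 1e-2, zeta_max = 2500),
               "rate \\* dt")
})

test_that("identical seeds give bit-identical trajectories", {
  a <- small_sim(seed = 99, n_cells = 100, total_time = 4)
  b <- small_sim(seed = 99, n_cells = 100, total_time = 4)
  expect_identical(a$position, b$position)
  expect_identical(a$cell, b$cell)
  expect_identical(a$n_success, b$n_success)
  c <- small_sim(seed = 100, n_cells = 100, total_time = 4)
  expect_false(identical(a$position, c$position))
})

test_that("spacing exclusion holds for every cell", {
  occ <- simulate_cells(simulation_config(
    n_cells = 150, total_time = 6, alpha_zeta = 5, beta_zeta = 0.5,
    pause_mode = "variable", seed = 3), check_spacing = TRUE)
  gaps <- unlist(tapply(occ$position, occ$cell,
                        function(p) diff(sort(p))))
  expect_true(all(gaps >= occ$config$s_p))
  expect_true(all(occ$position >= 1 & occ$position <= 2000))
})

test_that("long-run occupancy matches the stationary distribution", {
  # no pausing, constant zeta, sparse initiation: occupancy uniform over 1..N
  occ <- simulate_cells(simulation_config(
    n_cells = 1200, total_time = 10, alpha_zeta = 0.25, beta_zeta = 1,
    pause_mode = "none", zeta_mean = 2000, zeta_sd = 1e-6,
    zeta_min = 2000 - 1e-3, zeta_max = 2000 + 1e-3, seed = 8))
  thirds <- table(cut(occ$position, c(0, 667, 1333, 2000)))
  expect_gt(suppressWarnings(stats::chisq.test(thirds)$p.value), 0.001)

  # fixed pause site: pause/body occupancy ratio ~ 1/beta
  occ2 <- simulate_cells(simulation_config(
    n_cells = 1500, total_time = 15, alpha_zeta = 1, beta_zeta = 1,
    pause_mode = "fixed", seed = 12))
  n_pause <- sum(occ2$position == 50)
  body <- occ2$position > 200
  body_per_nt <- sum(body) / 1800
  ratio <- n_pause / body_per_nt
  # 1/beta = zeta/beta_zeta = 2000; binomial MC error ~ 1/sqrt(n_pause)
  se_rel <- 3 * sqrt(1 / n_pause + 1 / sum(body))
  expect_lt(abs(ratio / 2000 - 1), se_rel + 0.1)
})

test_that("read sampler follows the Poisson occupancy scaling", {
  occ <- small_sim(n_cells = 400, total_time = 10, seed = 5)
  set.seed(1)
  rc <- read_sampler_config(lambda_c = 200, n_sampled_cells = 200)
  p <- sample_reads(occ, rc)
  expect_s3_class(p, "gene_profile")
  expect_length(p$pause_counts, 200)
  expect_equal(p$gene_body_len, 19800)
  expect_error(sample_reads(occ, read_sampler_config(200, 5000)),
               "more cells")

  # doubling lambda doubles expected counts
  set.seed(2)
  tot1 <- mean(replicate(40, {
    q <- sample_reads(occ, read_sampler_config(100, 200))
    sum(q$pause_counts) + q$gene_body_sum
  }))
  set.seed(2)
  tot2 <- mean(replicate(40, {
    q <- sample_reads(occ, read_sampler_config(200, 200))
    sum(q$pause_counts) + q$gene_body_sum
  }))
  expect_equal(tot2 / tot1, 2, tolerance = 0.1)

  # empty occupancy gives an all-zero profile
  empty <- small_sim(alpha_zeta = 0, n_cells = 50, total_time = 1)
  p0 <- sample_reads(empty, read_sampler_config(100, 50))
  expect_equal(sum(p0$pause_counts) + p0$gene_body_sum, 0)
})

test_that("lambda calibration hits the target read depth", {
  expect_equal(calibrate_lambda(small_sim(n_cells = 200, total_time = 6),
                                target_depth = 0), 0)
  occ <- simulate_cells(simulation_config(
    n_cells = 1000, total_time = 15, alpha_zeta = 1, beta_zeta = 1,
    pause_mode = "fixed", seed = 31))
  lam <- calibrate_lambda(occ)
  expect_equal(calibrate_lambda(occ, target_depth = 2 * 0.049), 2 * lam)
  set.seed(3)
  depth <- mean(replicate(30, {
    p <- sample_reads(occ, read_sampler_config(lam, 500))
    p$gene_body_sum / p$gene_body_len
  }))
  expect_equal(depth, 0.049, tolerance = 0.1)
})

test_that("landing-pad occupancy and effective initiation match two-state theory", {
  # k = 50 <= s_p: exactly one RNAP fits; phi = alpha/(alpha+beta) = 1/2,
  # omega = alpha*beta/(alpha+beta) = 1/2 events/min
  occ <- simulate_cells(simulation_config(
    n_cells = 1500, total_time = 15, alpha_zeta = 1, beta_zeta = 1,
    pause_mode = "fixed", seed = 17))
  phi <- empirical_landing_pad_occupancy(occ)
  expect_lt(abs(phi - 0.5), 3 * sqrt(0.25 / 1500) + 0.02)
  om <- empirical_effective_initiation_rate(occ)
  expect_lt(abs(om - 0.5), 0.05)

  # beta >> alpha: pausing negligible, omega ~ alpha
  occ2 <- simulate_cells(simulation_config(
    n_cells = 800, total_time = 10, alpha_zeta = 0.5, beta_zeta = 50,
    pause_mode = "fixed", seed = 18))
  expect_equal(empirical_effective_initiation_rate(occ2), 0.5,
               tolerance = 0.1)

  # every cell occupied at the pad
  dense <- simulate_cells(simulation_config(
    n_cells = 100, total_time = 10, alpha_zeta = 20, beta_zeta = 0.01,
    pause_mode = "fixed", seed = 19))
  expect_gt(empirical_landing_pad_occupancy(dense), 0.98)
})

test_that("occupancy is monotone in the initiation and escape rates", {
  grid_phi <- matrix(NA, 3, 3)
  az <- c(0.3, 1, 3); bz <- c(0.3, 1, 3)
  for (i in 1:3) for (j in 1:3)
    grid_phi[i, j] <- empirical_landing_pad_occupancy(simulate_cells(
      simulation_config(n_cells = 500, total_time = 12, alpha_zeta = az[i],
                        beta_zeta = bz[j], pause_mode = "fixed", seed = 7)))
  slack <- 0.05   # Monte-Carlo slack at 500 cells
  expect_true(all(diff(grid_phi[, 1]) > -slack),
              all(diff(grid_phi[, 2]) > -slack),
              all(diff(grid_phi[, 3]) > -slack))
  expect_true(all(diff(grid_phi[1, ]) < slack) &&
              all(diff(grid_phi[2, ]) < slack) &&
              all(diff(grid_phi[3, ]) < slack))
})
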