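# Independent oracles used across tests. These deliberately take the slow,
# brute-force route (linear solves, grid searches, explicit convolutions) so
# that they share no code path with the implementation they check.

# stationary distribution of a full generator via null space of t(Q),
# conditioned on the engaged states 1..N
nullspace_stationary <- function(Q) {
  v <- svd(t(Q))$v[, nrow(Q)]   # right null vector of t(Q): pi Q = 0
  v <- abs(v) / sum(abs(v))
  v[-1] / sum(v[-1])
}

# argmax of the fixed-pause-site log-likelihood over a (chi, beta) grid
grid_mle <- function(x, k, chi_grid, beta_grid) {
  best <- c(NA, NA); best_ll <- -Inf
  for (chi in chi_grid) for (beta in beta_grid) {
    ll <- loglik_fixed_pause(x, chi, beta, k = k)
    if (ll > best_ll) { best_ll <- ll; best <- c(chi, beta) }
  }
  list(chi = best[1], beta = best[2], loglik = best_ll)
}

# naive textbook formulas for the f-weighted E-step complements (unstable
# when f ~ 1, so only used with bounded f)
naive_em_complements <- function(X, f, Yk) {
  k <- as.integer(names(f))
  w <- f / (1 - f) * (X - Yk)
  list(w = sum(w), z = sum(w * k), r = sum(w * k^2))
}

# explicit birth-death generator for r RNAPs in the pause region:
# states 0..r, births at alpha, deaths at beta; top-state stationary mass
birth_death_top_state <- function(alpha, beta, r) {
  G <- matrix(0, r + 1, r + 1)
  for (i in seq_len(r)) { G[i, i + 1] <- alpha; G[i + 1, i] <- beta }
  diag(G) <- -rowSums(G)
  v <- svd(t(G))$v[, r + 1]
  v <- abs(v) / sum(abs(v))
  v[r + 1]
}

# brute-force convolution of the two-Poisson mixture at one position
convolved_logpmf <- function(X, lam1, lam2) {
  log(sum(dpois(0:X, lam1) * dpois(X - (0:X), lam2)))
}

# small simulator run shared by several tests (cheap: ~1 s)
small_sim <- function(alpha_zeta = 1, beta_zeta = 1, pause_mode = "fixed",
                      n_cells = 400, total_time = 8, seed = 42, ...) {
  simulate_cells(simulation_config(
    n_cells = n_cells, total_time = total_time, alpha_zeta = alpha_zeta,
    beta_zeta = beta_zeta, pause_mode = pause_mode, seed = seed, ...))
}
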