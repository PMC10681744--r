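#' Simulator configuration
#'
#' Parameters for the discrete-time-slice RNAP traffic simulator. Defaults
#' reproduce the synthetic-data conditions used throughout the package's
#' validation experiments: 2000-bp templates, time slices of 1e-4 min,
#' per-position elongation rates drawn from a truncated normal with mean
#' 2000, sd 1000, bounds [1500, 2500] nt/min, and (in variable mode) pause
#' sites drawn per cell from a truncated normal with mean 50, sd 25, bounds
#' [17, 200] nt. The minimum center-to-center RNAP spacing defaults to
#' \code{s_p = 50} nt.
#'
#' @param n_cells number of cells C.
#' @param template_len template length N in nt.
#' @param total_time simulated time in minutes.
#' @param dt time-slice length in minutes. Bernoulli-per-slice validity
#'   requires \code{rate * dt < 1} for every rate.
#' @param alpha_zeta initiation rate in events/min.
#' @param beta_zeta pause-escape rate in events/min.
#' @param zeta_mean,zeta_sd,zeta_min,zeta_max truncated-normal parameters for
#'   the per-position elongation rates (nt/min).
#' @param pause_mode "fixed" (all cells pause at \code{pause_mean}),
#'   "variable" (per-cell truncated-normal pause sites) or "none" (pausing
#'   disabled, e.g. for calibration baselines).
#' @param pause_mean,pause_sd,pause_min,pause_max pause-site distribution
#'   parameters (nt).
#' @param s_p minimum center-to-center spacing between adjacent RNAPs (nt).
#' @param burn_in time (min) excluded from the initiation-event counters.
#' @param seed integer seed for the simulator's random stream.
#'
#' @return an object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_cells = 20000, template_len = 2000,
                              total_time = 40, dt = 1e-4,
                              alpha_zeta = 1, beta_zeta = 1,
                              zeta_mean = 2000, zeta_sd = 1000,
                              zeta_min = 1500, zeta_max = 2500,
                              pause_mode = c("fixed", "variable", "none"),
                              pause_mean = 50, pause_sd = 25,
                              pause_min = 17, pause_max = 200,
                              s_p = 50, burn_in = total_time / 4, seed = 1) {
  pause_mode <- match.arg(pause_mode)
  stopifnot(dt > 0, s_p >= 1, n_cells >= 1, template_len >= 3,
            total_time > 0, pause_min >= 1, pause_max <= template_len)
  rmax <- max(alpha_zeta, beta_zeta, zeta_max)
  if (rmax * dt >= 1)
    stop("rate * dt >= 1: decrease dt for Bernoulli-per-slice validity")
  structure(list(n_cells = as.integer(n_cells),
                 template_len = as.integer(template_len),
                 total_time = total_time, dt = dt,
                 alpha_zeta = alpha_zeta, beta_zeta = beta_zeta,
                 zeta_mean = zeta_mean, zeta_sd = zeta_sd,
                 zeta_min = zeta_min, zeta_max = zeta_max,
                 pause_mode = pause_mode, pause_mean = pause_mean,
                 pause_sd = pause_sd, pause_min = pause_min,
                 pause_max = pause_max, s_p = as.integer(s_p),
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "simulation_config")
}

# truncated-normal draws by rejection; n small, bounds wide: cheap
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate RNAP traffic across cells
#'
#' Runs the stochastic simulator: each cell carries an N-nt template; RNAPs
#' initiate at position 1 when the landing pad (positions 1..s_p) is free,
#' elongate with per-position probability \code{zeta_i * dt} per slice, wait
#' at the cell's pause site with escape probability \code{beta_zeta * dt},
#' and leave the template upon advancing past N. Advances that would bring
#' an RNAP within \code{s_p - 1} nt of its downstream neighbour are
#' cancelled. Per-position elongation rates are drawn once and shared across
#' cells; pause sites are drawn per cell (variable mode). Identical seeds
#' give bit-identical results.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param check_spacing assert the spacing invariant after every slice
#'   (debug mode; slows the run down).
#'
#' @return an object of class \code{"cell_occupancy"}: integer vectors
#'   \code{cell} and \code{position} giving the final RNAP active-site
#'   positions, per-cell \code{pause_site}, event counters
#'   (\code{n_success}, \code{n_blocked}, recorded after burn-in), the
#'   elongation-rate vector \code{zeta}, and the config.
#' @export
simulate_cells <- function(config, check_spacing = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  zeta <- rtruncnorm(config$template_len, config$zeta_mean, config$zeta_sd,
                     config$zeta_min, config$zeta_max)
  pause_site <- switch(config$pause_mode,
    fixed = rep(as.integer(round(config$pause_mean)), config$n_cells),
    variable = as.integer(pmin(pmax(round(
      rtruncnorm(config$n_cells, config$pause_mean, config$pause_sd,
                 config$pause_min, config$pause_max)),
      config$pause_min), config$pause_max)),
    none = rep(0L, config$n_cells))
  steps <- round(config$total_time / config$dt)
  burnin <- round(config$burn_in / config$dt)
  res <- .simulate_cells_cpp(config$n_cells, config$template_len,
                             steps, burnin, config$dt,
                             config$alpha_zeta, config$beta_zeta,
                             zeta, pause_site, config$s_p,
                             config$seed + 0.0, check_spacing)
  structure(list(cell = res$cell, position = res$position,
                 pause_site = pause_site,
                 n_success = res$n_success, n_blocked = res$n_blocked,
                 counter_time = config$total_time - config$burn_in,
                 zeta = zeta, config = config),
            class = "cell_occupancy")
}

#' @export
print.cell_occupancy <- function(x, ...) {
  cat(sprintf("<cell_occupancy> %d cells, %d engaged RNAPs (%.2f/cell), template %d nt\n",
              x$config$n_cells, length(x$position),
              length(x$position) / x$config$n_cells, x$config$template_len))
  invisible(x)
}

#' Read-sampler configuration
#'
#' Parameters of the synthetic read-count sampler: per-nt Poisson counts in
#' the pause region and a single Poisson total for the gene body, with
#' extrapolation from the simulated gene-body length \code{l_sim} to a
#' target length \code{l_targ} (default 19800 bp, emulating genes of
#' realistic length).
#'
#' @param lambda_c read-depth scale (see \code{\link{calibrate_lambda}}).
#' @param n_sampled_cells number of cells C_s drawn without replacement.
#' @param pause_region_len length of the per-nt sampled region (nt).
#' @param l_targ target gene-body length (bp).
#'
#' @return an object of class \code{"read_sampler_config"}.
#' @export
read_sampler_config <- function(lambda_c, n_sampled_cells = 5000,
                                pause_region_len = 200, l_targ = 19800) {
  stopifnot(lambda_c >= 0, n_sampled_cells >= 1, pause_region_len >= 1)
  structure(list(lambda_c = lambda_c,
                 n_sampled_cells = as.integer(n_sampled_cells),
                 pause_region_len = as.integer(pause_region_len),
                 l_targ = as.integer(l_targ)),
            class = "read_sampler_config")
}

#' Sample synthetic read counts from simulated occupancy
#'
#' Draws C_s cells without replacement from a simulation and samples a read
#' count at each pause-region position i from
#' \eqn{\mathrm{Pois}(\lambda_c R_i / C_s)}, where R_i is the number of
#' sampled cells with an RNAP active site at i; the gene-body total is drawn
#' from \eqn{\mathrm{Pois}(\lambda_c (R_{GB}/C_s)(l_{targ}/l_{sim}))}, where
#' R_GB counts RNAPs downstream of the pause region and l_sim is the
#' simulated gene-body length.
#'
#' @param occupancy a \code{\link{simulate_cells}} result.
#' @param rcfg a \code{\link{read_sampler_config}}.
#' @param gene_id identifier for the resulting profile.
#'
#' @return a \code{\link{gene_profile}} whose gene-body length is
#'   \code{l_targ}.
#' @export
sample_reads <- function(occupancy, rcfg, gene_id = "sim") {
  stopifnot(inherits(occupancy, "cell_occupancy"),
            inherits(rcfg, "read_sampler_config"))
  C <- occupancy$config$n_cells
  Cs <- rcfg$n_sampled_cells
  if (Cs > C) stop("cannot sample more cells than were simulated")
  P <- rcfg$pause_region_len
  l_sim <- occupancy$config$template_len - P
  keep <- sample.int(C, Cs)
  sel <- occupancy$cell %in% keep
  posn <- occupancy$position[sel]
  Ri <- tabulate(posn[posn <= P], nbins = P)
  R_gb <- sum(posn > P)
  X <- rpois(P, rcfg$lambda_c * Ri / Cs)
  gb <- rpois(1, rcfg$lambda_c * (R_gb / Cs) * (rcfg$l_targ / l_sim))
  gene_profile(gene_id, X, gb, rcfg$l_targ)
}

#' Calibrate the read-depth scale
#'
#' Chooses \eqn{\lambda_c} such that the expected mean gene-body read depth
#' on a baseline simulation equals \code{target_depth} (default 0.049
#' reads/bp, the median depth observed in real PRO-seq libraries that the
#' synthetic data emulate). The baseline is conventionally run at
#' \code{alpha_zeta = beta_zeta = 1} events/min.
#'
#' @param baseline a \code{\link{cell_occupancy}} from the baseline run.
#' @param target_depth desired mean gene-body depth in reads/bp.
#' @param pause_region_len pause-region length excluded from the gene body.
#'
#' @return scalar \code{lambda_c}.
#' @export
calibrate_lambda <- function(baseline, target_depth = 0.049,
                             pause_region_len = 200) {
  stopifnot(inherits(baseline, "cell_occupancy"))
  if (target_depth < 0) stop("target_depth must be nonnegative")
  C <- baseline$config$n_cells
  l_sim <- baseline$config$template_len - pause_region_len
  R_gb <- sum(baseline$position > pause_region_len)
  if (R_gb == 0) stop("no gene-body occupancy in the baseline run")
  # E[depth] = lambda_c * (R_gb / C) / l_sim, independent of l_targ
  target_depth * l_sim * C / R_gb
}

#' Empirical landing-pad occupancy
#'
#' Fraction of cells whose landing pad (positions 1..s_p) holds at least one
#' RNAP in the final simulator snapshot. This is the simulation counterpart
#' of the model parameter \eqn{\phi}.
#'
#' @param occupancy a \code{\link{cell_occupancy}}.
#' @param s_p landing-pad size; defaults to the simulated spacing.
#'
#' @return a fraction in [0, 1].
#' @export
empirical_landing_pad_occupancy <- function(occupancy,
                                            s_p = occupancy$config$s_p) {
  stopifnot(inherits(occupancy, "cell_occupancy"))
  occ_cells <- unique(occupancy$cell[occupancy$position <= s_p])
  length(occ_cells) / occupancy$config$n_cells
}

#' Empirical effective initiation rate
#'
#' Rate (events/min/cell) at which initiation events actually occurred in
#' the simulation (attempts that found the landing pad free), counted after
#' the burn-in window. This measures \eqn{\omega\zeta}, the effective
#' initiation rate after steric blocking.
#'
#' @param occupancy a \code{\link{cell_occupancy}}.
#'
#' @return events per minute per cell.
#' @export
empirical_effective_initiation_rate <- function(occupancy) {
  stopifnot(inherits(occupancy, "cell_occupancy"))
  if (occupancy$counter_time <= 0)
    stop("no counting window remains after burn-in")
  occupancy$n_success / (occupancy$config$n_cells * occupancy$counter_time)
}
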