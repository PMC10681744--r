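#' Steric-model configuration
#'
#' Settings for the steric-hindrance model: the minimum center-to-center
#' RNAP spacing \code{s_p} (structural estimates put it between about 33
#' and 70 nt; 50 nt is the default), the maximum number of RNAPs modeled in
#' the pause region \code{R}, the Beta prior on the landing-pad occupancy
#' \eqn{\phi} (shape a = b = 2 by default, weakly informative), and the
#' scale factors \code{zeta} (nt/min) and \code{lambda_scale} needed to turn
#' \eqn{\chi} into an effective initiation rate
#' \eqn{\omega\zeta = \chi\zeta/\lambda} (events/min).
#'
#' @param s_p minimum center-to-center spacing (nt).
#' @param R maximum RNAPs modeled in the pause region.
#' @param prior_a,prior_b Beta prior shape parameters (> 0).
#' @param zeta elongation rate (nt/min).
#' @param lambda_scale sequencing-depth scale lambda.
#'
#' @return an object of class \code{"steric_config"}.
#' @export
steric_config <- function(s_p = 50, R = 3, prior_a = 2, prior_b = 2,
                          zeta = 2000, lambda_scale = 1) {
  stopifnot(s_p >= 1, R >= 1, prior_a > 0, prior_b > 0, zeta > 0,
            lambda_scale > 0)
  structure(list(s_p = as.integer(s_p), R = as.integer(R),
                 prior_a = prior_a, prior_b = prior_b, zeta = zeta,
                 lambda_scale = lambda_scale),
            class = "steric_config")
}

#' Case probabilities for the number of RNAPs that fit in the pause region
#'
#' In a cell whose pause site is k, at most \eqn{r = \lceil k/s_p \rceil}
#' RNAPs fit between the TSS and the pause site. Integrating the pause-site
#' pmf over these geometric cases gives \eqn{q_r = F(r s_p) - F((r-1) s_p)}
#' for r < R, with the final case absorbing the remaining tail
#' (\eqn{q'_R = 1 - \sum_{r<R} q_r}).
#'
#' @param dist a \code{pause_site_distribution} (normalized pmf).
#' @param s_p minimum center-to-center spacing (nt).
#' @param R maximum number of cases.
#'
#' @return numeric vector q of length R summing to 1.
#' @export
q_fractions <- function(dist, s_p, R = 3) {
  stopifnot(inherits(dist, "pause_site_distribution"), s_p >= 1, R >= 1)
  k <- dist$k_min:dist$k_max
  if (R * s_p < dist$k_min)
    stop("R * s_p below the pause-site support: no case can hold the pause site")
  Fk <- function(x) sum(dist$f[k <= x])
  q <- numeric(R)
  if (R > 1)
    for (r in seq_len(R - 1)) q[r] <- Fk(r * s_p) - Fk((r - 1) * s_p)
  q[R] <- 1 - sum(q[-R])
  q
}

#' Landing-pad occupancy for a fixed maximum of r RNAPs
#'
#' Stationary probability that the landing pad is occupied when up to r
#' RNAPs fit in the pause region. The birth-death chain over 0..r occupants
#' (births at rate \eqn{\alpha\zeta}, deaths at \eqn{\beta\zeta}) has its
#' landing pad blocked exactly in the top state, giving
#' \deqn{\phi_r = \frac{\alpha^r}{\sum_{i=0}^{r} \alpha^i \beta^{r-i}},}
#' e.g. \eqn{\phi_1 = \alpha/(\alpha+\beta)},
#' \eqn{\phi_2 = \alpha^2/(\alpha^2+\beta^2+\alpha\beta)},
#' \eqn{\phi_3 = \alpha^3/(\alpha^3+\beta^3+\alpha^2\beta+\alpha\beta^2)}.
#'
#' @param alpha potential initiation rate.
#' @param beta pause-escape rate (same units as alpha; the result depends
#'   only on their ratio).
#' @param r number of RNAPs in the case (>= 1).
#'
#' @return occupancy probability in [0, 1].
#' @export
phi_case <- function(alpha, beta, r) {
  stopifnot(r >= 1, alpha >= 0, beta >= 0)
  if (alpha == 0 && beta == 0) stop("alpha and beta cannot both be zero")
  if (alpha == 0) return(0)
  if (beta == 0) return(1)
  x <- alpha / beta            # phi_r = x^r / sum_{i=0}^r x^i
  if (x <= 1) {
    x^r / sum(x^(0:r))
  } else {
    y <- 1 / x                 # divide through by alpha^r for large ratios
    1 / sum(y^(0:r))
  }
}

#' Mixture landing-pad occupancy
#'
#' Averages the case-specific occupancies over the geometric case
#' probabilities: \eqn{\phi = \sum_r q'_r \phi_r(\alpha, \beta)}. As
#' \eqn{q_1 \to 1} this reduces to the single-RNAP two-state result
#' \eqn{\phi = \alpha/(\alpha+\beta)}.
#'
#' @param alpha,beta rates (common units).
#' @param q case-probability vector from \code{\link{q_fractions}}.
#'
#' @return occupancy probability in [0, 1].
#' @export
phi_mixture <- function(alpha, beta, q) {
  stopifnot(all(q >= -1e-12), abs(sum(q) - 1) < 1e-8)
  sum(vapply(seq_along(q), function(r) q[r] * phi_case(alpha, beta, r),
             numeric(1)))
}

#' Recover the potential initiation rate and landing-pad occupancy
#'
#' Inverts the steric-hindrance relationship: given an effective initiation
#' rate \eqn{\omega} and pause-escape rate \eqn{\beta}, finds \eqn{(\alpha,
#' \phi)} such that \eqn{\phi = \sum_r q'_r\phi_r(\alpha,\beta)} and
#' \eqn{\alpha = \omega/(1-\phi)}. With a single case (q = (1,0,...)) the
#' closed form is \eqn{\hat\phi = \omega/\beta}, \eqn{\hat\alpha =
#' \omega\beta/(\beta-\omega)}; otherwise the fixed point in \eqn{\phi} is
#' found numerically on (0, 1). In every case a solution exists only when
#' \eqn{\omega < \beta}; otherwise the gene is saturated (\eqn{\phi \to 1})
#' and \eqn{\alpha} cannot be estimated.
#'
#' @param omega effective initiation rate (> 0).
#' @param beta pause-escape rate (> 0), same units as omega.
#' @param q case-probability vector.
#' @param eps bracketing offset for the numerical solve.
#'
#' @return list with \code{alpha}, \code{phi}, \code{flags} (contains
#'   \code{"saturated"} with \code{phi = 1}, \code{alpha = NA} when no root
#'   exists in (0, 1)).
#' @export
solve_alpha_phi <- function(omega, beta, q = c(1, 0, 0), eps = 1e-9) {
  if (omega <= 0 || beta <= 0) stop("omega and beta must be positive")
  if (omega >= beta)
    return(list(alpha = NA_real_, phi = 1, flags = "saturated"))
  if (q[1] >= 1 - 1e-12) {
    phi <- omega / beta
    return(list(alpha = omega * beta / (beta - omega), phi = phi,
                flags = character(0)))
  }
  h <- function(phi) phi - phi_mixture(omega / (1 - phi), beta, q)
  lo <- eps; hi <- 1 - eps
  if (h(lo) >= 0) {
    # fixed point essentially at zero occupancy
    phi <- phi_mixture(omega, beta, q)
  } else {
    if (h(hi) <= 0)
      return(list(alpha = NA_real_, phi = 1, flags = "saturated"))
    phi <- uniroot(h, c(lo, hi), tol = eps)$root
  }
  list(alpha = omega / (1 - phi), phi = phi, flags = character(0))
}

#' Fit the steric-hindrance model by EM
#'
#' Identical to \code{\link{fit_variable_pause}} except that the M-step for
#' beta maximizes, numerically, the beta/phi-dependent portion of the
#' expected complete-data log-posterior
#' \deqn{-\langle t\rangle\log\beta - \chi/\beta + (a-1)\log\phi +
#'   (b-1)\log(1-\phi),}
#' subject to the steric constraint linking \eqn{\phi} to \eqn{\beta}
#' through \eqn{\phi = \sum_r q'_r \phi_r(\alpha, \beta)} and
#' \eqn{\omega = (1-\phi)\alpha}, with
#' \eqn{\omega\zeta = \chi\zeta/\lambda} fixed by the pre-estimated
#' \eqn{\chi}. The Beta(a, b) prior keeps \eqn{\phi} inside (0, 1) and
#' regularizes genes whose data carry little information about occupancy.
#' The case probabilities q are recomputed from the evolving pause-site pmf
#' at each iteration.
#'
#' @param profile a \code{\link{gene_profile}}.
#' @param chi pre-estimated chi (> 0).
#' @param cfg a \code{\link{steric_config}}.
#' @param k_min,k_max pause-site support bounds.
#' @param tol,max_iter convergence controls (penalized log-likelihood and
#'   relative beta change).
#' @param sigma2_floor variance floor (nt^2).
#'
#' @return a list of class \code{"steric_fit"}: \code{estimate} (with
#'   \code{omega_zeta}, \code{alpha_zeta}, \code{phi} populated),
#'   \code{dist}, \code{mixture} (list q, phi, phi_r), \code{loglik},
#'   \code{n_iter}, \code{converged}, \code{flags}. Genes with
#'   \eqn{\hat\phi \ge 0.95} are flagged \code{"saturated"} and their
#'   \code{alpha_zeta} reported as NA (poorly defined).
#' @export
fit_steric <- function(profile, chi, cfg = steric_config(), k_min = 1,
                       k_max = 200, tol = 1e-6, max_iter = 200,
                       sigma2_floor = 0.25) {
  stopifnot(inherits(profile, "gene_profile"), inherits(cfg, "steric_config"))
  if (chi <= 0) stop("chi must be positive")
  omega_zeta <- chi * cfg$zeta / cfg$lambda_scale    # events/min
  kk <- k_min:k_max
  X <- profile$pause_counts[kk]
  if (sum(X) == 0) {
    return(structure(list(estimate = NULL, dist = NULL, mixture = NULL,
                          loglik = NA_real_, n_iter = 0L, converged = FALSE,
                          flags = "no_fit"),
                     class = "steric_fit"))
  }
  mu <- kk[which.max(X)]
  sigma2 <- 25^2
  ip <- mean(X) / chi
  b0 <- beta_from_pausing_index(max(ip, 1 + 1e-12), length(kk))
  beta <- if (is.na(b0$beta) || !is.finite(b0$beta)) 1 else b0$beta
  dist <- truncated_gaussian_pmf(mu, sigma2, k_min, k_max)

  penalty <- function(beta_u, q) {
    sol <- solve_alpha_phi(omega_zeta, beta_u * cfg$zeta, q)
    phi <- min(max(sol$phi, 1e-12), 1 - 1e-12)
    (cfg$prior_a - 1) * log(phi) + (cfg$prior_b - 1) * log(1 - phi)
  }
  ll_old <- -Inf
  flags <- character(0)
  converged <- FALSE
  iter <- 0L
  q <- q_fractions(dist, cfg$s_p, cfg$R)
  for (iter in seq_len(max_iter)) {
    stats <- e_step(profile, chi, beta, dist)
    if (stats$t_exp <= 0) {
      flags <- union(flags, "no_pause_signal")
      break
    }
    # numerical M-step for beta on the log scale around the unpenalized EM
    # update chi/<t>
    beta_em <- chi / stats$t_exp
    obj <- function(lb) {
      b <- exp(lb)
      -stats$t_exp * log(b) - chi / b + penalty(b, q)
    }
    opt <- optimize(obj, c(log(beta_em) - log(100), log(beta_em) + log(100)),
                    maximum = TRUE, tol = 1e-10)
    beta_new <- exp(opt$maximum)
    upd <- m_step(stats, profile, chi, sigma2_floor)
    if (!is.na(upd$mu)) {
      safe <- .update_pause_dist(X, stats$Yk_exp, dist, upd$mu, upd$sigma2,
                                 k_min, k_max, sigma2_floor)
      mu <- safe$mu
      sigma2 <- safe$sigma2
      dist <- truncated_gaussian_pmf(mu, sigma2, k_min, k_max)
      q <- q_fractions(dist, cfg$s_p, cfg$R)
    }
    flags <- union(flags, setdiff(upd$flags, "no_pause_signal"))
    ll <- loglik_variable_pause(profile, chi, beta_new, dist) +
      penalty(beta_new, q)
    if (!is.finite(ll))
      return(structure(list(estimate = NULL, dist = dist, mixture = NULL,
                            loglik = ll, n_iter = iter, converged = FALSE,
                            flags = union(flags, "nonconvergent")),
                       class = "steric_fit"))
    dbeta <- abs(beta_new - beta) / beta
    beta <- beta_new
    if (abs(ll - ll_old) < tol && dbeta < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  sol <- solve_alpha_phi(omega_zeta, beta * cfg$zeta, q)
  flags <- union(flags, sol$flags)
  alpha_zeta <- sol$alpha
  if (sol$phi >= 0.95) {
    flags <- union(flags, "alpha_poorly_defined")
    alpha_zeta <- NA_real_
  }
  phi_r <- vapply(seq_along(q), function(r)
    if (is.na(sol$alpha)) NA_real_
    else phi_case(sol$alpha, beta * cfg$zeta, r), numeric(1))
  est <- new_rate_estimate(chi, beta, zeta = cfg$zeta,
                           lambda_scale = cfg$lambda_scale,
                           omega_zeta = omega_zeta, alpha_zeta = alpha_zeta,
                           phi = sol$phi, flags = flags,
                           method = "em_steric", mu = mu, sigma2 = sigma2)
  structure(list(estimate = est, dist = dist,
                 mixture = list(q = q, phi = sol$phi, phi_r = phi_r),
                 loglik = ll_old, n_iter = iter, converged = converged,
                 flags = flags),
            class = "steric_fit")
}

#' @export
print.steric_fit <- function(x, ...) {
  if (is.null(x$estimate)) {
    cat("<steric_fit> no fit [", paste(x$flags, collapse = ","), "]\n")
  } else {
    cat(sprintf("<steric_fit> beta*zeta = %.4g, omega*zeta = %.4g, phi = %.3f, alpha*zeta = %s\n",
                x$estimate$beta_zeta, x$estimate$omega_zeta, x$estimate$phi,
                if (is.na(x$estimate$alpha_zeta)) "poorly defined"
                else sprintf("%.4g", x$estimate$alpha_zeta)))
  }
  invisible(x)
}

#' Pause-region half-life
#'
#' Expected time, converted to a half-life, for an RNAP to traverse the
#' pause region and escape the pause:
#' \deqn{T_{1/2} = \log 2 \cdot \frac{\bar k - 1 + 1/\hat\beta}{\zeta},}
#' with \eqn{\bar k} the mean pause-site position (nt), \eqn{\hat\beta} the
#' unitless pause-escape rate, and \eqn{\zeta} in nt/min. The log 2 factor
#' converts the mean of an exponential waiting time to a half-life.
#'
#' @param beta unitless pause-escape rate estimate (> 0). Divide a
#'   \code{beta_zeta} (events/min) by \code{zeta} before calling.
#' @param k_bar mean pause-site position (nt).
#' @param zeta elongation rate (nt/min).
#'
#' @return half-life in minutes.
#' @export
half_life <- function(beta, k_bar = 50, zeta = 2000) {
  if (any(beta <= 0, na.rm = TRUE)) stop("beta must be positive")
  log(2) * (k_bar - 1 + 1 / beta) / zeta
}
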