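#' Discrete truncated-Gaussian pause-site distribution
#'
#' Probability mass function for the pause-site position k across cells,
#' proportional to \eqn{(1/\sigma)\exp(-(k-\mu)^2/(2\sigma^2))} on the
#' integers \code{k_min..k_max} and renormalized (the bounded, discrete
#' support makes the explicit normalizer necessary).
#'
#' @param mu mean pause position (nt).
#' @param sigma2 variance (nt^2), > 0.
#' @param k_min,k_max integer support bounds.
#'
#' @return an object of class \code{"pause_site_distribution"} with fields
#'   \code{mu}, \code{sigma2}, \code{k_min}, \code{k_max} and the pmf
#'   \code{f} (named by position).
#' @export
truncated_gaussian_pmf <- function(mu, sigma2, k_min = 1, k_max = 200) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (k_min > k_max) stop("empty support")
  k <- k_min:k_max
  # log-scale for numerical safety far from mu; 1/sigma cancels on renorm
  lf <- -0.5 * (k - mu)^2 / sigma2
  f <- exp(lf - max(lf))
  f <- f / sum(f)
  names(f) <- k
  structure(list(mu = mu, sigma2 = sigma2,
                 k_min = as.integer(k_min), k_max = as.integer(k_max), f = f),
            class = "pause_site_distribution")
}

#' @export
print.pause_site_distribution <- function(x, ...) {
  cat(sprintf("<pause_site_distribution> mu = %.2f, sd = %.2f nt, support %d..%d\n",
              x$mu, sqrt(x$sigma2), x$k_min, x$k_max))
  invisible(x)
}

pause_window_counts <- function(profile, dist) {
  n <- length(profile$pause_counts)
  if (dist$k_max > n)
    stop("profile pause region shorter than the pause-site support")
  profile$pause_counts[dist$k_min:dist$k_max]
}

#' E-step of the variable-pause-site EM
#'
#' Under the mixture model, the read count X_k in the pause window is a sum
#' of a pause-derived Poisson (rate \eqn{\chi/\beta \cdot f_k}) and a
#' passing-polymerase Poisson (rate \eqn{\chi(1 - f_k)}), so the
#' pause-derived portion Y_k given X_k is binomial with probability
#' \deqn{p_k = \frac{1}{1 - \beta + \beta/f_k} = \frac{f_k}{f_k + \beta(1 - f_k)}}
#' (and p_k = 0 where f_k = 0). Posterior expected sufficient statistics:
#' \eqn{\langle Y_k\rangle = X_k p_k}, \eqn{\langle t\rangle = \sum_k \langle
#' Y_k\rangle}, \eqn{\langle u\rangle = \sum_k \langle Y_k\rangle k},
#' \eqn{\langle v\rangle = \sum_k \langle Y_k\rangle k^2}, and the
#' f-weighted complements \eqn{\langle w\rangle, \langle z\rangle, \langle
#' r\rangle} with weights \eqn{f_k/(1-f_k)} applied to \eqn{X_k - \langle
#' Y_k\rangle}. The latter are computed through the exact identity
#' \eqn{f_k/(1-f_k)\,(X_k - \langle Y_k\rangle) = \beta\langle Y_k\rangle},
#' which is stable even when some \eqn{f_k \approx 1}.
#'
#' @param profile a \code{\link{gene_profile}}.
#' @param chi pre-estimated read-depth-scaled initiation rate (> 0).
#' @param beta current pause-escape rate (> 0).
#' @param dist a \code{\link{truncated_gaussian_pmf}} (or any
#'   \code{pause_site_distribution}).
#'
#' @return an object of class \code{"em_stats"} with fields \code{p},
#'   \code{Yk_exp}, \code{t_exp}, \code{u_exp}, \code{v_exp}, \code{w_exp},
#'   \code{z_exp}, \code{r_exp}.
#' @export
e_step <- function(profile, chi, beta, dist) {
  if (chi <= 0 || beta <= 0) stop("chi and beta must be positive")
  f <- dist$f
  k <- dist$k_min:dist$k_max
  X <- pause_window_counts(profile, dist)
  p <- ifelse(f == 0, 0, f / (f + beta * (1 - f)))
  Yk <- X * p
  t_exp <- sum(Yk)
  u_exp <- sum(Yk * k)
  v_exp <- sum(Yk * k^2)
  structure(list(p = p, Yk_exp = Yk, t_exp = t_exp, u_exp = u_exp,
                 v_exp = v_exp, w_exp = beta * t_exp, z_exp = beta * u_exp,
                 r_exp = beta * v_exp),
            class = "em_stats")
}

#' M-step of the variable-pause-site EM
#'
#' Given the expected sufficient statistics, the updates are
#' \deqn{\hat\beta = \hat\chi / \langle t\rangle, \qquad
#'   \hat\mu = \frac{\langle u\rangle - \langle z\rangle}
#'                  {\langle t\rangle - \langle w\rangle}, \qquad
#'   \hat\sigma^2 = \frac{\langle v\rangle - \langle r\rangle}
#'                       {\langle t\rangle - \langle w\rangle} - \hat\mu^2.}
#'
#' @param stats an \code{\link{e_step}} result.
#' @param profile the \code{\link{gene_profile}} being fitted (unused by the
#'   updates themselves; kept for interface symmetry).
#' @param chi pre-estimated chi.
#' @param sigma2_floor minimum variance (nt^2); estimates at or below zero
#'   are floored here, with a warning, to prevent point-mass collapse on
#'   spiky data.
#'
#' @return list with \code{beta}, \code{mu}, \code{sigma2}, \code{flags}.
#' @export
m_step <- function(stats, profile, chi, sigma2_floor = 0.25) {
  flags <- character(0)
  if (stats$t_exp <= 0) {
    flags <- c(flags, "no_pause_signal")
    return(list(beta = NA_real_, mu = NA_real_, sigma2 = NA_real_,
                flags = flags))
  }
  beta <- chi / stats$t_exp
  denom <- stats$t_exp - stats$w_exp
  if (denom <= 0) {
    # only reachable when beta >= 1 (no pause enrichment at all)
    flags <- c(flags, "no_pause_signal")
    return(list(beta = beta, mu = NA_real_, sigma2 = NA_real_, flags = flags))
  }
  mu <- (stats$u_exp - stats$z_exp) / denom
  sigma2 <- (stats$v_exp - stats$r_exp) / denom - mu^2
  if (sigma2 <= sigma2_floor) {
    if (sigma2 <= 0)
      warning("nonpositive variance update; floored at ", sigma2_floor, " nt^2")
    sigma2 <- sigma2_floor
    flags <- c(flags, "sigma2_floored")
  }
  list(beta = beta, mu = mu, sigma2 = sigma2, flags = flags)
}

#' Observed-data log-likelihood of the variable-pause-site model
#'
#' Evaluates the mixture log-likelihood. The inner convolution over the
#' latent pause-derived counts Y_k collapses, by the sum-of-two-Poissons
#' identity, to \eqn{X_k \sim \mathrm{Pois}(\chi/\beta\, f_k + \chi(1 -
#' f_k))}; positions outside the support contribute
#' \eqn{X_i \sim \mathrm{Pois}(\chi)}. Data-only constants
#' (\eqn{\log X_i!} terms, and the gene-body positional detail beyond its
#' total) are omitted, consistently across evaluations.
#'
#' @param profile a \code{\link{gene_profile}}.
#' @param chi,beta model parameters (> 0).
#' @param dist a \code{pause_site_distribution}.
#'
#' @return scalar log-likelihood up to a data-only constant.
#' @export
loglik_variable_pause <- function(profile, chi, beta, dist) {
  if (chi <= 0 || beta <= 0) stop("chi and beta must be positive")
  X <- pause_window_counts(profile, dist)
  mu_k <- chi / beta * dist$f + chi * (1 - dist$f)
  ll <- sum(X * log(mu_k) - mu_k)
  # pause-region positions outside the support are plain Poisson(chi)
  outside <- profile$pause_counts[-(dist$k_min:dist$k_max)]
  if (length(outside))
    ll <- ll + sum(outside * log(chi) - chi)
  ll + profile$gene_body_sum * log(chi) - profile$gene_body_len * chi
}

# expected complete-data contribution of the pause-site pmf:
# sum_k Yk log f_k + (X_k - Yk) log(1 - f_k), with 0 log 0 = 0
.q_f <- function(X, Yk, f) {
  t1 <- ifelse(Yk > 0, Yk * log(f), 0)
  t2 <- ifelse(X - Yk > 0, (X - Yk) * log1p(-f), 0)
  sum(t1 + t2)
}

# Ascent-guaranteed update of (mu, sigma2). The closed-form moment updates
# maximize the complete-data objective exactly for an unbounded continuous
# Gaussian; under truncation to a bounded integer support they are only
# approximate, so they are accepted only when they do not decrease the
# objective, and refined numerically otherwise. This keeps the EM
# log-likelihood monotone.
.update_pause_dist <- function(X, Yk, dist_old, mu_new, sigma2_new,
                               k_min, k_max, sigma2_floor) {
  qf <- function(mu, s2)
    .q_f(X, Yk, truncated_gaussian_pmf(mu, s2, k_min, k_max)$f)
  q_old <- qf(dist_old$mu, dist_old$sigma2)
  cand <- list(c(dist_old$mu, dist_old$sigma2))
  if (is.finite(mu_new) && is.finite(sigma2_new))
    cand <- c(cand, list(c(mu_new, max(sigma2_new, sigma2_floor))))
  vals <- vapply(cand, function(p) qf(p[1], p[2]), numeric(1))
  best <- cand[[which.max(vals)]]
  if (max(vals) < q_old + 1e-12 && length(cand) > 1) {
    # moment update failed to improve: refine numerically from current point
    opt <- stats::optim(c(dist_old$mu, log(dist_old$sigma2)),
                        function(p) -qf(p[1], max(exp(p[2]), sigma2_floor)),
                        method = "Nelder-Mead",
                        control = list(maxit = 200))
    ref <- c(opt$par[1], max(exp(opt$par[2]), sigma2_floor))
    if (-opt$value > max(vals)) best <- ref
  }
  list(mu = best[1], sigma2 = best[2])
}

#' Fit the variable-pause-site model by EM
#'
#' Alternates \code{\link{e_step}} and \code{\link{m_step}}, re-deriving the
#' truncated-Gaussian pmf from the updated \eqn{(\mu, \sigma^2)} each
#' iteration, until the observed-data log-likelihood changes by less than
#' \code{tol} and the relative change in beta falls below \code{tol}. The
#' read-depth-scaled initiation rate \eqn{\chi} is pre-estimated from the
#' gene body (see \code{\link{mle_gene_body}}) and held fixed. Because the
#' closed-form moment updates for \eqn{(\mu, \sigma^2)} are exact only for
#' an unbounded Gaussian, they are safeguarded: an update that would lower
#' the expected complete-data objective on the truncated integer support is
#' replaced by a numerically refined one, preserving EM monotonicity.
#'
#' Initialization: \eqn{\mu_0} at the highest count in the window,
#' \eqn{\sigma_0 = 25} nt, and \eqn{\beta_0} from the pausing-index
#' approximation (falling back to 1 when there are no excess pause reads).
#'
#' @param profile a \code{\link{gene_profile}}.
#' @param chi pre-estimated chi (> 0).
#' @param k_min,k_max pause-site support bounds.
#' @param tol convergence tolerance on the log-likelihood and on the
#'   relative change in beta.
#' @param max_iter maximum EM iterations.
#' @param zeta elongation rate (nt/min) for reporting \code{beta_zeta}.
#' @param sigma2_floor variance floor passed to \code{\link{m_step}}.
#' @param trace record the log-likelihood after every iteration (returned
#'   as \code{loglik_trace}).
#'
#' @return a list of class \code{"pause_fit"}: \code{estimate} (a
#'   \code{rate_estimate}), \code{dist} (fitted pmf), \code{loglik},
#'   \code{n_iter}, \code{converged}, \code{flags}.
#' @export
fit_variable_pause <- function(profile, chi, k_min = 1, k_max = 200,
                               tol = 1e-6, max_iter = 200, zeta = 2000,
                               sigma2_floor = 0.25, trace = FALSE) {
  stopifnot(inherits(profile, "gene_profile"))
  if (chi <= 0) stop("chi must be positive (pre-estimate it from the gene body)")
  kk <- k_min:k_max
  X <- profile$pause_counts[kk]
  if (sum(X) == 0) {
    return(structure(list(estimate = NULL, dist = NULL, loglik = NA_real_,
                          n_iter = 0L, converged = FALSE, flags = "no_fit"),
                     class = "pause_fit"))
  }
  mu <- kk[which.max(X)]
  sigma2 <- 25^2
  ip <- mean(X) / chi
  b0 <- beta_from_pausing_index(max(ip, 1 + 1e-12), length(kk))
  beta <- if (is.na(b0$beta) || !is.finite(b0$beta)) 1 else b0$beta
  dist <- truncated_gaussian_pmf(mu, sigma2, k_min, k_max)
  ll_old <- -Inf
  ll_trace <- if (trace) numeric(0) else NULL
  flags <- character(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    stats <- e_step(profile, chi, beta, dist)
    upd <- m_step(stats, profile, chi, sigma2_floor)
    if ("no_pause_signal" %in% upd$flags) {
      flags <- union(flags, upd$flags)
      break
    }
    beta_new <- upd$beta
    safe <- .update_pause_dist(X, stats$Yk_exp, dist, upd$mu, upd$sigma2,
                               k_min, k_max, sigma2_floor)
    dist <- truncated_gaussian_pmf(safe$mu, safe$sigma2, k_min, k_max)
    ll <- loglik_variable_pause(profile, chi, beta_new, dist)
    if (!is.finite(ll)) stop("non-finite log-likelihood at iteration ", iter,
                             " (beta = ", beta_new, ", mu = ", safe$mu, ")")
    if (trace) ll_trace <- c(ll_trace, ll)
    dbeta <- abs(beta_new - beta) / beta
    beta <- beta_new
    mu <- safe$mu; sigma2 <- safe$sigma2
    flags <- union(flags, upd$flags)
    if (abs(ll - ll_old) < tol && dbeta < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  # the likelihood has a known boundary mode at sigma2 -> 0 (a single sharp
  # pause site); EM can stall at an interior stationary point when stray
  # background reads inflate the variance, so the collapsed candidate is
  # evaluated explicitly and kept if it fits better
  cand_mu <- kk[which.max(X)]
  d2 <- truncated_gaussian_pmf(cand_mu, sigma2_floor, k_min, k_max)
  b2 <- if ("no_pause_signal" %in% flags) 0 else beta
  for (j in seq_len(if (b2 > 0) 25 else 0)) {
    st2 <- e_step(profile, chi, b2, d2)
    if (st2$t_exp <= 0) break
    b2_new <- chi / st2$t_exp
    if (abs(b2_new - b2) / b2 < tol) { b2 <- b2_new; break }
    b2 <- b2_new
  }
  ll2 <- if (b2 > 0) loglik_variable_pause(profile, chi, b2, d2) else -Inf
  if (is.finite(ll2) && ll2 > ll_old) {
    beta <- b2; mu <- cand_mu; sigma2 <- sigma2_floor; dist <- d2
    ll_old <- ll2
    flags <- union(flags, "sigma2_floored")
    if (trace) ll_trace <- c(ll_trace, ll2)
  }
  est <- new_rate_estimate(chi, beta, zeta = zeta, flags = flags,
                           method = "em_variable_pause",
                           mu = mu, sigma2 = sigma2)
  structure(list(estimate = est, dist = dist, loglik = ll_old,
                 loglik_trace = ll_trace, n_iter = iter,
                 converged = converged, flags = flags),
            class = "pause_fit")
}

#' @export
print.pause_fit <- function(x, ...) {
  if ("no_fit" %in% x$flags) {
    cat("<pause_fit> no fit (empty pause window)\n")
  } else {
    cat(sprintf("<pause_fit> beta = %.4g (beta*zeta = %.4g), mu = %.1f, sd = %.1f nt; %d iter%s\n",
                x$estimate$beta, x$estimate$beta_zeta, x$estimate$mu,
                sqrt(x$estimate$sigma2), x$n_iter,
                if (x$converged) "" else " (not converged)"))
  }
  invisible(x)
}
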