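#' Infinitesimal generator of the single-RNAP Markov chain
#'
#' Builds the (N+1) x (N+1) rate matrix of the continuous-time Markov chain
#' describing one RNAP on an N-nt template. States are 0..N, where state 0
#' represents free (unengaged) RNAP and state i >= 1 the nucleotide position
#' of the active site. The only allowed moves are 0 -> 1 at rate
#' \eqn{\alpha\zeta}, k -> k+1 at rate \eqn{\beta\zeta}, N -> 0 at rate
#' \eqn{\gamma\zeta}, and i -> i+1 at rate \eqn{\zeta} elsewhere; the
#' diagonal makes each row sum to zero.
#'
#' @param rates a \code{\link{transcription_rates}} object; \code{zeta} must
#'   be scalar here.
#' @param geom a \code{\link{template_geometry}} object; requires 1 < k < N.
#'
#' @return a dense numeric matrix with dimnames "0".."N".
#' @export
build_generator <- function(rates, geom) {
  stopifnot(inherits(rates, "transcription_rates"),
            inherits(geom, "template_geometry"))
  if (length(rates$zeta) != 1) stop("build_generator requires scalar zeta")
  N <- geom$N; k <- geom$k
  if (k <= 1 || k >= N) stop("pause site k must satisfy 1 < k < N")
  z <- rates$zeta
  Q <- matrix(0, N + 1, N + 1, dimnames = list(0:N, 0:N))
  for (i in 0:(N - 1)) {
    r <- if (i == 0) rates$alpha * z else if (i == k) rates$beta * z else z
    Q[i + 1, i + 2] <- r
  }
  Q[N + 1, 1] <- rates$gamma * z
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of RNAP position, conditional on occupancy
#'
#' Closed-form stationary distribution of the engaged states 1..N of the
#' single-RNAP chain, conditional on the RNAP being on the template. The
#' density is flat along the gene body and elevated by 1/beta at the pause
#' site and 1/gamma at the termination site:
#' \deqn{\pi_i \propto 1/\beta \ (i = k),\ 1/\gamma \ (i = N),\ 1
#'   \ \mathrm{otherwise}}
#' with normalizer \eqn{Z = N - 2 + 1/\beta + 1/\gamma}. It is invariant to
#' both \eqn{\alpha} and \eqn{\zeta}.
#'
#' @param beta pause-escape rate (> 0).
#' @param gamma termination rate (> 0).
#' @param geom a \code{\link{template_geometry}}.
#'
#' @return numeric vector of length N summing to 1.
#' @export
stationary_distribution <- function(beta, gamma = 1, geom) {
  stopifnot(inherits(geom, "template_geometry"))
  if (beta <= 0 || gamma <= 0)
    stop("beta and gamma must be positive (zero rates give infinite mass)")
  N <- geom$N; k <- geom$k
  pi <- rep(1, N)
  pi[k] <- 1 / beta
  pi[N] <- 1 / gamma
  pi / (N - 2 + 1 / beta + 1 / gamma)
}

#' Expected read depth along the template
#'
#' Expected 3'-end read count at each position under the Poisson generative
#' model: \eqn{\mu_i = \chi} away from the pause site and
#' \eqn{\mu_k = \chi/\beta} at it, where \eqn{\chi = \lambda\omega/\zeta} is
#' the read-depth-scaled initiation rate (gene-body reads/bp). The
#' termination peak is omitted (gamma is dropped from inference).
#'
#' @param chi read-depth-scaled initiation rate (>= 0, reads/bp).
#' @param beta pause-escape rate (> 0).
#' @param geom a \code{\link{template_geometry}}.
#'
#' @return numeric vector mu_1..mu_N.
#' @export
expected_read_depth <- function(chi, beta, geom) {
  stopifnot(inherits(geom, "template_geometry"))
  if (chi < 0) stop("chi must be nonnegative")
  if (beta <= 0) stop("beta must be positive")
  mu <- rep(chi, geom$N)
  mu[geom$k] <- chi / beta
  mu
}

#' Log-likelihood of read counts under the fixed-pause-site model
#'
#' Evaluates the steady-state Poisson log-likelihood for a single
#' transcription unit with a known pause site k:
#' \deqn{\ell = s\log\chi - X_k\log\beta - \chi(N + 1/\beta - 1),}
#' where s is the total read count. The data-only constant
#' \eqn{-\sum_i \log X_i!} is omitted; oracle comparisons against sums of
#' Poisson log-pmfs must add it back.
#'
#' @param x either a full per-nt count vector X_1..X_N, or a
#'   \code{\link{gene_profile}} (in which case \code{geom} supplies N and the
#'   total count is the pause-region sum plus the gene-body sum).
#' @param chi read-depth-scaled initiation rate (> 0).
#' @param beta pause-escape rate (> 0).
#' @param geom a \code{\link{template_geometry}}; for a plain count vector it
#'   may be omitted and N is taken as \code{length(x)} with k from \code{k}.
#' @param k pause-site position, used when \code{geom} is missing.
#'
#' @return scalar log-likelihood (up to the omitted constant).
#' @export
loglik_fixed_pause <- function(x, chi, beta, geom = NULL, k = NULL) {
  if (chi <= 0 || beta <= 0) stop("chi and beta must be positive")
  if (inherits(x, "gene_profile")) {
    stopifnot(inherits(geom, "template_geometry"))
    if (any(x$pause_counts < 0)) stop("negative counts")
    s <- sum(x$pause_counts) + x$gene_body_sum
    Xk <- x$pause_counts[geom$k]
    N <- geom$N
  } else {
    if (any(x < 0)) stop("negative counts")
    if (is.null(k)) k <- geom$k
    N <- if (is.null(geom)) length(x) else geom$N
    s <- sum(x)
    Xk <- x[k]
  }
  s * log(chi) - Xk * log(beta) - chi * (N + 1 / beta - 1)
}
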