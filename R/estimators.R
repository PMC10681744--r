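#' Closed-form MLEs for chi and beta with a fixed, known pause site
#'
#' Maximum-likelihood estimators under the fixed-pause-site Poisson model:
#' \deqn{\hat\chi = (s - X_k)/(N - 1), \qquad
#'       \hat\beta = (s - X_k) / (X_k (N - 1)),}
#' i.e. the average read depth excluding the pause site, and its ratio to
#' the pause-site count. The inverse of \eqn{\hat\beta} is the classical
#' pausing index.
#'
#' @param x a full per-nt count vector X_1..X_N, or a
#'   \code{\link{gene_profile}} (N and k then come from \code{geom}).
#' @param geom a \code{\link{template_geometry}} (required for profiles).
#' @param k pause-site position when \code{x} is a plain vector and
#'   \code{geom} is missing.
#' @param zeta elongation rate (nt/min) used to report \code{beta_zeta}.
#'
#' @return a \code{"rate_estimate"}. When X_k = 0 the beta estimate is
#'   infinite and flagged \code{"no_pause_reads"}; when s = X_k, chi is 0
#'   and flagged \code{"no_body_reads"}.
#' @export
mle_fixed_pause <- function(x, geom = NULL, k = NULL, zeta = 2000) {
  if (inherits(x, "gene_profile")) {
    stopifnot(inherits(geom, "template_geometry"))
    s <- sum(x$pause_counts) + x$gene_body_sum
    N <- geom$N
    Xk <- x$pause_counts[geom$k]
  } else {
    if (is.null(k)) k <- geom$k
    N <- if (is.null(geom)) length(x) else geom$N
    s <- sum(x)
    Xk <- x[k]
  }
  if (N < 2) stop("need N >= 2")
  flags <- character(0)
  chi <- (s - Xk) / (N - 1)
  if (Xk == 0) {
    beta <- Inf
    flags <- c(flags, "no_pause_reads")
  } else beta <- (s - Xk) / (Xk * (N - 1))
  if (s == Xk) {
    flags <- c(flags, "no_body_reads")
    warning("all reads at the pause site: chi estimated as 0")
  }
  new_rate_estimate(chi, beta, zeta = zeta, flags = flags, method = "fixed_pause")
}

#' Gene-body MLEs for chi and beta
#'
#' The preferred, more robust estimators that avoid the complex signal of
#' the pause region: with \eqn{s'} the read count over a gene-body interval
#' of length M,
#' \deqn{\hat\chi = s'/M, \qquad \hat\beta = s'/(X_k M).}
#'
#' @param profile a \code{\link{gene_profile}}.
#' @param k pause-site position at which X_k is read (known or
#'   pre-estimated).
#' @param zeta elongation rate (nt/min) used to report \code{beta_zeta}.
#'
#' @return a \code{"rate_estimate"}; degenerate inputs are flagged rather
#'   than raising, so genome-scale tables survive sparse genes
#'   (\code{"no_pause_reads"} with infinite beta when X_k = 0;
#'   \code{"no_body_reads"} with chi = beta = 0 when s' = 0).
#' @export
mle_gene_body <- function(profile, k, zeta = 2000) {
  stopifnot(inherits(profile, "gene_profile"))
  M <- profile$gene_body_len
  if (M == 0) stop("gene-body length is zero")
  s2 <- profile$gene_body_sum
  Xk <- profile$pause_counts[k]
  flags <- character(0)
  chi <- s2 / M
  if (s2 == 0) {
    flags <- c(flags, "no_body_reads")
    beta <- 0
  } else if (Xk == 0) {
    flags <- c(flags, "no_pause_reads")
    beta <- Inf
  } else beta <- s2 / (Xk * M)
  new_rate_estimate(chi, beta, zeta = zeta, flags = flags, method = "gene_body")
}

#' Pausing index
#'
#' Ratio of the mean read depth in the pause region to the mean gene-body
#' depth, \eqn{I_P = \hat\chi_P/\hat\chi}. Under the fixed-pause-site model
#' this is the inverse of \eqn{\hat\beta}; with variable pause sites it only
#' has an approximate relationship to the pause-escape rate (see
#' \code{\link{beta_from_pausing_index}}).
#'
#' @param profile a \code{\link{gene_profile}}.
#' @param pause_interval integer range (default the whole stored pause
#'   region) over which the pause-region mean is taken.
#'
#' @return scalar I_P.
#' @export
pausing_index <- function(profile, pause_interval = NULL) {
  stopifnot(inherits(profile, "gene_profile"))
  if (is.null(pause_interval))
    pause_interval <- seq_along(profile$pause_counts)
  if (profile$gene_body_sum == 0) stop("zero gene-body depth")
  chi_p <- mean(profile$pause_counts[pause_interval])
  chi <- profile$gene_body_sum / profile$gene_body_len
  chi_p / chi
}

#' Approximate beta from the pausing index
#'
#' Closed-form approximation linking the pausing index to the pause-escape
#' rate when the pause site varies across cells: the excess reads in a pause
#' region of length L are roughly \eqn{t \approx L\hat\chi(I_P - 1)}, giving
#' \deqn{\hat\beta \approx 1 / (L (I_P - 1)).}
#' This clarifies why a naive pausing-index-based estimate of the escape
#' rate is off by roughly a factor of L.
#'
#' @param I_P pausing index (> 1 for a meaningful estimate).
#' @param L pause-region length, \code{k_max - k_min + 1}.
#'
#' @return a list with \code{beta} and \code{flags} (flag
#'   \code{"no_excess_pause_reads"} and beta = NA when I_P <= 1).
#' @export
beta_from_pausing_index <- function(I_P, L) {
  stopifnot(L >= 1)
  if (I_P <= 1)
    return(list(beta = NA_real_, flags = "no_excess_pause_reads"))
  list(beta = 1 / (L * (I_P - 1)), flags = character(0))
}
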