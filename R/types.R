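#' Transcription rate parameters
#'
#' Bundles the kinetic parameters of the polymerase movement model. All rates
#' except \code{zeta} are unitless multipliers of the elongation rate: the
#' physical initiation, pause-escape and termination rates are
#' \eqn{\alpha\zeta}, \eqn{\beta\zeta} and \eqn{\gamma\zeta} (events/min).
#'
#' @param alpha potential initiation rate (unitless, x zeta).
#' @param beta pause-escape rate (unitless, x zeta).
#' @param gamma termination rate (unitless, x zeta). Retained for completeness
#'   of the generator; excluded from all estimators.
#' @param zeta elongation rate in nt/min; a scalar or a per-position vector.
#' @param omega effective initiation rate after steric blocking (unitless,
#'   x zeta), or \code{NULL}. When \code{phi} is supplied, \code{omega} is
#'   derived as \code{(1 - phi) * alpha} if missing.
#' @param chi read-depth-scaled initiation rate \eqn{\chi = \lambda\omega/\zeta}
#'   (expected gene-body reads/bp), or \code{NULL}.
#' @param lambda_scale sequencing-depth scale \eqn{\lambda}, or \code{NULL}.
#' @param phi landing-pad occupancy probability in [0, 1], or \code{NULL}.
#'
#' @return an object of class \code{"transcription_rates"}.
#' @export
transcription_rates <- function(alpha, beta, gamma = 1, zeta = 2000,
                                omega = NULL, chi = NULL,
                                lambda_scale = NULL, phi = NULL) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(zeta))
  if (alpha < 0 || beta < 0 || gamma < 0 || any(zeta < 0))
    stop("rates must be nonnegative")
  if (!is.null(phi)) {
    if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
    if (is.null(omega)) omega <- (1 - phi) * alpha
    if (abs(omega - (1 - phi) * alpha) > 1e-10)
      stop("inconsistent omega: must equal (1 - phi) * alpha")
  }
  if (!is.null(omega) && omega > alpha + 1e-12)
    stop("omega must not exceed alpha")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, zeta = zeta,
                 omega = omega, chi = chi, lambda_scale = lambda_scale,
                 phi = phi),
            class = "transcription_rates")
}

#' Template geometry
#'
#' Coordinates are 1-based and inclusive along the transcription unit, with
#' position 1 at the TSS. \code{k} is the (fixed-model) pause-site position;
#' \code{k_min}/\code{k_max} bound the pause region; the gene-body interval
#' \code{[gene_body_start, gene_body_start + gene_body_len - 1]} is used to
#' estimate \eqn{\chi}.
#'
#' @param N template length in nt.
#' @param k pause-site position (nt).
#' @param k_min,k_max bounds of the pause region.
#' @param gene_body_start first position of the gene-body interval.
#' @param gene_body_len length M of the gene-body interval.
#'
#' @return an object of class \code{"template_geometry"}.
#' @export
template_geometry <- function(N, k = 50, k_min = 1, k_max = 200,
                              gene_body_start = k_max + 1,
                              gene_body_len = N - gene_body_start + 1) {
  stopifnot(N >= 3)
  if (!(k_min >= 1 && k_min <= k && k <= k_max))
    stop("need 1 <= k_min <= k <= k_max")
  if (k_max >= gene_body_start)
    stop("pause region must end before the gene body starts")
  if (gene_body_start + gene_body_len - 1 > N)
    stop("gene body extends past the template")
  structure(list(N = as.integer(N), k = as.integer(k),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 gene_body_start = as.integer(gene_body_start),
                 gene_body_len = as.integer(gene_body_len)),
            class = "template_geometry")
}

#' Per-gene read-count profile
#'
#' The observed data for one transcription unit: 3'-end read counts at each
#' position of the pause region (positions 1..\code{length(pause_counts)},
#' 5' to 3' from the refined TSS) plus a gene-body summary.
#'
#' @param gene_id gene identifier.
#' @param pause_counts integer vector of per-nt counts, X_1..X_kmax.
#' @param gene_body_sum total read count s' over the gene-body interval.
#' @param gene_body_len length M of the gene-body interval (bp).
#' @param total_sum optional total count s over the whole template.
#' @param strand "+" or "-".
#'
#' @return an object of class \code{"gene_profile"}.
#' @export
gene_profile <- function(gene_id, pause_counts, gene_body_sum, gene_body_len,
                         total_sum = NULL, strand = "+") {
  if (any(pause_counts < 0) || gene_body_sum < 0)
    stop("read counts must be nonnegative")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(total_sum) && total_sum < sum(pause_counts) + gene_body_sum - 1e-9)
    stop("total_sum smaller than its parts")
  structure(list(gene_id = as.character(gene_id),
                 pause_counts = as.numeric(pause_counts),
                 gene_body_sum = as.numeric(gene_body_sum),
                 gene_body_len = as.integer(gene_body_len),
                 total_sum = if (is.null(total_sum)) NULL else as.numeric(total_sum),
                 strand = strand),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("<gene_profile> %s (%s)  pause region: %d nt, %g reads; gene body: %g reads / %d bp\n",
              x$gene_id, x$strand, length(x$pause_counts),
              sum(x$pause_counts), x$gene_body_sum, x$gene_body_len))
  invisible(x)
}

#' @export
print.transcription_rates <- function(x, ...) {
  cat("<transcription_rates>\n")
  for (nm in names(x)) if (!is.null(x[[nm]]))
    cat(sprintf("  %-12s %s\n", nm, paste(signif(x[[nm]], 6), collapse = " ")))
  invisible(x)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> chi = %.4g, beta = %.4g", x$chi, x$beta))
  if (!is.null(x$beta_zeta)) cat(sprintf(" (beta*zeta = %.4g events/min)", x$beta_zeta))
  if (!is.null(x$flags) && length(x$flags)) cat("  [", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

new_rate_estimate <- function(chi, beta, zeta = NULL, lambda_scale = NULL,
                              omega_zeta = NULL, alpha_zeta = NULL, phi = NULL,
                              pausing_index = NULL, pause_region_len = NULL,
                              flags = character(0), ...) {
  out <- list(chi = chi, beta = beta,
              beta_zeta = if (is.null(zeta)) NULL else beta * zeta,
              zeta = zeta, lambda_scale = lambda_scale,
              omega_zeta = omega_zeta, alpha_zeta = alpha_zeta, phi = phi,
              pausing_index = pausing_index,
              pause_region_len = pause_region_len, flags = flags, ...)
  class(out) <- "rate_estimate"
  out
}
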