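#' Calibrate effective initiation rates against a reference point
#'
#' Estimates of the effective initiation rate from read depth are only
#' defined up to the unknown scale \eqn{\lambda/\zeta}. This workflow fixes
#' the scale using housekeeping genes: in "L" (low) mode the per-gene
#' \code{omega_zeta} values are multiplied by a single factor so that their
#' housekeeping median equals \code{target_median} (default 0.2
#' events/min); in "H" (high) mode the factor matches the housekeeping
#' median of a user-supplied reference table on the intersected gene set.
#' Treated samples are additionally rescaled by \code{treated_scale} (e.g.
#' a spike-in read ratio).
#'
#' @param fit_table data.frame with columns \code{gene_id} and
#'   \code{omega_zeta} (unscaled).
#' @param housekeeping_ids character vector of housekeeping gene ids.
#' @param mode "L" or "H".
#' @param target_median target housekeeping median (events/min), L mode.
#' @param reference_table data.frame gene_id, omega_zeta; required in H
#'   mode.
#' @param treated_scale extra multiplicative factor for treated samples.
#'
#' @return list with \code{table} (rescaled; extra column
#'   \code{omega_zeta_raw}) and \code{scale_factor}.
#' @export
calibrate_initiation <- function(fit_table, housekeeping_ids,
                                 mode = c("L", "H"), target_median = 0.2,
                                 reference_table = NULL, treated_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(fit_table),
            all(c("gene_id", "omega_zeta") %in% names(fit_table)),
            length(housekeeping_ids) > 0, target_median > 0)
  hk <- intersect(housekeeping_ids, fit_table$gene_id)
  if (length(hk) == 0) stop("no housekeeping genes found in the fit table")
  if (mode == "H") {
    if (is.null(reference_table))
      stop("H mode requires a reference table of omega*zeta values")
    hk <- intersect(hk, reference_table$gene_id)
    if (length(hk) == 0)
      stop("no housekeeping genes shared with the reference table")
    target_median <- median(
      reference_table$omega_zeta[match(hk, reference_table$gene_id)])
  }
  med <- median(fit_table$omega_zeta[match(hk, fit_table$gene_id)])
  if (med <= 0) stop("housekeeping median is not positive")
  fac <- target_median / med
  out <- fit_table
  out$omega_zeta_raw <- out$omega_zeta
  out$omega_zeta <- out$omega_zeta * fac * treated_scale
  list(table = out, scale_factor = fac)
}

#' Filter to robustly expressed genes across two conditions
#'
#' Keeps the genes falling in the top \code{quantile} fraction by chi in
#' both conditions (default the top 80 percent of each).
#'
#' @param table_a,table_b data.frames with columns \code{gene_id} and
#'   \code{chi}.
#' @param quantile fraction of each table to keep (0, 1].
#'
#' @return character vector of retained gene ids.
#' @export
expression_filter <- function(table_a, table_b, quantile = 0.8) {
  stopifnot(quantile > 0, quantile <= 1)
  top <- function(tab) {
    thr <- stats::quantile(tab$chi, 1 - quantile, type = 7)
    tab$gene_id[tab$chi >= thr]
  }
  intersect(top(table_a), top(table_b))
}

#' Per-gene pause half-life table
#'
#' Applies \code{\link{half_life}} to every gene of a fit table. Flagged or
#' nonpositive beta estimates propagate as missing half-lives.
#'
#' @param fit_table data.frame with \code{gene_id} and \code{beta_zeta}
#'   (events/min). If a per-gene \code{mu} column is present it is used as
#'   the mean pause position, otherwise \code{k_bar}.
#' @param k_bar default mean pause-site position (nt).
#' @param zeta elongation rate (nt/min).
#' @param verbose print the median and mean half-life.
#'
#' @return the table with a \code{half_life_min} column.
#' @export
halflife_table <- function(fit_table, k_bar = 50, zeta = 2000,
                           verbose = FALSE) {
  stopifnot(all(c("gene_id", "beta_zeta") %in% names(fit_table)))
  beta <- fit_table$beta_zeta / zeta
  kb <- if ("mu" %in% names(fit_table)) fit_table$mu else k_bar
  ok <- is.finite(beta) & beta > 0
  hl <- rep(NA_real_, nrow(fit_table))
  hl[ok] <- log(2) * ((if (length(kb) > 1) kb[ok] else kb) - 1 +
                        1 / beta[ok]) / zeta
  fit_table$half_life_min <- hl
  if (verbose)
    message(sprintf("half-life: median %.3g min, mean %.3g min (%d genes)",
                    median(hl, na.rm = TRUE), mean(hl, na.rm = TRUE),
                    sum(ok)))
  fit_table
}

#' Fit a table of gene profiles
#'
#' Convenience wrapper running one of the estimators over a profile list
#' and returning a tidy per-gene table.
#'
#' @param profiles named list of \code{\link{gene_profile}} objects.
#' @param method "gene-body" (closed form at a fixed pause site k),
#'   "naive" (full-template MLE; requires per-nt body counts, so it uses
#'   the stored pause region plus gene-body summary), or "em"
#'   (variable-pause-site EM).
#' @param k fixed pause-site position for the closed-form methods.
#' @param k_min,k_max EM support bounds.
#' @param zeta elongation rate (nt/min).
#' @param ... further arguments to \code{\link{fit_variable_pause}}.
#'
#' @return data.frame with one row per gene: gene_id, chi, beta, beta_zeta,
#'   mu, sigma2, loglik, n_iter, flags.
#' @export
fit_profiles <- function(profiles, method = c("gene-body", "naive", "em"),
                         k = 50, k_min = 1, k_max = 200, zeta = 2000, ...) {
  method <- match.arg(method)
  rows <- lapply(profiles, function(p) {
    chi <- p$gene_body_sum / p$gene_body_len
    if (method == "em") {
      if (chi <= 0 || sum(p$pause_counts[k_min:k_max]) == 0)
        return(data.frame(gene_id = p$gene_id, chi = chi, beta = NA,
                          beta_zeta = NA, mu = NA, sigma2 = NA, loglik = NA,
                          n_iter = 0L, flags = "no_fit",
                          stringsAsFactors = FALSE))
      ft <- fit_variable_pause(p, chi, k_min, k_max, zeta = zeta, ...)
      if ("no_fit" %in% ft$flags || is.null(ft$estimate))
        return(data.frame(gene_id = p$gene_id, chi = chi, beta = NA,
                          beta_zeta = NA, mu = NA, sigma2 = NA, loglik = NA,
                          n_iter = ft$n_iter,
                          flags = paste(ft$flags, collapse = ";"),
                          stringsAsFactors = FALSE))
      e <- ft$estimate
      data.frame(gene_id = p$gene_id, chi = e$chi, beta = e$beta,
                 beta_zeta = e$beta_zeta, mu = e$mu, sigma2 = e$sigma2,
                 loglik = ft$loglik, n_iter = ft$n_iter,
                 flags = paste(ft$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    } else {
      e <- if (method == "gene-body") {
        mle_gene_body(p, k, zeta = zeta)
      } else {
        P <- length(p$pause_counts)
        geom <- template_geometry(P + p$gene_body_len, k = k, k_max = P)
        mle_fixed_pause(p, geom = geom, zeta = zeta)
      }
      data.frame(gene_id = p$gene_id, chi = e$chi, beta = e$beta,
                 beta_zeta = e$beta_zeta, mu = NA, sigma2 = NA, loglik = NA,
                 n_iter = 0L, flags = paste(e$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
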