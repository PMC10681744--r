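#' Fixture specification for synthetic gene profiles
#'
#' Describes a set of synthetic genes drawn directly from the generative
#' read-count model (no polymerase-traffic simulation): per-gene chi and
#' beta are sampled log-uniformly from the given ranges, and pause-region
#' counts follow the Poisson mixture with mean
#' \eqn{\chi/\beta\, f_k + \chi(1-f_k)} under a truncated-Gaussian
#' pause-site distribution (or a point mass in fixed mode).
#'
#' @param n_genes number of genes.
#' @param chi_range,beta_range two-element ranges sampled log-uniformly.
#' @param pause_mode "variable" or "fixed".
#' @param mu_range,sigma_range ranges for the pause-site mean and sd (nt);
#'   in fixed mode only \code{mu_range} is used (rounded to integers).
#' @param k_min,k_max pause-site support / stored pause-region bounds.
#' @param gene_body_len gene-body length M (bp).
#' @param seed RNG seed.
#'
#' @return an object of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(n_genes = 20, chi_range = c(0.02, 0.2),
                         beta_range = c(2e-4, 2e-2),
                         pause_mode = c("variable", "fixed"),
                         mu_range = c(30, 80), sigma_range = c(10, 40),
                         k_min = 1, k_max = 200, gene_body_len = 19800,
                         seed = 1) {
  pause_mode <- match.arg(pause_mode)
  stopifnot(all(chi_range > 0), all(beta_range > 0), all(sigma_range > 0),
            n_genes >= 1)
  structure(list(n_genes = as.integer(n_genes), chi_range = chi_range,
                 beta_range = beta_range, pause_mode = pause_mode,
                 mu_range = mu_range, sigma_range = sigma_range,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 gene_body_len = as.integer(gene_body_len),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Generate synthetic gene profiles with known truth
#'
#' Draws profiles from the generative model described in
#' \code{\link{fixture_spec}}. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#'
#' @return list with \code{profiles} (named list of
#'   \code{\link{gene_profile}}) and \code{truth} (data.frame gene_id, chi,
#'   beta, mu, sigma2).
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  chi <- runif_log(n, spec$chi_range)
  beta <- runif_log(n, spec$beta_range)
  mu <- runif(n, spec$mu_range[1], spec$mu_range[2])
  sigma <- runif(n, spec$sigma_range[1], spec$sigma_range[2])
  profiles <- vector("list", n)
  ids <- sprintf("gene%03d", seq_len(n))
  for (i in seq_len(n)) {
    if (spec$pause_mode == "fixed") {
      mu[i] <- round(mu[i])
      f <- numeric(spec$k_max - spec$k_min + 1)
      f[mu[i] - spec$k_min + 1] <- 1
      sigma[i] <- 0
    } else {
      f <- truncated_gaussian_pmf(mu[i], sigma[i]^2, spec$k_min,
                                  spec$k_max)$f
    }
    lam <- chi[i] / beta[i] * f + chi[i] * (1 - f)
    X <- numeric(spec$k_max)
    X[spec$k_min:spec$k_max] <- rpois(length(lam), lam)
    if (spec$k_min > 1)
      X[seq_len(spec$k_min - 1)] <- rpois(spec$k_min - 1, chi[i])
    gb <- rpois(1, chi[i] * spec$gene_body_len)
    profiles[[i]] <- gene_profile(ids[i], X, gb, spec$gene_body_len)
  }
  names(profiles) <- ids
  list(profiles = profiles,
       truth = data.frame(gene_id = ids, chi = chi, beta = beta, mu = mu,
                          sigma2 = sigma^2, stringsAsFactors = FALSE))
}

#' Write a miniature genome-track bundle for I/O testing
#'
#' Lays the spec's synthetic genes head-to-tail (alternating strands) on a
#' toy chromosome and writes plus/minus bedGraph coverage, a BED6 gene
#' annotation, and a cap bedGraph with a single spike at each TSS, such
#' that profiling the bundle through \code{\link{build_gene_profiles}}
#' recovers the source profiles exactly. Gene-body counts are distributed
#' deterministically (round-robin) over the body interval so the body sum
#' is preserved.
#'
#' @param spec a \code{\link{fixture_spec}}; \code{gene_body_len} should be
#'   modest (a few kb) to keep the bundle small.
#' @param dir output directory (created if needed).
#' @param gb_offset gap between pause region and gene body, matching the
#'   profiling default.
#'
#' @return invisibly, a list of the four file paths plus the source
#'   profiles.
#' @export
generate_track_bundle <- function(spec, dir, gb_offset = 1250) {
  gen <- generate_profiles(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  P <- spec$k_max
  glen <- gb_offset + spec$gene_body_len          # TSS..body end, bp
  gap <- 2000                                      # intergenic spacer
  chrom <- "chrS"
  plus <- list(); minus <- list(); cap <- list(); bed <- list()
  cursor <- gap
  for (i in seq_along(gen$profiles)) {
    p <- gen$profiles[[i]]
    st <- if (i %% 2 == 1) "+" else "-"
    p$strand <- st
    gen$profiles[[i]] <- p
    # body counts: integer vector of length M summing to gb_sum
    M <- spec$gene_body_len
    base <- p$gene_body_sum %/% M
    extra <- p$gene_body_sum %% M
    body <- rep(base, M)
    if (extra > 0) body[seq_len(extra)] <- body[seq_len(extra)] + 1
    if (st == "+") {
      tss <- cursor + 1
      pause_pos <- tss:(tss + P - 1)
      body_pos <- (tss + gb_offset):(tss + gb_offset + M - 1)
      gstart <- tss; gend <- tss + glen - 1
      pc <- p$pause_counts; bc <- body
    } else {
      tss <- cursor + glen
      pause_pos <- (tss - P + 1):tss
      body_pos <- (tss - gb_offset - M + 1):(tss - gb_offset)
      gstart <- cursor + 1; gend <- tss
      pc <- rev(p$pause_counts); bc <- rev(body)
    }
    tgt <- if (st == "+") "plus" else "minus"
    rows <- data.frame(pos = c(pause_pos, body_pos), val = c(pc, bc))
    rows <- rows[rows$val > 0, , drop = FALSE]
    if (nrow(rows)) {
      df <- data.frame(chrom = chrom, start = rows$pos - 1L, end = rows$pos,
                       value = rows$val)
      if (st == "+") plus[[length(plus) + 1L]] <- df
      else minus[[length(minus) + 1L]] <- df
    }
    cap[[length(cap) + 1L]] <- data.frame(chrom = chrom, start = tss - 1L,
                                          end = tss, value = 5)
    bed[[length(bed) + 1L]] <- data.frame(chrom = chrom, start = gstart - 1L,
                                          end = gend, name = p$gene_id,
                                          score = 0, strand = st)
    cursor <- gend + gap
  }
  paths <- list(plus = file.path(dir, "signal_plus.bedGraph"),
                minus = file.path(dir, "signal_minus.bedGraph"),
                cap = file.path(dir, "cap.bedGraph"),
                genes = file.path(dir, "genes.bed"))
  wbg <- function(rows, path) {
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(chrom = chrom, start = 0L, end = 1L, value = 0)
    write.table(tab[order(tab$start), ], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  wbg(plus, paths$plus)
  wbg(minus, paths$minus)
  wbg(cap, paths$cap)
  write.table(do.call(rbind, bed), paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(paths, list(profiles = gen$profiles, truth = gen$truth)))
}
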