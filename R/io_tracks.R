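#' Load strand-specific 3'-end coverage tracks
#'
#' Reads a plus-strand and a minus-strand coverage track (bigWig or
#' bedGraph, chosen by file extension) into per-base run-length-encoded
#' coverage. Tracks follow the 0-based half-open bigWig/bedGraph
#' convention on disk; queries use 1-based inclusive genomic coordinates.
#'
#' @param plus_track,minus_track paths to the two strand tracks.
#'
#' @return an object of class \code{"coverage_signal"} holding one
#'   \code{RleList} per strand.
#' @export
load_signal <- function(plus_track, minus_track) {
  structure(list(plus = .track_coverage(plus_track),
                 minus = .track_coverage(minus_track)),
            class = "coverage_signal")
}

.track_coverage <- function(path) {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "BigWig"
         else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (any(gr$score < 0, na.rm = TRUE))
    stop("coverage values must be nonnegative counts: ", path)
  GenomicRanges::coverage(gr, weight = "score")
}

#' Per-base signal query, oriented 5' to 3'
#'
#' Returns the per-base counts over \code{[start, end]} (1-based,
#' inclusive) on the requested strand. Minus-strand queries are reversed so
#' that the first element is the gene's 5'-most base. Chromosomes absent
#' from a track are zero-filled with a warning.
#'
#' @param signal a \code{\link{load_signal}} result.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic interval.
#' @param strand "+" or "-".
#'
#' @return numeric vector of length \code{end - start + 1}.
#' @export
query_signal <- function(signal, chrom, start, end, strand = "+") {
  stopifnot(inherits(signal, "coverage_signal"), start >= 1, end >= start)
  cov <- if (strand == "+") signal$plus else signal$minus
  if (!chrom %in% names(cov)) {
    warning("chromosome ", chrom, " absent from track; zero-filled")
    v <- numeric(end - start + 1)
  } else {
    rle <- cov[[chrom]]
    n <- length(rle)
    v <- numeric(end - start + 1)
    if (start <= n) {
      hi <- min(end, n)
      v[seq_len(hi - start + 1)] <- as.numeric(S4Vectors::window(rle, start, hi))
    }
  }
  if (strand == "-") rev(v) else v
}

#' Read gene annotations
#'
#' Reads BED6 (simple path) or Ensembl-dialect GTF gene annotations into a
#' gene table. For GTF, only \code{gene}-level records with
#' \code{gene_biotype "protein_coding"} are retained. Genomic coordinates
#' are 1-based inclusive; \code{tss} is the strand-aware 5' end and
#' \code{gene_end} the 3' end.
#'
#' @param path annotation file.
#' @param format "bed" or "gtf" (guessed from the extension by default).
#'
#' @return data.frame with columns gene_id, chrom, strand, start, end, tss,
#'   gene_end.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    keep <- gr$type == "gene"
    if (!is.null(gr$gene_biotype))
      keep <- keep & gr$gene_biotype %in% "protein_coding"
    gr <- gr[keep]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  }
  st <- as.character(GenomicRanges::strand(gr))
  if (any(!st %in% c("+", "-")))
    stop("all genes must be stranded (+/-)")
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = st, start = s, end = e,
             tss = ifelse(st == "+", s, e),
             gene_end = ifelse(st == "+", e, s),
             stringsAsFactors = FALSE)
}

#' Refine TSS positions with a cap-selected 5' signal
#'
#' Moves each annotated TSS to the position with the highest cap signal
#' (e.g. CoPRO-cap) within \code{radius} bp, searching a symmetric genomic
#' window. Genes with no cap signal in the window are flagged as dropped.
#' Ties are broken toward the annotated TSS (then toward the genomically
#' leftmost candidate, deterministically).
#'
#' @param genes gene table from \code{\link{read_genes}}.
#' @param cap_signal a \code{\link{load_signal}} result for the cap track.
#' @param radius search radius in bp.
#'
#' @return the gene table with columns \code{refined_tss} (NA when no
#'   signal) and \code{tss_dropped}.
#' @export
refine_tss <- function(genes, cap_signal, radius = 250) {
  refined <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    lo <- max(1, genes$tss[i] - radius)
    hi <- genes$tss[i] + radius
    v <- query_signal(cap_signal, genes$chrom[i], lo, hi, genes$strand[i])
    if (genes$strand[i] == "-") v <- rev(v)   # back to genomic order
    if (all(v == 0)) next
    pos <- (lo:hi)[v == max(v)]
    pos <- pos[order(abs(pos - genes$tss[i]), pos)][1]
    refined[i] <- pos
  }
  genes$refined_tss <- refined
  genes$tss_dropped <- is.na(refined)
  genes
}

#' Build per-gene read-count profiles from coverage tracks
#'
#' For each gene, extracts the pause region (\code{pause_len} bp starting
#' at the refined TSS, 5' to 3') and the gene-body interval (from
#' \code{gb_offset} bp downstream of the refined TSS to at most
#' \code{gb_cap} bp downstream, clipped at the annotated gene end). Genes
#' are excluded if they overlap another gene on the same strand, were
#' dropped during TSS refinement, have an empty gene body after clipping,
#' or have fewer than \code{min_reads} reads in either the pause region or
#' the gene body.
#'
#' @param genes gene table (from \code{\link{read_genes}}, optionally after
#'   \code{\link{refine_tss}}; without refinement the annotated TSS is
#'   used).
#' @param signal a \code{\link{load_signal}} result.
#' @param pause_len pause-region length (bp).
#' @param gb_offset distance from the refined TSS to the gene-body start.
#' @param gb_cap maximum extent of the gene body downstream of the TSS.
#' @param min_reads minimum reads required in each region.
#'
#' @return list with \code{profiles} (list of \code{\link{gene_profile}})
#'   and \code{dropped} (data.frame gene_id, reason).
#' @export
build_gene_profiles <- function(genes, signal, pause_len = 200,
                                gb_offset = 1250, gb_cap = 90000,
                                min_reads = 20) {
  stopifnot(inherits(signal, "coverage_signal"))
  if (is.null(genes$refined_tss)) {
    genes$refined_tss <- genes$tss
    genes$tss_dropped <- FALSE
  }
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  ov <- GenomicRanges::countOverlaps(gr, gr)   # strand-aware by default
  profiles <- list()
  dropped <- list()
  drop <- function(id, reason) dropped[[length(dropped) + 1L]] <<-
    data.frame(gene_id = id, reason = reason, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    id <- genes$gene_id[i]
    if (ov[i] > 1) { drop(id, "same_strand_overlap"); next }
    if (genes$tss_dropped[i]) { drop(id, "no_cap_signal"); next }
    tss <- genes$refined_tss[i]
    st <- genes$strand[i]
    if (st == "+") {
      p_lo <- tss; p_hi <- tss + pause_len - 1
      b_lo <- tss + gb_offset
      b_hi <- min(tss + gb_cap - 1, genes$gene_end[i])
    } else {
      p_hi <- tss; p_lo <- tss - pause_len + 1
      b_hi <- tss - gb_offset
      b_lo <- max(tss - gb_cap + 1, genes$gene_end[i])
    }
    if (b_hi < b_lo || p_lo < 1) { drop(id, "gene_body_too_short"); next }
    pause <- query_signal(signal, genes$chrom[i], p_lo, p_hi, st)
    body <- query_signal(signal, genes$chrom[i], b_lo, b_hi, st)
    if (sum(pause) < min_reads) { drop(id, "low_pause_reads"); next }
    if (sum(body) < min_reads) { drop(id, "low_body_reads"); next }
    profiles[[id]] <- gene_profile(id, pause, sum(body), length(body),
                                   strand = st)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(gene_id = character(0), reason = character(0))
  list(profiles = profiles, dropped = dropped)
}

#' Write gene profiles to a TSV table
#'
#' One row per gene: \code{gene_id}, \code{strand}, per-nt pause-region
#' counts \code{X_1..X_P}, \code{gb_sum}, \code{gb_len}. Lossless
#' round-trip with \code{\link{read_profiles}}.
#'
#' @param profiles list of \code{\link{gene_profile}} objects with equal
#'   pause-region lengths.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  if (length(profiles) == 0) {
    hdr <- c("gene_id", "strand", paste0("X_", 1:200), "gb_sum", "gb_len")
    writeLines(paste(hdr, collapse = "\t"), path)
    return(invisible(path))
  }
  P <- unique(vapply(profiles, function(p) length(p$pause_counts), 1L))
  if (length(P) != 1) stop("profiles have differing pause-region lengths")
  rows <- lapply(profiles, function(p)
    data.frame(gene_id = p$gene_id, strand = p$strand,
               t(p$pause_counts), gb_sum = p$gene_body_sum,
               gb_len = p$gene_body_len, stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  names(tab)[3:(2 + P)] <- paste0("X_", seq_len(P))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene profiles from a TSV table
#'
#' @param path a file written by \code{\link{write_profiles}}.
#' @return named list of \code{\link{gene_profile}} objects.
#' @export
read_profiles <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "strand", "gb_sum", "gb_len")
  if (!all(need %in% names(tab)))
    stop("malformed profile table: missing ", paste(setdiff(need, names(tab)),
                                                    collapse = ", "))
  xcols <- grep("^X_[0-9]+$", names(tab), value = TRUE)
  xcols <- xcols[order(as.integer(sub("X_", "", xcols)))]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    x <- as.numeric(tab[i, xcols])
    if (any(is.na(x)) || is.na(tab$gb_sum[i]) || is.na(tab$gb_len[i]))
      stop("malformed profile row at line ", i + 1L, " of ", path)
    out[[tab$gene_id[i]]] <- gene_profile(tab$gene_id[i], x, tab$gb_sum[i],
                                          tab$gb_len[i],
                                          strand = tab$strand[i])
  }
  out
}
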