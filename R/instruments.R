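#' Define a gene locus
#'
#' @param gene_symbol gene name.
#' @param chrom chromosome label.
#' @param start,end 1-based base-pair bounds, start <= end.
#' @return object of class \code{gene_locus} with \code{center}, the
#'   midpoint \code{floor((start + end) / 2)}. The cis window is measured
#'   from this center (the blood-eQTL convention); pass \code{start} as both
#'   bounds for a TSS-based window.
#' @export
gene_locus <- function(gene_symbol, chrom, start, end) {
  stopifnot(start <= end, start > 0)
  out <- list(gene_symbol = gene_symbol, chrom = as.character(chrom),
              start = start, end = end,
              center = floor((start + end) / 2))
  class(out) <- "gene_locus"
  out
}

# canonical candidate ordering: ascending P, then descending |z|, then id
.order_candidates <- function(df) {
  df[order(df$pval, -abs(df$beta / df$se), df$snp_id), , drop = FALSE]
}

#' Select cis eQTL candidates for a gene
#'
#' Keeps SNPs within \code{window_bp} of the gene center (closed interval:
#' a SNP exactly at the window edge is included) whose association P-value
#' is strictly below \code{p_threshold}, sorted by ascending P-value.
#'
#' @param eqtl quantitative \code{summary_table} of eQTL statistics.
#' @param locus a \code{gene_locus}.
#' @param window_bp cis window half-width in bp (default 1 Mb).
#' @param p_threshold genome-wide significance threshold (default 5e-8,
#'   strict inequality).
#' @return data.frame of candidate records (possibly zero rows: a gene with
#'   no candidate has no instrument and is skipped, not an error).
#' @export
select_cis_candidates <- function(eqtl, locus, window_bp = 1e6,
                                  p_threshold = 5e-8) {
  stopifnot(inherits(eqtl, "summary_table"), inherits(locus, "gene_locus"))
  if (eqtl$trait_type != "quantitative") {
    stop("instrument selection requires a quantitative (eQTL) table")
  }
  rec <- eqtl$records
  keep <- rec$chrom == locus$chrom &
    abs(rec$pos - locus$center) <= window_bp &
    rec$pval < p_threshold
  .order_candidates(rec[keep, , drop = FALSE])
}

#' Pick the top eQTL (smallest P-value)
#'
#' Ties on P are broken by larger |beta/se|, then lexicographic SNP id.
#'
#' @param candidates data.frame from \code{\link{select_cis_candidates}}.
#' @return single-row data.frame.
#' @export
top_eqtl <- function(candidates) {
  if (nrow(candidates) == 0L) stop("no instrument: candidate list is empty")
  .order_candidates(candidates)[1, , drop = FALSE]
}

#' Pairwise squared-correlation (LD) matrix from a reference panel
#'
#' @param panel a \code{reference_panel}.
#' @param snp_ids SNP ids, all present in the panel.
#' @return symmetric matrix of r-squared values with unit diagonal,
#'   dimnames = snp_ids.
#' @export
ld_matrix <- function(panel, snp_ids) {
  stopifnot(inherits(panel, "reference_panel"))
  missing <- setdiff(snp_ids, colnames(panel$dosages))
  if (length(missing)) {
    stop("SNP id(s) absent from panel: ", paste(missing, collapse = ", "))
  }
  r <- stats::cor(panel$dosages[, snp_ids, drop = FALSE])
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Greedy LD clumping of eQTL candidates
#'
#' Accept the best (smallest-P) remaining SNP, discard every remaining SNP
#' with r-squared above \code{r2_max} to any accepted SNP, and repeat. The
#' retained set has all pairwise r-squared at or below the threshold.
#'
#' @param candidates data.frame sorted by ascending P-value (re-sorted
#'   defensively with the canonical tie-break).
#' @param ld r-squared matrix covering all candidates (see
#'   \code{\link{ld_matrix}}).
#' @param r2_max clumping threshold (default 0.01).
#' @param locus optional \code{gene_locus} attached to the result.
#' @param n sample size used for per-SNP strength; defaults to each
#'   record's own \code{n}.
#' @return object of class \code{instrument} with \code{snps} (retained
#'   records), \code{per_snp_r2}, \code{per_snp_f}, \code{mode}
#'   ("multi_snp"), \code{gene}.
#' @export
clump <- function(candidates, ld, r2_max = 0.01, locus = NULL, n = NULL) {
  if (nrow(candidates) == 0L) stop("no instrument: candidate list is empty")
  cand <- .order_candidates(candidates)
  if (!all(cand$snp_id %in% rownames(ld))) {
    stop("LD matrix does not cover all candidates")
  }
  remaining <- cand$snp_id
  accepted <- character(0)
  while (length(remaining)) {
    keep <- remaining[1]
    accepted <- c(accepted, keep)
    remaining <- remaining[-1]
    if (length(remaining)) {
      remaining <- remaining[ld[remaining, keep] <= r2_max]
    }
  }
  snps <- cand[match(accepted, cand$snp_id), , drop = FALSE]
  new_instrument(snps, mode = "multi_snp", locus = locus, n = n)
}

#' Single-SNP instrument from the top eQTL
#'
#' @param candidates candidate data.frame (see
#'   \code{\link{select_cis_candidates}}).
#' @param locus optional \code{gene_locus}.
#' @return an \code{instrument} with \code{mode = "top_snp"}.
#' @export
top_snp_instrument <- function(candidates, locus = NULL) {
  new_instrument(top_eqtl(candidates), mode = "top_snp", locus = locus)
}

new_instrument <- function(snps, mode, locus = NULL, n = NULL) {
  nn <- if (is.null(n)) snps$n else rep(n, length.out = nrow(snps))
  strength <- instrument_strength(snps$beta, snps$se, nn)
  out <- list(gene = locus, snps = snps,
              per_snp_r2 = strength$r2, per_snp_f = strength$f,
              mode = mode)
  class(out) <- "instrument"
  out
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("instrument (%s): %d SNP(s), total R2 = %.4g, min F = %.4g\n",
              x$mode, nrow(x$snps), sum(x$per_snp_r2), min(x$per_snp_f)))
  invisible(x)
}

#' Instrument strength: variance explained and F-statistic
#'
#' From the z-statistic \code{z = beta/se}: \code{r2 = z^2 / (z^2 + n - 2)}
#' and \code{f = r2 (n - 2) / (1 - r2)} (which reduces to \code{z^2} for a
#' single SNP). R-squared is computed from the z-statistic rather than from
#' allele frequency because frequency is optional in public summary files;
#' the two agree asymptotically for a unit-variance trait. For a clumped
#' (approximately independent) multi-SNP instrument the total R-squared is
#' the sum of the per-SNP values.
#'
#' @param beta,se per-SNP effect and standard error (vectorized).
#' @param n per-SNP sample size (> 2).
#' @return list with numeric vectors \code{r2} and \code{f}.
#' @export
instrument_strength <- function(beta, se, n) {
  if (any(n <= 2)) stop("sample size must exceed 2")
  if (any(se <= 0)) stop("se must be positive")
  z2 <- (beta / se)^2
  r2 <- z2 / (z2 + n - 2)
  f <- r2 * (n - 2) / (1 - r2)
  list(r2 = r2, f = f)
}

#' F-statistic from a printed R-squared and sample size
#'
#' @param r2 variance explained, in [0, 1).
#' @param n sample size (> 2).
#' @return F-statistic \code{r2 (n - 2) / (1 - r2)}.
#' @export
f_from_r2 <- function(r2, n) {
  stopifnot(all(r2 >= 0), all(r2 < 1), all(n > 2))
  r2 * (n - 2) / (1 - r2)
}
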