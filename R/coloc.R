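# Approximate-Bayes-factor colocalization: posterior probabilities that two
# traits' association signals in a cis region share one causal variant,
# under the single-causal-variant-per-trait assumption.

.logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
.logdiff <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Per-SNP log approximate Bayes factor (Wakefield-style)
#'
#' With shrinkage \code{r = prior_sd^2 / (prior_sd^2 + se^2)} and
#' \code{z = beta/se}, the log-ABF for association against the null is
#' \code{0.5 * (log(1 - r) + r * z^2)} — the log marginal-likelihood ratio
#' of a normal effect prior with SD \code{prior_sd} against a point null.
#'
#' @param beta,se observed effect and standard error (vectorized; se > 0).
#' @param prior_sd SD of the effect prior on the trait's own scale
#'   (convention: 0.15 for a quantitative trait in SD units, 0.2 for
#'   log-odds).
#' @return numeric vector of log-ABFs.
#' @export
abf_per_snp <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (prior_sd <= 0) stop("prior_sd must be positive")
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Extract and align a cis region shared by two summary tables
#'
#' Intersects the SNP sets within \code{window_bp} of \code{center}
#' (closed interval) on one chromosome and allele-harmonises the outcome to
#' the exposure orientation using the same rules as \code{\link{harmonise}}.
#'
#' @param exposure,outcome \code{summary_table}s.
#' @param chrom chromosome label (defaults to the exposure table's single
#'   chromosome).
#' @param center region center, base pairs.
#' @param window_bp half-width (default 1 Mb).
#' @param palindromic_maf_limit passed to the harmonisation rules.
#' @return object of class \code{region_pair}: \code{snps} data.frame with
#'   positions and per-trait beta/se/eaf/n, plus \code{center},
#'   \code{window_bp}, \code{excluded}.
#' @export
extract_region <- function(exposure, outcome, center, window_bp = 1e6,
                           chrom = NULL, palindromic_maf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"))
  if (is.null(chrom)) {
    chrom <- unique(exposure$records$chrom)
    if (length(chrom) != 1L) {
      stop("exposure spans multiple chromosomes; pass `chrom` explicitly")
    }
  }
  ex <- exposure$records
  ex <- ex[ex$chrom == chrom & abs(ex$pos - center) <= window_bp, ,
           drop = FALSE]
  if (nrow(ex) == 0L) stop("no exposure SNPs in region")
  h <- harmonise(ex, outcome, palindromic_maf_limit = palindromic_maf_limit)
  if (nrow(h$snps) == 0L) {
    stop("no overlap: no SNP shared by exposure and outcome in region")
  }
  d <- h$snps
  d$pos <- ex$pos[match(d$snp_id, ex$snp_id)]
  d$n_x <- ex$n[match(d$snp_id, ex$snp_id)]
  orec <- outcome$records
  d$n_y <- orec$n[match(d$snp_id, orec$snp_id)]
  out <- list(snps = d, center = center, window_bp = window_bp,
              chrom = chrom, excluded = h$excluded)
  class(out) <- "region_pair"
  out
}

#' Colocalization posterior probabilities for five hypotheses
#'
#' H0: no association with either trait; H1/H2: association with the
#' exposure/outcome only; H3: both, two distinct causal variants; H4: both,
#' one shared causal variant. Per-SNP log-ABFs are combined with
#' log-sum-exp; hypothesis sums are S1 = sum_i ABF1_i, S2 = sum_j ABF2_j,
#' S4 = sum_i ABF1_i ABF2_i and S3 = S1 S2 - S4 (the off-diagonal pairs);
#' posteriors are proportional to \{1, p1 S1, p2 S2, p1 p2 S3, p12 S4\}.
#'
#' @param region a \code{region_pair} (or data.frame with bx/sx/by/sy).
#' @param p1,p2 prior probabilities a SNP is causal for the exposure /
#'   outcome (default 1e-4 each).
#' @param p12 prior probability a SNP is causal for both (default 1e-5).
#' @param prior_sd_quant,prior_sd_cc effect-prior SDs for the quantitative
#'   exposure (0.15) and the binary outcome on the log-odds scale (0.2).
#' @return object of class \code{coloc_posterior}: \code{pp} (named pp0 ..
#'   pp4, summing to 1), \code{nsnps}, \code{per_snp_h4} (posterior that
#'   each SNP is the shared variant, given H4), \code{single_snp} flag (H3
#'   undefined, computed with S3 = 0).
#' @export
coloc_posteriors <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  d <- if (inherits(region, "region_pair")) region$snps else region
  stopifnot(is.data.frame(d), nrow(d) >= 1L,
            all(c("bx", "sx", "by", "sy") %in% names(d)))
  l1 <- abf_per_snp(d$bx, d$sx, prior_sd_quant)
  l2 <- abf_per_snp(d$by, d$sy, prior_sd_cc)
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s4 <- .logsumexp(l1 + l2)
  single_snp <- nrow(d) == 1L
  s3 <- if (single_snp) -Inf else .logdiff(s1 + s2, s4)
  logpost <- c(
    pp0 = 0,
    pp1 = log(p1) + s1,
    pp2 = log(p2) + s2,
    pp3 = log(p1) + log(p2) + s3,
    pp4 = log(p12) + s4
  )
  pp <- exp(logpost - .logsumexp(logpost))
  per_snp_h4 <- exp((l1 + l2) - s4)
  names(per_snp_h4) <- if ("snp_id" %in% names(d)) d$snp_id else NULL
  out <- list(pp = pp, nsnps = nrow(d), per_snp_h4 = per_snp_h4,
              single_snp = single_snp)
  class(out) <- "coloc_posterior"
  out
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf("coloc_posterior over %d SNP(s)%s\n", x$nsnps,
              if (x$single_snp) " [single SNP: H3 set to 0]" else ""))
  print(round(x$pp, 4))
  invisible(x)
}
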