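.PALINDROMIC_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

.is_palindromic <- function(ea, oa) paste(ea, oa, sep = "/") %in% .PALINDROMIC_PAIRS

#' Harmonise exposure and outcome summary statistics to a common allele
#'
#' Aligns every instrument SNP so the exposure and outcome effects are
#' expressed relative to the same effect allele. Rules, applied per SNP:
#' \itemize{
#'   \item absent from the outcome table: excluded, reason
#'     \code{missing_in_outcome};
#'   \item same allele pair, same orientation: retained unchanged;
#'   \item same pair, swapped orientation: outcome beta sign-flipped and
#'     outcome frequency complemented, flagged \code{flipped};
#'   \item palindromic pair (A/T or C/G): orientation is unresolvable from
#'     alleles alone, so the SNP is retained only when both allele
#'     frequencies are available, both minor-allele frequencies are below
#'     \code{palindromic_maf_limit}, and the frequencies are concordant
#'     (same side of 0.5) after orientation; otherwise excluded, reason
#'     \code{palindromic_ambiguous};
#'   \item any other allele combination: excluded, reason
#'     \code{allele_mismatch}.
#' }
#'
#' @param exposure an \code{instrument} (or a data.frame of exposure
#'   records with the internal schema).
#' @param outcome binary \code{summary_table} of outcome statistics.
#' @param palindromic_maf_limit frequency ambiguity bound (default 0.42).
#' @return object of class \code{harmonised_set}: \code{snps} data.frame
#'   (snp_id, effect_allele, other_allele, bx, sx, by, sy, eaf_x, eaf_y,
#'   flipped, palindromic) and \code{excluded} data.frame (snp_id, reason).
#' @export
harmonise <- function(exposure, outcome, palindromic_maf_limit = 0.42) {
  exp_rec <- if (inherits(exposure, "instrument")) exposure$snps else exposure
  stopifnot(is.data.frame(exp_rec))
  if (nrow(exp_rec) == 0L) stop("no instrument: exposure has no SNPs")
  out_rec <- if (inherits(outcome, "summary_table")) outcome$records else outcome

  rows <- vector("list", nrow(exp_rec))
  excl <- list()
  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, ]
    j <- match(e$snp_id, out_rec$snp_id)
    drop <- function(reason) {
      excl[[length(excl) + 1L]] <<- data.frame(snp_id = e$snp_id,
                                               reason = reason)
    }
    if (is.na(j)) { drop("missing_in_outcome"); next }
    o <- out_rec[j, ]
    same <- o$effect_allele == e$effect_allele &&
      o$other_allele == e$other_allele
    swapped <- o$effect_allele == e$other_allele &&
      o$other_allele == e$effect_allele
    if (!same && !swapped) { drop("allele_mismatch"); next }
    pal <- .is_palindromic(e$effect_allele, e$other_allele)
    by <- if (swapped) -o$beta else o$beta
    eaf_y <- if (swapped && !is.na(o$eaf)) 1 - o$eaf else o$eaf
    if (pal) {
      if (is.na(e$eaf) || is.na(eaf_y)) { drop("palindromic_ambiguous"); next }
      maf_x <- min(e$eaf, 1 - e$eaf)
      maf_y <- min(eaf_y, 1 - eaf_y)
      concordant <- sign(e$eaf - 0.5) == sign(eaf_y - 0.5)
      if (maf_x >= palindromic_maf_limit || maf_y >= palindromic_maf_limit ||
          !concordant) {
        drop("palindromic_ambiguous"); next
      }
    }
    rows[[i]] <- data.frame(
      snp_id = e$snp_id,
      effect_allele = e$effect_allele, other_allele = e$other_allele,
      bx = e$beta, sx = e$se, by = by, sy = o$se,
      eaf_x = e$eaf, eaf_y = eaf_y,
      flipped = swapped, palindromic = pal,
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(snps)) {
    snps <- data.frame(snp_id = character(0), effect_allele = character(0),
                       other_allele = character(0), bx = numeric(0),
                       sx = numeric(0), by = numeric(0), sy = numeric(0),
                       eaf_x = numeric(0), eaf_y = numeric(0),
                       flipped = logical(0), palindromic = logical(0))
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(snp_id = character(0), reason = character(0))
  rownames(snps) <- NULL
  out <- list(snps = snps, excluded = excluded)
  class(out) <- "harmonised_set"
  out
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("harmonised_set: %d SNP(s) retained (%d flipped), %d excluded\n",
              nrow(x$snps), sum(x$snps$flipped), nrow(x$excluded)))
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# accept a harmonised_set or a bare data.frame with bx/sx/by/sy columns
.h_snps <- function(h) {
  df <- if (inherits(h, "harmonised_set")) h$snps else h
  stopifnot(is.data.frame(df),
            all(c("bx", "sx", "by", "sy") %in% names(df)))
  df
}
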