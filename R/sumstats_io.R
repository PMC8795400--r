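#' Column-mapping dialect for summary-statistics files
#'
#' Public eQTL and GWAS summary files use a range of column names for the
#' same quantities. A dialect maps the file's column names onto the internal
#' schema: \code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#' \code{n}, and for binary traits \code{n_cases}, \code{n_controls}.
#'
#' @param ... named overrides, e.g. \code{snp_id = "rsid"}, \code{pval = "P"}.
#'   Names must be internal field names; values are the column names in the
#'   file. Optional fields (\code{eaf}, \code{n_cases}, \code{n_controls})
#'   may be set to \code{NA} to mark them absent.
#' @param preset one of \code{"default"} (internal names), \code{"gwas"}
#'   (SNP/CHR/BP/A1/A2/FREQ/BETA/SE/P/N) or \code{"eqtlgen"}
#'   (SNP/SNPChr/SNPPos/AssessedAllele/OtherAllele/...).
#' @return named character vector mapping internal field -> file column.
#' @examples
#' sumstats_dialect(preset = "gwas", pval = "P_BOLT")
#' @export
sumstats_dialect <- function(..., preset = c("default", "gwas", "eqtlgen")) {
  preset <- match.arg(preset)
  base <- c(
    snp_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval",
    n = "n", n_cases = "n_cases", n_controls = "n_controls"
  )
  if (preset == "gwas") {
    base[c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")] <-
      c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "BETA", "SE", "P", "N")
  } else if (preset == "eqtlgen") {
    base[c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")] <-
      c("SNP", "SNPChr", "SNPPos", "AssessedAllele", "OtherAllele",
        "AlleleB_all", "Beta", "SE", "Pvalue", "NrSamples")
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad)) {
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    }
    base[names(overrides)] <- unlist(overrides, use.names = FALSE)
  }
  base
}

.MANDATORY_FIELDS <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "beta", "se", "pval", "n")
.NUMERIC_FIELDS <- c("pos", "eaf", "beta", "se", "pval",
                     "n", "n_cases", "n_controls")

#' Construct a summary table of per-SNP association statistics
#'
#' The central container for one trait's summary statistics: a validated
#' data frame of per-SNP records plus trait metadata. Rows violating the
#' record invariants (see Details) are dropped and tallied in the attached
#' load report.
#'
#' @details Record invariants: unique \code{snp_id}; alleles single
#'   characters in A/C/G/T and distinct; \code{se > 0}; \code{pval} in
#'   (0, 1]; \code{eaf} (if present) in (0, 1); for binary traits
#'   \code{n_cases + n_controls == n}. Alleles are upper-cased on entry;
#'   indels / multi-character alleles are rejected (biallelic SNPs only).
#'
#' @param records data.frame with the internal schema columns.
#' @param trait_type "quantitative" or "binary".
#' @param trait_label,source_label free-text labels (e.g. gene, tissue).
#' @return object of class \code{summary_table}: list with \code{records},
#'   \code{trait_type}, \code{trait_label}, \code{source_label} and a
#'   \code{load_report} (accepted/rejected counts with reasons).
#' @export
summary_table <- function(records, trait_type = c("quantitative", "binary"),
                          trait_label = "", source_label = "") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.MANDATORY_FIELDS, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("eaf", "n_cases", "n_controls")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  records <- records[, c(.MANDATORY_FIELDS, "eaf", "n_cases", "n_controls")]
  for (col in .NUMERIC_FIELDS) records[[col]] <- as.numeric(records[[col]])
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  reasons <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reasons[is.na(reasons) & bad] <<- why
  }
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(!ok_allele(records$effect_allele) | !ok_allele(records$other_allele),
       "invalid_allele")
  flag(records$effect_allele == records$other_allele, "identical_alleles")
  flag(!is.finite(records$beta), "missing_beta")
  flag(!(records$se > 0), "nonpositive_se")
  flag(!(records$pval > 0 & records$pval <= 1), "pval_out_of_range")
  flag(!(records$n > 2), "invalid_n")
  flag(!(records$pos > 0), "invalid_pos")
  has_eaf <- !is.na(records$eaf)
  flag(has_eaf & !(records$eaf > 0 & records$eaf < 1), "eaf_out_of_range")
  flag(duplicated(records$snp_id), "duplicate_snp_id")
  if (trait_type == "binary") {
    has_cc <- !is.na(records$n_cases) & !is.na(records$n_controls)
    flag(has_cc & abs(records$n_cases + records$n_controls - records$n) > 0.5,
         "case_control_mismatch")
  }

  keep <- is.na(reasons)
  rejected <- table(reasons[!keep])
  report <- list(
    n_input = nrow(records),
    n_accepted = sum(keep),
    n_rejected = sum(!keep),
    reasons = as.list(rejected)
  )
  if (report$n_accepted == 0L) {
    stop("no valid rows after validation (", report$n_rejected, " rejected)")
  }
  out <- list(
    records = records[keep, , drop = FALSE],
    trait_type = trait_type,
    trait_label = trait_label,
    source_label = source_label,
    load_report = report
  )
  rownames(out$records) <- NULL
  class(out) <- "summary_table"
  out
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("summary_table: %d SNPs, %s trait", nrow(x$records), x$trait_type))
  if (nzchar(x$trait_label)) cat(" [", x$trait_label, "]", sep = "")
  if (nzchar(x$source_label)) cat(" (", x$source_label, ")", sep = "")
  cat("\n")
  if (x$load_report$n_rejected > 0) {
    cat("  rejected on load:", x$load_report$n_rejected, "row(s)\n")
  }
  invisible(x)
}

#' Read summary statistics from a delimited text file
#'
#' @param path TSV or CSV file with a header row. Delimiter is inferred from
#'   the extension (.csv -> comma, otherwise tab).
#' @param dialect column mapping from \code{\link{sumstats_dialect}}.
#' @param trait_type,trait_label,source_label passed to
#'   \code{\link{summary_table}}.
#' @return validated \code{summary_table}; rejected rows are counted in its
#'   \code{load_report}.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_type = c("quantitative", "binary"),
                          trait_label = "", source_label = "") {
  trait_type <- match.arg(trait_type)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty input: no data rows in ", path)
  wanted <- dialect[.MANDATORY_FIELDS]
  absent <- wanted[!wanted %in% names(raw) | is.na(wanted)]
  if (length(absent)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(sprintf("%s (mapped to %s)", absent, names(absent)),
               collapse = ", "))
  }
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(dialect)) {
    col <- dialect[[field]]
    records[[field]] <- if (!is.na(col) && col %in% names(raw)) {
      raw[[col]]
    } else NA_character_
  }
  summary_table(records, trait_type = trait_type,
                trait_label = trait_label, source_label = source_label)
}

.format_col <- function(x, scientific = FALSE) {
  if (is.character(x)) return(ifelse(is.na(x), "NA", x))
  if (scientific) {
    return(ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 6)))
  }
  ifelse(is.na(x),
         "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                sprintf("%.0f", x),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write a summary table (or any tabular result) as deterministic TSV
#'
#' Column order and float formatting are fixed (6 significant digits;
#' P-values and posterior probabilities in scientific notation) so repeated
#' writes of the same object are byte-identical and outputs are diffable.
#'
#' @param x a \code{summary_table} or plain data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(x, path) {
  df <- if (inherits(x, "summary_table")) x$records else x
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("refusing to write an empty table")
  sci_cols <- intersect(c("pval", "pp0", "pp1", "pp2", "pp3", "pp4"), names(df))
  out <- df
  for (col in names(out)) {
    out[[col]] <- .format_col(out[[col]], scientific = col %in% sci_cols)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
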