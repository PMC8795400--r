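#' A priori power for binary-outcome MR
#'
#' Normal-approximation power to detect an alternative odds ratio with an
#' instrument explaining \code{r2} of the exposure variance, in a study of
#' \code{n_cases} cases and \code{n_controls} controls. With N the total
#' sample and phi the case fraction, the noncentrality is
#' \code{sqrt(N * r2 * phi * (1 - phi)) * |log(or_alt)|} and
#' \code{power = Phi(ncp - z_{1-alpha/2})}. Power is identical for
#' \code{or_alt} and \code{1/or_alt} (a risk OR of 1.2 and a protective OR
#' of 0.80 give the same power).
#'
#' @param r2 instrument variance explained, in [0, 1). r2 = 0 is allowed
#'   and gives power alpha/2 (one tail of the null rejection region).
#' @param n_cases,n_controls case and control counts.
#' @param or_alt alternative odds ratio (default 1.2; must differ from 1).
#' @param alpha two-sided significance level (default 0.05).
#' @return list: \code{power} (probability), \code{ncp}, and the echoed
#'   configuration.
#' @export
mr_power_binary <- function(r2, n_cases, n_controls, or_alt = 1.2,
                            alpha = 0.05) {
  stopifnot(r2 >= 0, r2 < 1, n_cases > 0, n_controls > 0,
            or_alt > 0, or_alt != 1, alpha > 0, alpha < 1)
  n <- n_cases + n_controls
  phi <- n_cases / n
  ncp <- sqrt(n * r2 * phi * (1 - phi)) * abs(log(or_alt))
  power <- stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
  list(power = power, ncp = ncp,
       config = list(r2 = r2, n_cases = n_cases, n_controls = n_controls,
                     or_alt = or_alt, alpha = alpha))
}

#' Bonferroni evidence tier for a P-value
#'
#' Classifies association evidence against a Bonferroni-corrected strong
#' threshold: \code{strong} if P < alpha / n_tests, \code{suggestive} if
#' alpha / n_tests <= P < alpha, \code{weak} otherwise. The boundary uses
#' the exact alpha / n_tests (0.05 / 14 = 0.003571...), not a rounded
#' value.
#'
#' @param pval P-value(s), vectorized.
#' @param n_tests number of independent tests (default 14, the number of
#'   analysable genes in a 20-gene family with 6 lacking instruments).
#' @param alpha family-wise level (default 0.05).
#' @return character vector in \{"strong", "suggestive", "weak"\}.
#' @export
bonferroni_tier <- function(pval, n_tests = 14, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  thr <- alpha / n_tests
  ifelse(pval < thr, "strong", ifelse(pval < alpha, "suggestive", "weak"))
}

#' Batch power / instrument-strength table
#'
#' @param strength data.frame with columns \code{gene}, \code{source},
#'   \code{r2} (fraction), \code{f}.
#' @param outcomes data.frame with columns \code{outcome}, \code{n_cases},
#'   \code{n_controls}.
#' @param or_alt,alpha passed to \code{\link{mr_power_binary}}.
#' @return data.frame: one row per gene x source, R2/F plus one power
#'   column (percent) per outcome, and a display column capping at ">99".
#' @export
power_table <- function(strength, outcomes, or_alt = 1.2, alpha = 0.05) {
  out <- strength
  for (k in seq_len(nrow(outcomes))) {
    pw <- vapply(strength$r2, function(r2) {
      100 * mr_power_binary(r2, outcomes$n_cases[k], outcomes$n_controls[k],
                            or_alt = or_alt, alpha = alpha)$power
    }, numeric(1))
    col <- paste0("power_", outcomes$outcome[k])
    out[[col]] <- pw
    out[[paste0(col, "_display")]] <-
      ifelse(pw > 99, ">99", formatC(pw, format = "f", digits = 2))
  }
  out
}
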