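# Causal-effect estimators on harmonised summary statistics. All P-values
# use the normal approximation, the summary-data MR convention.

new_mr_estimate <- function(method, nsnp, beta, se, extras = list()) {
  z975 <- stats::qnorm(0.975)
  ci_low <- beta - z975 * se
  ci_high <- beta + z975 * se
  pval <- 2 * stats::pnorm(-abs(beta / se))
  out <- list(method = method, nsnp = nsnp, beta = beta, se = se,
              ci_low = ci_low, ci_high = ci_high,
              or_ = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
              pval = min(max(pval, .Machine$double.xmin), 1),
              extras = extras)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (nsnp = %d): OR %.3f (95%% CI %.3f, %.3f), P = %.3g\n",
              x$method, x$nsnp, x$or_, x$or_low, x$or_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
             or_ = x$or_, or_low = x$or_low, or_high = x$or_high,
             pval = x$pval, stringsAsFactors = FALSE)
}

#' Wald-ratio causal estimate from a single SNP
#'
#' beta = by / bx; the default standard error is the first-order delta
#' method sy / |bx| (the summary-MR platform default); the second-order
#' form additionally propagates the exposure uncertainty.
#'
#' @param bx,sx exposure effect and SE.
#' @param by,sy outcome effect and SE.
#' @param second_order use the second-order delta-method SE.
#' @return an \code{mr_estimate} (method \code{"wald_ratio"}).
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) stop("undefined ratio: exposure effect is zero")
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    sy / abs(bx)
  }
  new_mr_estimate("wald_ratio", 1L, beta, se,
                  extras = list(second_order = second_order))
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights 1/sy^2, equivalent to an inverse-variance meta-analysis of
#' the per-SNP Wald ratios. Uses the multiplicative random-effects model:
#' the fixed-effect SE is multiplied by the residual scale
#' \code{sqrt(Q / (nsnp - 1))} when it exceeds 1, and left unscaled when
#' the model is underdispersed (scale floored at 1). A single SNP reduces
#' exactly to the Wald ratio.
#'
#' @param h a \code{harmonised_set} (or data.frame with bx/sx/by/sy).
#' @return an \code{mr_estimate} (method \code{"ivw"}); \code{extras} holds
#'   the applied residual \code{scale} and the heterogeneity stat \code{q}.
#' @export
ivw <- function(h) {
  d <- .h_snps(h)
  n <- nrow(d)
  if (n == 0L) stop("no data: harmonised set is empty")
  if (n == 1L) {
    est <- wald_ratio(d$bx, d$sx, d$by, d$sy)
    est$method <- "ivw"
    return(est)
  }
  w <- 1 / d$sy^2
  beta <- sum(d$bx * d$by * w) / sum(d$bx^2 * w)
  se_fixed <- sqrt(1 / sum(d$bx^2 * w))
  q <- sum(w * (d$by - beta * d$bx)^2)
  scale <- max(1, sqrt(q / (n - 1)))
  new_mr_estimate("ivw", n, beta, se_fixed * scale,
                  extras = list(scale = scale, q = q, df = n - 1L))
}

#' Cochran's Q heterogeneity statistic across per-SNP causal effects
#'
#' Q = sum_j w_j (ratio_j - beta)^2 with w_j = (bx_j / sy_j)^2, referred to
#' a chi-square with nsnp - 1 degrees of freedom.
#'
#' @param h a \code{harmonised_set}.
#' @param beta_ivw the pooled estimate (defaults to \code{ivw(h)$beta}).
#' @return list \code{q}, \code{df}, \code{pval}.
#' @export
cochran_q <- function(h, beta_ivw = NULL) {
  d <- .h_snps(h)
  n <- nrow(d)
  if (n < 2L) stop("insufficient SNPs: Cochran's Q needs at least 2")
  if (is.null(beta_ivw)) beta_ivw <- ivw(d)$beta
  w <- (d$bx / d$sy)^2
  q <- sum(w * (d$by / d$bx - beta_ivw)^2)
  df <- n - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

# weighted least squares of y on X, multiplicative random effects with the
# residual scale floored at 1; returns coef, se, the applied scale and the
# weighted RSS
.wls_mult <- function(X, y, w, floor_scale = TRUE) {
  xtw <- t(X * w)
  xtx <- xtw %*% X
  coefs <- solve(xtx, xtw %*% y)
  resid <- y - X %*% coefs
  rss_w <- sum(w * resid^2)
  df <- length(y) - ncol(X)
  sigma <- if (df > 0) sqrt(rss_w / df) else NA_real_
  scale <- if (floor_scale) max(1, sigma) else sigma
  se <- sqrt(diag(solve(xtx))) * scale
  list(coef = as.numeric(coefs), se = se, scale = scale, rss_w = rss_w,
       df = df)
}

#' MR-Egger regression
#'
#' Every SNP is oriented so its exposure effect is positive, then outcome
#' effects are regressed on exposure effects with an intercept, weights
#' 1/sy^2. The slope estimates the causal effect allowing all SNPs a shared
#' directional pleiotropic offset; the intercept (with its SE and P) is the
#' directional-pleiotropy test. Multiplicative random-effects scale floored
#' at 1, as for IVW. Requires at least 3 SNPs.
#'
#' @param h a \code{harmonised_set}.
#' @return an \code{mr_estimate} (method \code{"egger"}); \code{extras}
#'   holds \code{intercept}, \code{intercept_se}, \code{intercept_pval},
#'   \code{scale}, and the Egger heterogeneity \code{q} on nsnp - 2 df.
#' @export
mr_egger <- function(h) {
  d <- .h_snps(h)
  n <- nrow(d)
  if (n < 3L) {
    stop("insufficient SNPs: MR-Egger requires an instrument with >= 3 ",
         "independent SNPs")
  }
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- 1 / d$sy^2
  fit <- .wls_mult(cbind(1, bx), by, w)
  est <- new_mr_estimate(
    "egger", n, fit$coef[2], fit$se[2],
    extras = list(
      intercept = fit$coef[1], intercept_se = fit$se[1],
      intercept_pval = 2 * stats::pnorm(-abs(fit$coef[1] / fit$se[1])),
      scale = fit$scale, q = fit$rss_w, df = n - 2L
    )
  )
  est
}

.weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(ratio[1])
  k <- length(ratio)
  if (0.5 >= cum[k]) return(ratio[k])
  stats::approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

.parametric_boot_se <- function(d, point_fun, n_boot, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(d)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, d$bx, d$sx)
    by <- stats::rnorm(n, d$by, d$sy)
    point_fun(by / bx, (bx / d$sy)^2)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median causal estimate
#'
#' The per-SNP Wald ratios are sorted and the estimate is the ratio at
#' cumulative normalized inverse-variance weight 0.5 (linear interpolation
#' of the midpoints), consistent when SNPs carrying at least half the
#' weight are valid instruments. SE by seeded parametric bootstrap.
#'
#' @param h a \code{harmonised_set} with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return an \code{mr_estimate} (method \code{"weighted_median"}).
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1) {
  d <- .h_snps(h)
  if (nrow(d) < 3L) {
    stop("insufficient SNPs: weighted median requires >= 3 SNPs")
  }
  w <- (d$bx / d$sy)^2
  beta <- .weighted_median_point(d$by / d$bx, w)
  se <- .parametric_boot_se(d, .weighted_median_point, n_boot, seed)
  new_mr_estimate("weighted_median", nrow(d), beta, se,
                  extras = list(n_boot = n_boot, seed = seed))
}

.weighted_mode_point <- function(ratio, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) / length(ratio)^0.2
  if (!is.finite(s) || s <= 0) return(ratio[which.max(w)])
  dens <- stats::density(ratio, weights = w, bw = bandwidth_factor * s,
                         n = 2048)
  dens$x[which.max(dens$y)]
}

#' Weighted-mode causal estimate
#'
#' Kernel-smoothed weighted density of the per-SNP Wald ratios (normal
#' kernel, modified Silverman bandwidth 0.9 min(sd, mad) nsnp^-1/5 times
#' \code{bandwidth_factor}); the estimate is the density argmax, consistent
#' when the largest group of SNPs with equal ratios is valid. SE by seeded
#' parametric bootstrap.
#'
#' @param h a \code{harmonised_set} with at least 3 SNPs.
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @param n_boot,seed bootstrap parameters.
#' @return an \code{mr_estimate} (method \code{"weighted_mode"}).
#' @export
weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  d <- .h_snps(h)
  if (nrow(d) < 3L) {
    stop("insufficient SNPs: weighted mode requires >= 3 SNPs")
  }
  w <- (d$bx / d$sy)^2
  beta <- .weighted_mode_point(d$by / d$bx, w, bandwidth_factor)
  se <- .parametric_boot_se(
    d, function(r, ww) .weighted_mode_point(r, ww, bandwidth_factor),
    n_boot, seed
  )
  new_mr_estimate("weighted_mode", nrow(d), beta, se,
                  extras = list(bandwidth_factor = bandwidth_factor,
                                n_boot = n_boot, seed = seed))
}

#' Run every applicable MR estimator on a harmonised set
#'
#' Single-SNP instruments get the Wald ratio only; 2 SNPs add IVW and
#' Cochran's Q; 3 or more add Egger, weighted median and weighted mode.
#'
#' @param h a \code{harmonised_set}.
#' @param n_boot,seed bootstrap parameters for median/mode.
#' @return data.frame with one row per method (method, nsnp, beta, se,
#'   or_, or_low, or_high, pval).
#' @export
mr_all <- function(h, n_boot = 1000, seed = 1) {
  d <- .h_snps(h)
  n <- nrow(d)
  ests <- list()
  if (n == 1L) {
    ests$wald <- wald_ratio(d$bx, d$sx, d$by, d$sy)
  } else if (n >= 2L) {
    ests$ivw <- ivw(d)
    if (n >= 3L) {
      ests$egger <- mr_egger(d)
      ests$wmed <- weighted_median(d, n_boot = n_boot, seed = seed)
      ests$wmode <- weighted_mode(d, n_boot = n_boot, seed = seed + 1L)
    }
  }
  do.call(rbind, lapply(ests, as.data.frame))
}

#' Numeric sensitivity diagnostics for a multi-SNP instrument
#'
#' @param h a \code{harmonised_set} with at least 2 SNPs.
#' @return list of data.frames: \code{per_snp} (snp_id, beta, se — the
#'   per-SNP Wald ratios, forest/scatter data), \code{leave_one_out}
#'   (snp_id omitted, beta, se — IVW omitting each SNP in turn) and
#'   \code{funnel} (precision |bx|/sy against the ratio estimate).
#' @export
sensitivity_scan <- function(h) {
  d <- .h_snps(h)
  n <- nrow(d)
  if (n < 2L) stop("sensitivity scan requires >= 2 SNPs")
  per_snp <- data.frame(
    snp_id = d$snp_id, beta = d$by / d$bx, se = d$sy / abs(d$bx),
    stringsAsFactors = FALSE
  )
  loo <- lapply(seq_len(n), function(i) {
    est <- ivw(d[-i, , drop = FALSE])
    data.frame(snp_id = d$snp_id[i], beta = est$beta, se = est$se,
               stringsAsFactors = FALSE)
  })
  funnel <- data.frame(
    snp_id = d$snp_id, precision = abs(d$bx) / d$sy, beta = d$by / d$bx,
    stringsAsFactors = FALSE
  )
  list(per_snp = per_snp, leave_one_out = do.call(rbind, loo),
       funnel = funnel)
}
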