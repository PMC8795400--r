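# Simulation of linked eQTL / case-control GWAS summary statistics with a
# known causal structure, used to validate every downstream stage.
#
# Genotypes follow a first-order autoregressive haplotype process: each
# haplotype carries a latent standard-normal AR(1) series along the SNPs and
# the allele is the indicator that the latent value falls below the MAF
# quantile, so adjacent-SNP linkage disequilibrium decays geometrically.

.simulate_haplotype_dosages <- function(n_individuals, maf, ld_decay) {
  m <- length(maf)
  n_hap <- 2L * n_individuals
  z <- matrix(0, n_hap, m)
  z[, 1] <- stats::rnorm(n_hap)
  if (m > 1) {
    innov_sd <- sqrt(1 - ld_decay^2)
    for (j in 2:m) {
      z[, j] <- ld_decay * z[, j - 1] + innov_sd * stats::rnorm(n_hap)
    }
  }
  thresh <- stats::qnorm(maf)
  alleles <- sweep(z, 2, thresh, "<") * 1
  dos <- alleles[seq_len(n_individuals), , drop = FALSE] +
    alleles[n_individuals + seq_len(n_individuals), , drop = FALSE]
  dos
}

#' Simulate a genotype reference panel with autoregressive LD
#'
#' @param n_individuals panel size (>= 50).
#' @param n_snps number of SNPs.
#' @param ld_decay latent haplotype autocorrelation in [0, 1); 0 gives
#'   independent SNPs, values near 1 give long-range LD.
#' @param maf_range interval within (0, 0.5] from which per-SNP minor-allele
#'   frequencies are drawn uniformly.
#' @param seed integer seed; the panel is reproducible given the seed.
#' @param chrom chromosome label for all SNPs.
#' @param pos_start,pos_step base-pair coordinates: SNP j sits at
#'   \code{pos_start + (j-1) * pos_step}.
#' @return object of class \code{reference_panel}: \code{dosages}
#'   (individuals x SNPs, allele counts 0/1/2, columns named by SNP id),
#'   \code{snp_meta} (snp_id, chrom, pos, effect_allele, other_allele),
#'   \code{maf}, \code{ld_decay}, \code{seed}. No SNP is monomorphic.
#' @export
simulate_reference_panel <- function(n_individuals, n_snps, ld_decay = 0.8,
                                     maf_range = c(0.05, 0.5), seed = 1,
                                     chrom = "1", pos_start = 1e6,
                                     pos_step = 10000) {
  stopifnot(n_individuals >= 50, n_snps >= 1)
  if (!(ld_decay >= 0 && ld_decay < 1)) stop("ld_decay must be in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an increasing interval within (0, 0.5]")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  dos <- .simulate_haplotype_dosages(n_individuals, maf, ld_decay)
  # guard against the rare monomorphic draw so LD is always defined
  mono <- which(apply(dos, 2, stats::var) == 0)
  for (j in mono) dos[1, j] <- if (dos[1, j] == 0) 1 else dos[1, j] - 1
  snp_ids <- sprintf("rs%05d", seq_len(n_snps))
  colnames(dos) <- snp_ids
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_snps, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
  panel <- list(
    dosages = dos,
    snp_meta = data.frame(
      snp_id = snp_ids, chrom = chrom,
      pos = pos_start + (seq_len(n_snps) - 1) * pos_step,
      effect_allele = ea, other_allele = unname(oa),
      stringsAsFactors = FALSE
    ),
    maf = maf, ld_decay = ld_decay, seed = seed
  )
  class(panel) <- "reference_panel"
  panel
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Define the causal ground truth of a simulation
#'
#' @param theta true causal effect of expression on the outcome, in log-odds
#'   per SD of expression.
#' @param causal_eqtl_ids SNP ids with a direct effect on expression.
#' @param h2_cis proportion of expression variance explained by the causal
#'   eQTLs, in [0, 1).
#' @param pleiotropy named numeric vector of per-SNP direct (horizontal
#'   pleiotropic) effects on the outcome liability, log-odds per allele.
#' @param scenario label for the preset that produced this truth.
#' @param seed integer seed recorded for the bundle.
#' @return object of class \code{simulation_truth}.
#' @export
simulation_truth <- function(theta = 0, causal_eqtl_ids = character(0),
                             h2_cis = 0, pleiotropy = numeric(0),
                             scenario = "custom", seed = NA_integer_) {
  if (!(h2_cis >= 0 && h2_cis < 1)) stop("h2_cis must be in [0, 1)")
  if (length(causal_eqtl_ids) > 0 && h2_cis == 0) {
    stop("h2_cis = 0 is inconsistent with a non-empty causal eQTL set")
  }
  if (theta != 0 && length(causal_eqtl_ids) == 0) {
    stop("nonzero theta requires at least one causal eQTL")
  }
  out <- list(theta = theta, causal_eqtl_ids = causal_eqtl_ids,
              h2_cis = h2_cis, pleiotropy = pleiotropy,
              scenario = scenario, seed = seed)
  class(out) <- "simulation_truth"
  out
}

# Per-SNP raw causal weights on expression and the scaling constant that
# makes the genetic value explain h2_cis of a unit-variance expression.
# Deterministic given the panel, so the expression and outcome studies share
# the same genetic architecture.
.expression_architecture <- function(panel, truth) {
  idx <- match(truth$causal_eqtl_ids, panel$snp_meta$snp_id)
  if (anyNA(idx)) {
    stop("causal eQTL id(s) absent from panel: ",
         paste(truth$causal_eqtl_ids[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 0) {
    return(list(idx = integer(0), w = numeric(0), scale = 0))
  }
  w <- rep(1, length(idx))
  gv <- panel$dosages[, idx, drop = FALSE] %*% w
  v <- stats::var(as.numeric(gv))
  list(idx = idx, w = w, scale = sqrt(truth$h2_cis / v))
}

#' Simulate an eQTL study and return per-SNP summary statistics
#'
#' Individual-level genotypes are drawn from the panel's generative process
#' (same MAFs and LD decay), expression is linear in the causal dosages plus
#' Gaussian noise scaled so the cis-heritability equals \code{truth$h2_cis},
#' and expression is standardized to unit SD before the per-SNP marginal
#' regressions, so betas are in SD-of-expression units per allele.
#'
#' @param panel a \code{reference_panel}.
#' @param truth a \code{simulation_truth}; its causal ids must be panel SNPs.
#' @param n study sample size (>= 100).
#' @param seed integer seed.
#' @return quantitative \code{summary_table} covering every panel SNP.
#' @export
simulate_expression_study <- function(panel, truth, n, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"), n >= 100)
  arch <- .expression_architecture(panel, truth)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- .simulate_haplotype_dosages(n, panel$maf, panel$ld_decay)
  gv <- if (length(arch$idx)) {
    as.numeric(g[, arch$idx, drop = FALSE] %*% arch$w) * arch$scale
  } else rep(0, n)
  y <- gv + stats::rnorm(n, sd = sqrt(1 - truth$h2_cis))
  y <- (y - mean(y)) / stats::sd(y)

  gc_ <- scale(g, center = TRUE, scale = FALSE)
  sxx <- colSums(gc_^2)
  sxx[sxx == 0] <- NA_real_
  sxy <- as.numeric(crossprod(gc_, y - mean(y)))
  beta <- sxy / sxx
  syy <- sum((y - mean(y))^2)
  sse <- syy - beta^2 * sxx
  se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval <- pmax(pval, .Machine$double.xmin)
  rec <- panel$snp_meta
  rec$eaf <- colMeans(g) / 2
  rec$beta <- beta
  rec$se <- se
  rec$pval <- pval
  rec$n <- n
  rec <- rec[is.finite(rec$beta) & is.finite(rec$se) & rec$se > 0, ]
  summary_table(rec, trait_type = "quantitative",
                trait_label = "expression", source_label = "simulated")
}

#' Simulate a case-control outcome study and return per-SNP log-OR statistics
#'
#' Disease liability is \code{theta} times the genetic expression score (the
#' causal-eQTL value on the standardized expression scale) plus any per-SNP
#' pleiotropic effects plus standard-logistic noise; case status is liability
#' above the threshold that yields the target population prevalence
#' (threshold-then-sample ascertainment). With logistic noise the per-SNP
#' conditional effects are exact log-odds ratios, matching how GWAS
#' consortia report binary-trait effects. Per-SNP log-OR, SE and P come from
#' the logistic score statistic on the sampled case-control set.
#'
#' @param panel a \code{reference_panel}.
#' @param truth a \code{simulation_truth}.
#' @param n_cases,n_controls sampled counts (each >= 500).
#' @param seed integer seed.
#' @param prevalence population disease prevalence (default 0.10).
#' @return binary \code{summary_table} covering every panel SNP.
#' @export
simulate_outcome_study <- function(panel, truth, n_cases, n_controls,
                                   seed = 1, prevalence = 0.10) {
  stopifnot(inherits(panel, "reference_panel"),
            n_cases >= 500, n_controls >= 500)
  arch <- .expression_architecture(panel, truth)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_pop <- ceiling(1.15 * max(n_cases / prevalence,
                              n_controls / (1 - prevalence)))
  g <- .simulate_haplotype_dosages(n_pop, panel$maf, panel$ld_decay)
  gscore <- if (length(arch$idx)) {
    as.numeric(g[, arch$idx, drop = FALSE] %*% arch$w) * arch$scale
  } else rep(0, n_pop)
  eta <- truth$theta * gscore
  if (length(truth$pleiotropy)) {
    pidx <- match(names(truth$pleiotropy), panel$snp_meta$snp_id)
    if (anyNA(pidx)) stop("pleiotropy names must be panel SNP ids")
    eta <- eta + as.numeric(g[, pidx, drop = FALSE] %*% truth$pleiotropy)
  }
  liability <- eta + stats::rlogis(n_pop)
  thresh <- stats::quantile(liability, 1 - prevalence, names = FALSE)
  is_case <- liability > thresh
  case_pool <- which(is_case)
  control_pool <- which(!is_case)
  if (length(case_pool) < n_cases || length(control_pool) < n_controls) {
    stop("simulated population too small for requested case/control counts")
  }
  sel <- c(sample(case_pool, n_cases), sample(control_pool, n_controls))
  y <- c(rep(1, n_cases), rep(0, n_controls))
  gs <- g[sel, , drop = FALSE]

  # logistic score statistic: U = sum g (y - ybar), V = ybar(1-ybar) Sxx
  ybar <- mean(y)
  gc_ <- scale(gs, center = TRUE, scale = FALSE)
  sxx <- colSums(gc_^2)
  sxx[sxx == 0] <- NA_real_
  u <- as.numeric(crossprod(gs, y - ybar))
  v <- ybar * (1 - ybar) * sxx
  beta <- u / v
  se <- 1 / sqrt(v)
  z <- beta / se
  pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  rec <- panel$snp_meta
  rec$eaf <- colMeans(gs) / 2
  rec$beta <- beta
  rec$se <- se
  rec$pval <- pval
  rec$n <- n_cases + n_controls
  rec$n_cases <- n_cases
  rec$n_controls <- n_controls
  rec <- rec[is.finite(rec$beta) & is.finite(rec$se) & rec$se > 0, ]
  summary_table(rec, trait_type = "binary",
                trait_label = "disease", source_label = "simulated")
}

#' Build a preset simulation scenario
#'
#' Desk-scale bundles (at most 200 SNPs, at most 20,000 simulated
#' individuals per study) exercising the causal configurations the pipeline
#' must distinguish. Labels mirror the colocalization hypotheses:
#' \describe{
#'   \item{h0}{no causal variant for either trait.}
#'   \item{h1 / h2}{a causal variant for expression only / outcome only
#'     (outcome-only association implemented as a pleiotropic SNP effect).}
#'   \item{h3}{two distinct causal variants in LD (panel r-squared ~ 0.5),
#'     one driving expression, the other the outcome.}
#'   \item{h4}{one shared causal variant driving both traits.}
#'   \item{null}{10 strong, valid eQTL instruments; theta = 0.}
#'   \item{causal}{10 strong, valid instruments; theta = 0.2.}
#'   \item{invalid_mix}{as causal, but 40\% of the instruments also carry
#'     direct pleiotropic outcome effects.}
#' }
#'
#' @param name scenario label.
#' @param seed integer seed controlling panel and both studies.
#' @return list with \code{panel}, \code{exposure} (quantitative
#'   \code{summary_table}), \code{outcome} (binary \code{summary_table}) and
#'   \code{truth}.
#' @export
make_scenario <- function(name = c("h0", "h1", "h2", "h3", "h4",
                                   "null", "causal", "invalid_mix"),
                          seed = 1) {
  name <- match.arg(name)
  multi <- name %in% c("null", "causal", "invalid_mix")
  if (multi) {
    n_snps <- 60L
    panel <- simulate_reference_panel(500, n_snps, ld_decay = 0.2,
                                      maf_range = c(0.1, 0.5), seed = seed)
    causal_ids <- panel$snp_meta$snp_id[seq(3, 57, by = 6)]  # 10 spread out
    theta <- if (name == "causal" || name == "invalid_mix") 0.2 else 0
    pleio <- numeric(0)
    if (name == "invalid_mix") {
      old <- .Random.seed_save()
      set.seed(seed + 7L)
      bad <- sample(causal_ids, 4)  # 40% of the 10 instruments
      pleio <- stats::setNames(stats::runif(4, 0.05, 0.12) *
                                 sample(c(-1, 1), 4, replace = TRUE), bad)
      .Random.seed_restore(old)
    }
    truth <- simulation_truth(theta = theta, causal_eqtl_ids = causal_ids,
                              h2_cis = 0.3, pleiotropy = pleio,
                              scenario = name, seed = seed)
    exposure <- simulate_expression_study(panel, truth, n = 6000,
                                          seed = seed + 1L)
    outcome <- simulate_outcome_study(panel, truth, n_cases = 1000,
                                      n_controls = 5000, seed = seed + 2L)
    return(list(panel = panel, exposure = exposure, outcome = outcome,
                truth = truth))
  }

  # regional (colocalization) presets: one 100-SNP cis region, strong LD
  panel <- simulate_reference_panel(600, 100, ld_decay = 0.9,
                                    maf_range = c(0.1, 0.5), seed = seed)
  mid <- 50L
  mid_id <- panel$snp_meta$snp_id[mid]
  truth <- switch(
    name,
    h0 = simulation_truth(scenario = "h0", seed = seed),
    h1 = simulation_truth(theta = 0, causal_eqtl_ids = mid_id, h2_cis = 0.15,
                          scenario = "h1", seed = seed),
    h2 = simulation_truth(pleiotropy = stats::setNames(0.35, mid_id),
                          scenario = "h2", seed = seed),
    h4 = simulation_truth(theta = 0.8, causal_eqtl_ids = mid_id,
                          h2_cis = 0.15, scenario = "h4", seed = seed),
    h3 = {
      # pick the partner whose panel r2 with the mid SNP is closest to 0.5
      r2 <- as.numeric(stats::cor(panel$dosages[, mid],
                                  panel$dosages)^2)
      r2[mid] <- NA
      partner <- which.min(abs(r2 - 0.5))
      simulation_truth(
        theta = 0, causal_eqtl_ids = mid_id, h2_cis = 0.15,
        pleiotropy = stats::setNames(0.35, panel$snp_meta$snp_id[partner]),
        scenario = "h3", seed = seed
      )
    }
  )
  exposure <- simulate_expression_study(panel, truth, n = 8000,
                                        seed = seed + 1L)
  outcome <- simulate_outcome_study(panel, truth, n_cases = 1800,
                                    n_controls = 9000, seed = seed + 2L)
  list(panel = panel, exposure = exposure, outcome = outcome, truth = truth)
}

#' Write a scenario bundle to a directory as TSV plus a truth file
#'
#' @param bundle result of \code{\link{make_scenario}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly. Files: \code{exposure.tsv},
#'   \code{outcome.tsv}, \code{panel.tsv}, \code{truth.json}.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(bundle$exposure, file.path(dir, "exposure.tsv"))
  write_table(bundle$outcome, file.path(dir, "outcome.tsv"))
  write_panel(bundle$panel, file.path(dir, "panel.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(theta = truth$theta, causal_eqtl_ids = truth$causal_eqtl_ids,
         h2_cis = truth$h2_cis,
         pleiotropy = as.list(truth$pleiotropy),
         scenario = truth$scenario, seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write / read a reference panel as TSV
#'
#' Rows are SNPs: five metadata columns followed by one integer dosage
#' column per panel individual.
#'
#' @param panel a \code{reference_panel}.
#' @param path file path.
#' @return \code{path} / a \code{reference_panel} (with \code{maf} recomputed
#'   from the dosages and \code{ld_decay} unknown).
#' @export
write_panel <- function(panel, path) {
  df <- panel$snp_meta
  dmat <- t(panel$dosages)
  colnames(dmat) <- sprintf("ind%04d", seq_len(nrow(panel$dosages)))
  out <- cbind(df, as.data.frame(dmat))
  write_table(out, path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  stopifnot(all(meta_cols %in% names(raw)))
  dcols <- setdiff(names(raw), meta_cols)
  dos <- t(as.matrix(raw[, dcols, drop = FALSE]))
  storage.mode(dos) <- "double"
  colnames(dos) <- raw$snp_id
  rownames(dos) <- NULL
  maf <- colMeans(dos) / 2
  maf <- pmin(maf, 1 - maf)
  panel <- list(dosages = dos,
                snp_meta = raw[, meta_cols],
                maf = maf, ld_decay = NA_real_, seed = NA_integer_)
  class(panel) <- "reference_panel"
  panel
}
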