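# Shared fixture builders: everything is generated in code, no stored data.

make_records <- function(n = 3, chrom = "1", pos = NULL, pval = NULL,
                         beta = NULL, se = NULL, eaf = NULL,
                         effect_allele = NULL, other_allele = NULL,
                         n_samples = 10000) {
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = if (is.null(pos)) 1e6 + seq_len(n) * 1000 else pos,
    effect_allele = if (is.null(effect_allele)) rep("A", n) else effect_allele,
    other_allele = if (is.null(other_allele)) rep("G", n) else other_allele,
    eaf = if (is.null(eaf)) rep(0.3, n) else eaf,
    beta = if (is.null(beta)) seq(0.1, 0.1 + 0.05 * (n - 1), by = 0.05) else beta,
    se = if (is.null(se)) rep(0.01, n) else se,
    pval = if (is.null(pval)) rep(1e-10, n) else pval,
    n = n_samples,
    stringsAsFactors = FALSE
  )
}

make_table <- function(..., trait_type = "quantitative") {
  summary_table(make_records(...), trait_type = trait_type)
}

make_harmonised <- function(bx, sx, by, sy) {
  data.frame(
    snp_id = sprintf("rs%03d", seq_along(bx)),
    bx = bx, sx = sx, by = by, sy = sy,
    stringsAsFactors = FALSE
  )
}

# plain-arithmetic enumeration oracle for colocalization posteriors on
# small regions (no log-sum-exp; double loop for the two-variant sum)
naive_posteriors <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  b1 <- exp(l1); b2 <- exp(l2)
  s1 <- sum(b1); s2 <- sum(b2); s4 <- sum(b1 * b2)
  s3 <- 0
  for (i in seq_along(b1)) {
    for (j in seq_along(b2)) {
      if (i != j) s3 <- s3 + b1[i] * b2[j]
    }
  }
  raw <- c(1, p1 * s1, p2 * s2, p1 * p2 * s3, p12 * s4)
  raw / sum(raw)
}

# instrument -> harmonised -> IVW on a multi-SNP scenario bundle
scenario_ivw <- function(sc, window_locus = NULL) {
  locus <- if (is.null(window_locus)) {
    meta <- sc$panel$snp_meta
    gene_locus("G", meta$chrom[1], min(meta$pos), max(meta$pos))
  } else window_locus
  cand <- select_cis_candidates(sc$exposure, locus)
  if (nrow(cand) == 0) return(NULL)
  ld <- ld_matrix(sc$panel, cand$snp_id)
  inst <- clump(cand, ld)
  h <- harmonise(inst, sc$outcome)
  if (nrow(h$snps) == 0) return(NULL)
  ivw(h)
}

# a synthetic multi-gene dataset: one AR(1) panel of n_genes 10-SNP blocks;
# the first `n_active` genes carry causal eQTLs in their block (a mix of
# 1-, 2- and 3-SNP architectures so the pipeline exercises both the
# single-SNP Wald path and the multi-SNP estimators), the rest are null.
make_multigene_fixture <- function(n_genes = 20, n_active = 14, seed = 42,
                                   theta = 0.2) {
  n_snps <- n_genes * 10L
  panel <- simulate_reference_panel(400, n_snps, ld_decay = 0.2,
                                    maf_range = c(0.15, 0.5), seed = seed,
                                    pos_step = 10000)
  centers <- 10L * (seq_len(n_genes) - 1L) + 5L
  causal_idx <- unlist(lapply(seq_len(n_active), function(g) {
    base <- 10L * (g - 1L)
    if (g <= 7) base + 5L                      # single causal eQTL
    else if (g <= 12) base + c(3L, 8L)         # two, weak mutual LD
    else base + c(2L, 5L, 8L)                  # three
  }))
  causal <- panel$snp_meta$snp_id[causal_idx]
  truth <- simulation_truth(theta = theta, causal_eqtl_ids = causal,
                            h2_cis = 0.45, scenario = "custom", seed = seed)
  exposure <- simulate_expression_study(panel, truth, n = 6000,
                                        seed = seed + 1L)
  outcome <- simulate_outcome_study(panel, truth, n_cases = 1000,
                                    n_controls = 4000, seed = seed + 2L)
  genes <- lapply(seq_len(n_genes), function(g) {
    center_pos <- panel$snp_meta$pos[centers[g]]
    gene_locus(sprintf("G%02d", g), panel$snp_meta$chrom[1],
               center_pos, center_pos)
  })
  list(panel = panel, exposure = exposure, outcome = outcome,
       truth = truth, genes = genes)
}

make_multigene_config <- function(fix, seed = 1, ...) {
  pipeline_config(
    genes = fix$genes,
    exposures = list(list(label = "tissueA", table = fix$exposure)),
    outcomes = list(list(label = "disease", table = fix$outcome,
                         n_cases = 1000, n_controls = 4000)),
    panel = fix$panel,
    window_bp = 40000, seed = seed, n_boot = 100, ...
  )
}
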