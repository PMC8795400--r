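---
title: "Two-sample MR of gene expression on disease risk: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR of gene expression on disease risk: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprmr)
```

## The problem

`exprmr` estimates the causal effect of a gene's expression level on the
risk of a binary disease from two independent sets of summary statistics:
a cis-eQTL study giving per-SNP effects on expression (in SD units), and a
case-control GWAS giving per-SNP effects on disease (log odds ratios).
Germline genotype is fixed at conception, so SNPs that robustly alter
expression can serve as instrumental variables: under the usual
instrumental-variable assumptions (relevance, no confounding of the
SNP-outcome relationship, no effect on the outcome except through
expression) the ratio of outcome to exposure effects identifies the causal
log-odds change per SD of expression.

## Instrument construction

Candidate instruments are cis SNPs — within 1 Mb of the gene's midpoint, a
closed interval, following the convention of the large blood-eQTL
meta-analyses — with eQTL association $P < 5\times10^{-8}$ (strict
inequality). Two instruments are built per gene:

* **top SNP** (primary): the single smallest-$P$ candidate, with ties
  broken by larger $|z|$ and then SNP id (the selection must be
  deterministic; the sources we model do not state a tie rule);
* **multi-SNP** (secondary): greedy LD clumping at $r^2 \le 0.01$ against
  a genotype reference panel — accept the best remaining SNP, drop
  everything in LD with it, repeat.

Instrument strength uses the z-statistic identity
$R^2 = z^2/(z^2 + n - 2)$ and $F = R^2 (n-2)/(1-R^2)$, which reduces to
$F = z^2$ for one SNP. We compute $R^2$ from $z$ rather than from allele
frequency because frequency is optional in public summary files; for a
unit-variance trait the two routes agree asymptotically and the package
tests that property on simulated data. Genes with no candidate are
reported and skipped, and the multiple-testing denominator counts only
analysable genes.

## Harmonisation

Effects are aligned to a common effect allele per SNP. Swapped allele
pairs flip the sign of the outcome beta and complement its frequency.
Palindromic SNPs (A/T, C/G) cannot be strand-resolved from alleles alone:
they are retained only when both allele frequencies are available, both
minor-allele frequencies are below 0.42, and the frequencies are
concordant after orientation; otherwise they are excluded with an audit
reason. The 0.42 bound is the default of the standard two-sample-MR
harmonisation framework; frequency-based resolution near 0.5 is
unreliable, and dropping ambiguous SNPs is the conservative choice.

## Estimators

With $\hat\beta_{Xj}, \hat\beta_{Yj}$ the harmonised per-SNP effects and
$\sigma_{Yj}$ the outcome SE:

* **Wald ratio** (single SNP): $\hat\theta = \hat\beta_Y/\hat\beta_X$ with
  first-order delta SE $\sigma_Y/|\hat\beta_X|$, the summary-MR platform
  default; a second-order form adding the exposure-noise term is available
  behind a flag. With strong instruments ($F$ in the hundreds) the two are
  nearly identical.
* **IVW**: weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin with weights $1/\sigma_{Yj}^2$, equal to the inverse-variance
  meta-analysis of the per-SNP Wald ratios. We use the multiplicative
  random-effects model: the fixed-effect SE is multiplied by the residual
  scale $\sqrt{Q/(n-1)}$ when it exceeds 1 and left alone when the
  regression is underdispersed (floor at 1). The floor is specific to the
  multiplicative model, which is why that model is used rather than an
  additive one.
* **Cochran's Q**: $\sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$ with
  $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$, referred to $\chi^2_{n-1}$.
* **MR-Egger** (≥ 3 SNPs): the same weighted regression with an intercept,
  after orienting all SNPs to positive exposure effect; the intercept is
  the directional-pleiotropy test.
* **Weighted median** (≥ 3 SNPs): the per-SNP ratio at cumulative
  normalized weight 0.5, interpolating between the cumulative-weight
  midpoints; consistent when valid instruments carry half the weight.
* **Weighted mode** (≥ 3 SNPs): argmax of the weighted normal-kernel
  density of the ratios with bandwidth
  $0.9\,\min(\mathrm{sd},\mathrm{mad})\,n^{-1/5}$ times a user factor.
  The cited method names no tuning rule, so the modified Silverman rule is
  a documented package choice.

Median and mode SEs come from a seeded parametric bootstrap (default 1000
draws of $\hat\beta_X, \hat\beta_Y$ from their sampling distributions).
All P-values use the normal approximation, the summary-data convention.
`sensitivity_scan()` returns per-SNP ratios, leave-one-out IVW series and
funnel coordinates as plain data frames; plotting is left to the user.

## Colocalization

An MR hit can reflect two different causal variants in LD rather than one
shared variant. For the cis region around the top eQTL we compute
Wakefield-style per-SNP log approximate Bayes factors
$\tfrac12[\log(1-r) + r z^2]$, $r = W/(W + \mathrm{se}^2)$, and combine
them by log-sum-exp into posteriors for the five standard hypotheses (no
signal; exposure only; outcome only; two distinct variants; one shared
variant). Priors are the conventional $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$, with effect-prior SDs $W = 0.15$ (quantitative) and
$0.2$ (log-odds) — the defaults of the colocalization method this module
follows, since the analyses we model print no priors. The two-distinct
sum uses the identity $S_3 = S_1 S_2 - S_4$; a test checks it against the
explicit double loop. Single-SNP regions set $S_3 = 0$ and are flagged.
The single-causal-variant-per-trait assumption is inherited and is the
main limitation.

## Power and multiple testing

For a case-control outcome with $N$ samples and case fraction $\phi$, the
noncentrality of the instrumented test of an odds ratio $\mathrm{OR}_1$ is
$\sqrt{N R^2 \phi(1-\phi)}\,|\ln \mathrm{OR}_1|$, giving
$\mathrm{power} = \Phi(\mathrm{ncp} - z_{1-\alpha/2})$. Power is exactly
symmetric in $\mathrm{OR}_1 \leftrightarrow 1/\mathrm{OR}_1$. This
normal-approximation form reproduces the published power table we
validate against from its printed $R^2$ and case/control counts, to
within the rounding of the printed inputs. Evidence tiers use the exact
Bonferroni boundary $\alpha/n_{\text{tests}}$ with $n_{\text{tests}}$
recomputed as the number of genes that yielded at least one instrument.

## The synthetic-data generator

Every stochastic claim in the test suite runs on simulated data with
known truth, because the real eQTL/GWAS inputs are access-controlled and
far beyond desk scale.

* **Genotypes**: haplotypes carry a latent standard-normal AR(1) series
  along SNPs; the allele indicator thresholds the latent value at the MAF
  quantile, and dosages are haplotype sums. This gives geometrically
  decaying LD — enough to exercise clumping and colocalization, though it
  reproduces neither recombination hotspots nor real human LD blocks.
* **Expression**: linear in the causal dosages plus Gaussian noise,
  scaled so the causal SNPs explain exactly `h2_cis` of variance, then
  standardized to unit SD so betas are in SD units.
* **Outcome**: liability equals `theta` times the genetic expression
  score plus per-SNP pleiotropic effects plus standard-logistic noise;
  case status thresholds the liability at the 10% population-prevalence
  quantile and cases/controls are then sampled (threshold-then-sample
  ascertainment). Logistic noise makes the conditional per-SNP effects
  exact log odds ratios, so case-control sampling does not bias them and
  the marginal per-SNP log-OR is `theta` times the exposure beta up to a
  negligible non-collapsibility term. Per-SNP statistics use the logistic
  score statistic, matching how GWAS consortia produce log-OR/SE.

Preset scenarios fix the study conditions: `causal` (10 independent
eQTLs, `theta = 0.2`, `h2_cis = 0.3`, eQTL n = 6,000, 1,000 cases /
5,000 controls), `null` (same with `theta = 0`), `invalid_mix` (40% of
instruments get direct outcome effects), and the regional presets
`h0`–`h4` (100 SNPs, strong LD, eQTL n = 8,000, 1,800 cases / 9,000
controls; `h4` plants one shared variant, `h3` picks a partner SNP whose
panel $r^2$ is nearest 0.5). All sizes are desk-scale — at most 200 SNPs
and 20,000 simulated individuals per study — chosen so a replicate runs
in well under a second while leaving the preset effects comfortably
detectable; the 200-replicate causal recovery and 500-replicate null
calibration in the acceptance suite use exactly these presets. The `h4`
preset's `theta = 0.8` is deliberately large so the outcome signal at
desk-scale case counts is strong enough for colocalization to be
decisive.

What passing these tests shows is that the estimators, diagnostics and
posteriors behave correctly under the model they assume. It does not show
robustness to real-data features the generator omits: sample overlap
between the two studies, population stratification, imputation error,
winner's curse from discovery-and-use of the same eQTL study, or
realistic LD.

## Numerical choices and edge cases

* Coordinates are 1-based; all windows are closed intervals.
* Posterior arithmetic is in log space; sums to 1 are tested at 1e-10.
* An exposure effect of exactly zero makes the Wald ratio undefined and
  is an error, not an NA.
* A panel SNP drawn monomorphic (rare at the default MAF range) has one
  dosage toggled so LD is always defined.
* `write_table()` fixes column order and prints floats at 6 significant
  digits (P-values in scientific notation), so identical analyses produce
  byte-identical outputs; round-trips through TSV agree to that
  precision.
* Bootstrap seeds are explicit arguments; the pipeline threads one seed
  through every stochastic step, so a config fully determines the report.

## A worked run

```{r example, eval = FALSE}
sc <- make_scenario("causal", seed = 11)
locus <- gene_locus("GENE1", "1", 1e6, 1.59e6)
cand <- select_cis_candidates(sc$exposure, locus)
inst <- clump(cand, ld_matrix(sc$panel, cand$snp_id))
h <- harmonise(inst, sc$outcome)
mr_all(h, n_boot = 200, seed = 1)
```

## Known limitations

No proxy-SNP lookup for instrument SNPs missing from the outcome; no
correlated-SNP (generalized) IVW, so clumping must precede estimation; no
multivariable MR or outlier-removal estimators; colocalization assumes at
most one causal variant per trait per region; the power formula is the
binary-outcome normal approximation only.
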