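test_that("reference panels are reproducible by seed and vary across seeds", {
  p1 <- simulate_reference_panel(60, 20, ld_decay = 0.5, seed = 9)
  p2 <- simulate_reference_panel(60, 20, ld_decay = 0.5, seed = 9)
  p3 <- simulate_reference_panel(60, 20, ld_decay = 0.5, seed = 10)
  expect_identical(p1$dosages, p2$dosages)
  expect_false(identical(p1$dosages, p3$dosages))
  expect_true(all(p1$dosages %in% 0:2))
  freqs <- colMeans(p1$dosages) / 2
  expect_true(all(freqs > 0 & freqs < 1))  # no monomorphic SNP
})

test_that("LD structure follows the autoregressive decay", {
  # independent SNPs: off-diagonal correlations are sampling noise
  p0 <- simulate_reference_panel(400, 30, ld_decay = 0, seed = 21)
  r0 <- stats::cor(p0$dosages)
  off <- abs(r0[upper.tri(r0)])
  expect_lt(mean(off), 3 / sqrt(400))

  # strong decay: adjacent pairs carry more LD than lag-5 pairs
  p9 <- simulate_reference_panel(400, 30, ld_decay = 0.9, seed = 22)
  r9 <- stats::cor(p9$dosages)^2
  adj <- mean(r9[cbind(1:29, 2:30)])
  lag5 <- mean(r9[cbind(1:25, 6:30)])
  expect_gt(adj, lag5)
})

test_that("degenerate generator parameters are rejected", {
  expect_error(simulate_reference_panel(60, 5, maf_range = c(0.4, 0.2)),
               "maf_range")
  expect_error(simulate_reference_panel(60, 5, ld_decay = 1), "ld_decay")
  expect_error(simulation_truth(theta = 0.2), "causal")
  expect_error(simulation_truth(causal_eqtl_ids = "rs00001", h2_cis = 0),
               "h2_cis")
})

test_that("a planted single eQTL recovers its cis-heritability two ways", {
  panel <- simulate_reference_panel(300, 10, ld_decay = 0, seed = 31)
  truth <- simulation_truth(causal_eqtl_ids = "rs00003", h2_cis = 0.05,
                            seed = 31)
  tab <- simulate_expression_study(panel, truth, n = 10000, seed = 32)
  rec <- tab$records[tab$records$snp_id == "rs00003", ]
  # route 1: variance explained from the z-statistic
  s <- instrument_strength(rec$beta, rec$se, rec$n)
  expect_equal(s$r2, 0.05, tolerance = 0.3)
  # route 2: 2 eaf (1 - eaf) beta^2 for a unit-variance trait
  r2_freq <- 2 * rec$eaf * (1 - rec$eaf) * rec$beta^2
  expect_equal(r2_freq, 0.05, tolerance = 0.3)
  expect_equal(s$r2, r2_freq, tolerance = 0.05)
  # non-causal, unlinked SNPs explain next to nothing
  others <- tab$records[tab$records$snp_id != "rs00003", ]
  expect_true(all(instrument_strength(others$beta, others$se,
                                      others$n)$r2 < 0.01))
})

test_that("expression tables under an empty causal set behave as null", {
  panel <- simulate_reference_panel(300, 40, ld_decay = 0, seed = 41)
  truth <- simulation_truth(seed = 41)
  hits <- 0L
  for (s in 1:3) {
    tab <- simulate_expression_study(panel, truth, n = 5000, seed = 100 + s)
    hits <- hits + sum(tab$records$pval < 5e-8)
  }
  expect_equal(hits, 0L)
})

test_that("null outcome z-scores are calibrated at the nominal rate", {
  panel <- simulate_reference_panel(300, 100, ld_decay = 0, seed = 51)
  truth <- simulation_truth(seed = 51)
  z <- unlist(lapply(1:5, function(s) {
    tab <- simulate_outcome_study(panel, truth, n_cases = 1000,
                                  n_controls = 4000, seed = 200 + s)
    tab$records$beta / tab$records$se
  }))
  rej <- mean(abs(z) > stats::qnorm(0.975))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  expect_lt(abs(mean(z)), 0.1)
})

test_that("outcome effects track theta times the exposure effects", {
  panel <- simulate_reference_panel(300, 10, ld_decay = 0, seed = 61)
  truth <- simulation_truth(theta = 0.2, causal_eqtl_ids = "rs00005",
                            h2_cis = 0.1, seed = 61)
  ex <- simulate_expression_study(panel, truth, n = 10000, seed = 62)
  # average outcome betas over replicates to beat the per-study noise
  bys <- vapply(1:8, function(s) {
    out <- simulate_outcome_study(panel, truth, n_cases = 2000,
                                  n_controls = 8000, seed = 300 + s)
    out$records$beta[out$records$snp_id == "rs00005"]
  }, numeric(1))
  bx <- ex$records$beta[ex$records$snp_id == "rs00005"]
  se_mean <- 0.03 / sqrt(8)  # per-study SE is ~0.03 at these counts
  expect_equal(mean(bys), 0.2 * bx, tolerance = 4 * se_mean / (0.2 * bx))
})

test_that("outcome studies are deterministic given the seed", {
  panel <- simulate_reference_panel(300, 10, ld_decay = 0.3, seed = 71)
  truth <- simulation_truth(theta = 0.3, causal_eqtl_ids = "rs00002",
                            h2_cis = 0.1, seed = 71)
  a <- simulate_outcome_study(panel, truth, 800, 800, seed = 5)
  b <- simulate_outcome_study(panel, truth, 800, 800, seed = 5)
  c <- simulate_outcome_study(panel, truth, 800, 800, seed = 6)
  expect_identical(a$records, b$records)
  expect_false(identical(a$records, c$records))
})

test_that("scenario presets honour their contracts", {
  sc <- make_scenario("causal", seed = 3)
  expect_equal(sc$truth$theta, 0.2)
  expect_length(sc$truth$causal_eqtl_ids, 10L)
  expect_true(all(sc$truth$causal_eqtl_ids %in% sc$panel$snp_meta$snp_id))
  expect_identical(sc$exposure$trait_type, "quantitative")
  expect_identical(sc$outcome$trait_type, "binary")

  h0 <- make_scenario("h0", seed = 3)
  expect_gt(min(h0$exposure$records$pval), 5e-8)
  expect_gt(min(h0$outcome$records$pval), 5e-8)

  h3 <- make_scenario("h3", seed = 3)
  causal_pair <- c(h3$truth$causal_eqtl_ids, names(h3$truth$pleiotropy))
  r2 <- ld_matrix(h3$panel, causal_pair)[1, 2]
  expect_gte(r2, 0.3)
  expect_lte(r2, 0.7)

  mix <- make_scenario("invalid_mix", seed = 3)
  expect_length(mix$truth$pleiotropy, 4L)  # 40% of 10 instruments
  expect_true(all(names(mix$truth$pleiotropy) %in%
                    mix$truth$causal_eqtl_ids))
})

test_that("scenario bundles round-trip through the scenario writer", {
  sc <- make_scenario("causal", seed = 8)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("exposure.tsv", "outcome.tsv", "panel.tsv", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$theta, 0.2)
  panel <- read_panel(file.path(dir, "panel.tsv"))
  expect_identical(unname(panel$dosages), unname(sc$panel$dosages))
  back <- read_sumstats(file.path(dir, "exposure.tsv"),
                        trait_type = "quantitative")
  expect_equal(back$records$beta, sc$exposure$records$beta,
               tolerance = 1e-5)
})
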