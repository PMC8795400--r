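test_that("Wald ratio handles the null and the delta-method SE", {
  est <- wald_ratio(bx = 0.5, sx = 0.02, by = 0, sy = 0.01)
  expect_equal(est$beta, 0)
  expect_equal(est$or_, 1.0)
  expect_equal(est$se, 0.02)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.01), "zero")
})

test_that("Wald ratio is invariant to a joint sign flip", {
  a <- wald_ratio(0.4, 0.02, 0.0233, 0.006)
  b <- wald_ratio(-0.4, 0.02, -0.0233, 0.006)
  expect_equal(a$beta, b$beta)
  expect_equal(a$se, b$se)
  expect_equal(a$pval, b$pval)
})

test_that("Wald ratio SEs agree with Monte-Carlo error propagation", {
  bx <- 0.4; sx <- 0.02; by <- 0.0233; sy <- 0.006
  est1 <- wald_ratio(bx, sx, by, sy)
  expect_equal(est1$beta, 0.05825, tolerance = 1e-10)
  expect_equal(est1$se, 0.015, tolerance = 1e-10)
  expect_equal(est1$or_, 1.060, tolerance = 1e-3)
  est2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
  withr::with_seed(99, {
    sim <- rnorm(2e5, by, sy) / rnorm(2e5, bx, sx)
    expect_equal(est2$se, sd(sim), tolerance = 0.05)
  })
  expect_gt(est2$se, est1$se)  # exposure noise only adds uncertainty
})

test_that("IVW on one SNP equals the Wald ratio exactly", {
  h <- make_harmonised(bx = 0.4, sx = 0.02, by = 0.02, sy = 0.006)
  w <- wald_ratio(0.4, 0.02, 0.02, 0.006)
  i <- ivw(h)
  expect_identical(i$beta, w$beta)
  expect_identical(i$se, w$se)
})

test_that("identical ratios give the common ratio, Q = 0, scale floored", {
  h <- make_harmonised(bx = c(0.2, 0.4, 0.5), sx = rep(0.01, 3),
                       by = c(0.06, 0.12, 0.15), sy = c(0.01, 0.02, 0.01))
  est <- ivw(h)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$extras$scale, 1)
  q <- cochran_q(h, est$beta)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
})

test_that("IVW equals the closed-form meta-analysis of Wald ratios", {
  h <- make_harmonised(bx = c(0.31, 0.22, 0.45, 0.18, 0.29),
                       sx = rep(0.02, 5),
                       by = c(0.065, 0.041, 0.088, 0.044, 0.050),
                       sy = c(0.012, 0.02, 0.015, 0.025, 0.01))
  ratios <- h$by / h$bx
  w <- (h$bx / h$sy)^2
  oracle <- sum(w * ratios) / sum(w)
  est <- ivw(h)
  expect_equal(est$beta, oracle, tolerance = 1e-12)
  # fixed-effect SE from meta-analysis weights, before any scaling
  expect_equal(est$se / est$extras$scale, 1 / sqrt(sum(w)),
               tolerance = 1e-12)
})

test_that("Cochran's Q matches hand arithmetic and the WLS identity", {
  # two SNPs with ratios 0 and 1, equal weights (bx/sy)^2 = 4
  h <- make_harmonised(bx = c(2, 2), sx = c(0.1, 0.1),
                       by = c(0, 2), sy = c(1, 1))
  est <- ivw(h)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  q <- cochran_q(h, est$beta)
  expect_equal(q$q, 2, tolerance = 1e-12)
  expect_equal(q$df, 1L)

  # Q equals the weighted RSS of the origin regression (via stats::lm)
  h2 <- make_harmonised(bx = c(0.3, 0.5, 0.2, 0.4), sx = rep(0.02, 4),
                        by = c(0.1, 0.12, 0.03, 0.09),
                        sy = c(0.01, 0.02, 0.015, 0.012))
  fit <- stats::lm(by ~ bx - 1, data = h2, weights = 1 / h2$sy^2)
  rss_w <- sum((1 / h2$sy^2) * residuals(fit)^2)
  expect_equal(cochran_q(h2)$q, rss_w, tolerance = 1e-10)
  expect_error(cochran_q(make_harmonised(0.3, 0.01, 0.1, 0.01)),
               "insufficient")
})

test_that("MR-Egger matches the normal-equations oracle", {
  h <- make_harmonised(bx = c(0.2, 0.35, 0.5), sx = rep(0.02, 3),
                       by = c(0.07, 0.10, 0.16), sy = c(0.01, 0.02, 0.012))
  est <- mr_egger(h)
  # independent route: solve the 2x2 weighted normal equations directly
  w <- 1 / h$sy^2
  X <- cbind(1, h$bx)
  coefs <- solve(t(X) %*% (w * X), t(X) %*% (w * h$by))
  expect_equal(est$extras$intercept, coefs[1], tolerance = 1e-10)
  expect_equal(est$beta, coefs[2], tolerance = 1e-10)
  # and against stats::lm
  fit <- stats::lm(by ~ bx, data = h, weights = w)
  expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_error(mr_egger(h[1:2, ]), "3")
})

test_that("a constant pleiotropic offset moves the Egger intercept only", {
  h <- make_harmonised(bx = c(0.2, 0.35, 0.5, 0.27, 0.44),
                       sx = rep(0.02, 5),
                       by = c(0.07, 0.10, 0.16, 0.08, 0.13),
                       sy = c(0.01, 0.02, 0.012, 0.015, 0.011))
  base <- mr_egger(h)
  shifted <- h
  shifted$by <- h$by + 0.05
  est <- mr_egger(shifted)
  expect_equal(est$beta, base$beta, tolerance = 1e-10)
  expect_equal(est$extras$intercept, base$extras$intercept + 0.05,
               tolerance = 1e-10)
})

test_that("the Egger intercept is null-behaved without pleiotropy", {
  withr::with_seed(17, {
    bx <- runif(20, 0.1, 0.5)
    sy <- runif(20, 0.01, 0.03)
    by <- 0.25 * bx + rnorm(20, 0, sy)
    h <- make_harmonised(bx, rep(0.01, 20), by, sy)
    est <- mr_egger(h)
    expect_lt(abs(est$extras$intercept), 3 * est$extras$intercept_se)
    expect_gt(est$extras$intercept_pval, 0.001)
  })
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  # all ratios equal: estimate is that ratio
  h0 <- make_harmonised(bx = c(0.2, 0.3, 0.4), sx = rep(0.01, 3),
                        by = c(0.05, 0.075, 0.1), sy = c(0.01, 0.015, 0.02))
  expect_equal(weighted_median(h0, n_boot = 50, seed = 1)$beta, 0.25,
               tolerance = 1e-12)
  # equal weights, ratios {0.1, 0.2, 0.9}: cumulative midpoints
  # {1/6, 3/6, 5/6} put weight 0.5 exactly on the middle ratio
  h1 <- make_harmonised(bx = c(1, 1, 1), sx = rep(0.01, 3),
                        by = c(0.1, 0.2, 0.9), sy = c(1, 1, 1))
  expect_equal(weighted_median(h1, n_boot = 50, seed = 1)$beta, 0.2,
               tolerance = 1e-12)
})

test_that("weighted median resists a pleiotropic minority better than IVW", {
  bx <- rep(0.3, 10)
  sy <- rep(0.05, 10)
  by <- 0.2 * bx
  by[7:10] <- by[7:10] + 0.15  # 4 of 10 SNPs carry direct outcome effects
  h <- make_harmonised(bx, rep(0.01, 10), by, sy)
  est_ivw <- ivw(h)
  est_med <- weighted_median(h, n_boot = 100, seed = 2)
  expect_lt(abs(est_med$beta - 0.2), abs(est_ivw$beta - 0.2))
  expect_equal(est_med$beta, 0.2, tolerance = 0.05)
})

test_that("weighted mode finds the majority mode and ignores SNP order", {
  h <- make_harmonised(
    bx = rep(0.3, 10), sx = rep(0.01, 10),
    by = 0.3 * c(0.19, 0.2, 0.21, 0.2, 0.18, 0.22, 0.2, 0.9, 0.88, 0.92),
    sy = rep(0.01, 10)
  )
  est <- weighted_mode(h, n_boot = 50, seed = 3)
  ratios <- h$by / h$bx
  w <- (h$bx / h$sy)^2
  s <- 0.9 * min(sd(ratios), mad(ratios)) / 10^0.2
  expect_equal(est$beta, 0.2, tolerance = s)  # within one bandwidth
  # grid-search argmax oracle over the weighted kernel density
  grid <- seq(min(ratios) - 3 * s, max(ratios) + 3 * s, length.out = 8001)
  dens <- vapply(grid, function(x) {
    sum(w / sum(w) * dnorm(x, ratios, s))
  }, numeric(1))
  expect_equal(est$beta, grid[which.max(dens)], tolerance = 2 * s)

  perm <- h[c(5, 9, 1, 10, 3, 7, 2, 8, 6, 4), ]
  expect_equal(weighted_mode(perm, n_boot = 50, seed = 3)$beta, est$beta,
               tolerance = 1e-12)
})

test_that("all estimators share the per-SNP sign-flip invariance", {
  withr::with_seed(23, {
    bx <- runif(6, 0.2, 0.5)
    by <- 0.3 * bx + rnorm(6, 0, 0.01)
    h <- make_harmonised(bx, rep(0.01, 6), by, rep(0.012, 6))
    flip <- rep(c(1, -1), 3)
    hf <- make_harmonised(bx * flip, rep(0.01, 6), by * flip, rep(0.012, 6))
    expect_equal(ivw(hf)$beta, ivw(h)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(hf)$beta, mr_egger(h)$beta, tolerance = 1e-12)
    expect_equal(weighted_median(hf, n_boot = 50, seed = 4)$beta,
                 weighted_median(h, n_boot = 50, seed = 4)$beta,
                 tolerance = 1e-12)
    expect_equal(weighted_mode(hf, n_boot = 50, seed = 4)$beta,
                 weighted_mode(h, n_boot = 50, seed = 4)$beta,
                 tolerance = 1e-12)
  })
})

test_that("Cochran's Q is chi-square calibrated under homogeneity", {
  withr::with_seed(31, {
    qs <- replicate(300, {
      bx <- runif(6, 0.2, 0.5)
      sy <- runif(6, 0.01, 0.02)
      by <- 0.25 * bx + rnorm(6, 0, sy)
      cochran_q(make_harmonised(bx, rep(0.005, 6), by, sy))$q
    })
    expect_equal(mean(qs), 5, tolerance = 0.15)  # df = nsnp - 1 = 5
  })
})

test_that("the sensitivity scan reduces correctly at nsnp = 2", {
  h <- make_harmonised(bx = c(0.3, 0.4), sx = c(0.01, 0.01),
                       by = c(0.09, 0.1), sy = c(0.01, 0.02))
  scan <- sensitivity_scan(h)
  # leaving one SNP out leaves the other's Wald ratio
  expect_equal(scan$leave_one_out$beta,
               c(0.1 / 0.4, 0.09 / 0.3), tolerance = 1e-12)
  expect_equal(scan$per_snp$beta, h$by / h$bx, tolerance = 1e-12)
  expect_equal(scan$funnel$precision, abs(h$bx) / h$sy, tolerance = 1e-12)
  expect_error(sensitivity_scan(h[1, ]), "2")
})

test_that("dropping one SNP from a homogeneous set barely moves IVW", {
  withr::with_seed(37, {
    bx <- runif(8, 0.2, 0.5)
    sy <- rep(0.015, 8)
    by <- 0.2 * bx + rnorm(8, 0, sy)
    h <- make_harmonised(bx, rep(0.01, 8), by, sy)
    full <- ivw(h)
    scan <- sensitivity_scan(h)
    expect_true(all(abs(scan$leave_one_out$beta - full$beta) < full$se))
  })
})

test_that("mr_all dispatches on instrument size", {
  h1 <- make_harmonised(0.4, 0.02, 0.02, 0.01)
  expect_identical(mr_all(h1)$method, "wald_ratio")
  h2 <- make_harmonised(c(0.4, 0.3), c(0.02, 0.02), c(0.02, 0.02),
                        c(0.01, 0.01))
  expect_identical(mr_all(h2)$method, "ivw")
  h5 <- make_harmonised(runif(5, 0.2, 0.4), rep(0.02, 5),
                        runif(5, 0.02, 0.1), rep(0.01, 5))
  expect_setequal(mr_all(h5, n_boot = 50)$method,
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
})
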