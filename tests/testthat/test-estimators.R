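test_that("wald_ratio implements the delta-method ratio", {
  r <- wald_ratio(0.2, 0.01, 0.4, 0.1)
  expect_equal(r$estimate, 2)
  expect_equal(r$se, 0.5)
  expect_lt(r$ci_low, r$estimate)
  expect_gt(r$ci_high, r$estimate)

  r0 <- wald_ratio(0.2, 0.01, 0, 0.1)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$pval, 1)

  # joint sign flip (allele relabeling) leaves the estimate unchanged
  expect_equal(wald_ratio(-0.2, 0.01, -0.4, 0.1)$estimate, 2)
  expect_error(wald_ratio(0, 0.01, 0.4, 0.1), "beta_x")
})

test_that("ivw equals the closed-form WLS through the origin", {
  h <- make_harmonized(bx = c(1, 1), sx = 0.01, by = c(0.5, 0.7), sy = 1)
  expect_equal(ivw(h)$estimate, 0.6)

  # general WLS oracle
  set.seed(2)
  bx <- rnorm(8, 0.1, 0.02); by <- rnorm(8, 0.03, 0.01)
  sy <- runif(8, 0.005, 0.02)
  h <- make_harmonized(bx, 0.005, by, sy)
  h$se_y <- sy
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  q <- sum(w * (by - theta * bx)^2)
  se <- sqrt(max(1, q / 7) / sum(w * bx^2))
  fit <- ivw(h)
  expect_equal(fit$estimate, theta)
  expect_equal(fit$se, se)
  expect_equal(fit$q, q)

  # single-SNP path equals the Wald ratio
  h1 <- make_harmonized(0.1, 0.01, 0.05, 0.02)
  f1 <- ivw(h1)
  expect_equal(f1$estimate, 0.5)
  expect_equal(f1$se, 0.2)
  expect_equal(f1$reason, "single_snp_wald_fallback")
})

test_that("egger recovers slope and intercept; degenerate input flagged", {
  # exact data with zero intercept: slope equals fixed-effect IVW
  bx <- c(0.05, 0.1, 0.2)
  by <- 0.4 * bx
  h <- make_harmonized(bx, 0.005, by, 0.01)
  e <- egger(h)
  expect_equal(e$estimate, 0.4, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(ivw(h)$estimate, 0.4, tolerance = 1e-10)

  # all beta_x equal: not estimable
  h <- make_harmonized(rep(0.1, 5), 0.005, rnorm(5, 0, 0.01), 0.01)
  e <- egger(h)
  expect_false(e$estimable)
  expect_equal(e$reason, "degenerate_beta_x")

  expect_false(egger(make_harmonized(1:2 / 10, 0.01, 1:2 / 20, 0.01))$estimable)
})

test_that("egger estimates directional pleiotropy (simulation)", {
  ints <- slopes <- numeric(200)
  for (r in 1:200) {
    truth <- sim_truth(n_snp = 50, theta = 0, n_x = 5e4, n_y = 1e5,
                       pleiotropy_mode = "directional", alpha_mean = 0.05,
                       frac_pleiotropic = 1, seed = 1000 + r)
    h <- sim_harmonized(truth)
    e <- egger(h)
    ints[r] <- e$egger_intercept
    slopes[r] <- e$estimate
  }
  expect_lt(abs(mean(ints) - 0.05), 0.01)
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("weighted median interpolates the weight-0.5 crossing", {
  # equal weights, ratios {1, 2, 9}: the median ratio
  h <- make_harmonized(bx = c(0.1, 0.1, 0.1), sx = 0.01,
                       by = c(0.1, 0.2, 0.9), sy = 0.01)
  wm <- weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(wm$estimate, 2)
  expect_gt(wm$se, 0)

  # identical ratios: estimate equals the common value, tiny bootstrap se
  h <- make_harmonized(bx = rep(0.2, 5), sx = 1e-6,
                       by = rep(0.08, 5), sy = 1e-6)
  wm <- weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(wm$estimate, 0.4, tolerance = 1e-6)
  expect_lt(wm$se, 1e-3)

  expect_false(weighted_median(make_harmonized(0.1, 0.01, 0.1, 0.01))$estimable)
})

test_that("mode estimator finds the majority mode with documented ties", {
  h <- make_harmonized(bx = rep(0.1, 4), sx = 0.001,
                       by = c(0.05, 0.05, 0.05, 0.5), sy = 0.001)
  m <- mode_estimator(h, weighted = FALSE, n_boot = 0)
  expect_lt(abs(m$estimate - 0.5), 0.1)

  # symmetric bimodal: the lower mode wins (smallest grid argmax)
  h <- make_harmonized(bx = rep(0.1, 4), sx = 0.001,
                       by = c(0.1, 0.1, 0.2, 0.2), sy = 0.001)
  m <- mode_estimator(h, weighted = FALSE, n_boot = 0)
  expect_lt(m$estimate, 1.5)
  expect_gt(m$estimate, 0.5)

  # zero bandwidth (all ratios equal): the common value
  h <- make_harmonized(bx = rep(0.1, 3), sx = 0.001,
                       by = rep(0.03, 3), sy = 0.001)
  m <- mode_estimator(h, weighted = TRUE, n_boot = 0)
  expect_equal(m$estimate, 0.3, tolerance = 1e-9)
})

test_that("scale equivariance and allele-flip invariance hold", {
  truth <- sim_truth(n_snp = 30, theta = 0.3, seed = 77)
  h <- sim_harmonized(truth)
  for (c_mult in c(2, 0.5)) {
    hc <- h
    hc$beta_y <- h$beta_y * c_mult
    hc$se_y <- h$se_y * c_mult
    expect_equal(ivw(hc)$estimate, c_mult * ivw(h)$estimate,
                 tolerance = 1e-10)
    expect_equal(egger(hc)$estimate, c_mult * egger(h)$estimate,
                 tolerance = 1e-10)
    expect_equal(weighted_median(hc, n_boot = 0)$estimate,
                 c_mult * weighted_median(h, n_boot = 0)$estimate,
                 tolerance = 1e-10)
  }
  # joint flips of a subset of SNPs
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), nrow(h), replace = TRUE)
  hf <- h
  hf$beta_x[flip] <- -h$beta_x[flip]
  hf$beta_y[flip] <- -h$beta_y[flip]
  expect_equal(ivw(hf)$estimate, ivw(h)$estimate, tolerance = 1e-10)
  expect_equal(egger(hf)$estimate, egger(h)$estimate, tolerance = 1e-10)
  expect_equal(weighted_median(hf, n_boot = 0)$estimate,
               weighted_median(h, n_boot = 0)$estimate, tolerance = 1e-10)
  expect_equal(mode_estimator(hf, n_boot = 0)$estimate,
               mode_estimator(h, n_boot = 0)$estimate, tolerance = 1e-10)
})

test_that("run_all_methods covers the six-result contract", {
  # single SNP: Wald ratio plus Steiger result only estimable entries
  h1 <- make_harmonized(0.1, 0.005, 0.03, 0.004)
  res <- run_all_methods(h1, seed = 1, n_boot = 50)
  expect_true("wald_ratio" %in% res$method)
  expect_true("steiger_ivw" %in% res$method)
  expect_false(any(res$estimable[res$method %in%
                                   c("egger", "weighted_median")]))

  # clean simulation: all six estimable and mutually within 2 SE
  truth <- sim_truth(n_snp = 10, theta = 0.3, seed = 21)
  h <- sim_harmonized(truth)
  res <- run_all_methods(h, seed = 2, n_boot = 300)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$estimable))
  est <- res$estimate; se <- res$se
  for (i in seq_along(est)) for (j in seq_along(est))
    expect_lt(abs(est[i] - est[j]), 2 * (se[i] + se[j]) + 1e-12)

  # bit-identical on repeat with the same seed
  res2 <- run_all_methods(h, seed = 2, n_boot = 300)
  expect_identical(res$estimate, res2$estimate)
  expect_identical(res$se, res2$se)

  expect_equal(nrow(run_all_methods(h[0, ], seed = 1)), 0L)
})
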