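test_that("eligibility filter applies strict rules with per-rule counts", {
  meta <- data.frame(
    trait_id = sprintf("t%02d", 1:10),
    ancestry = c(rep("European", 8), "East Asian", "African"),
    n = c(3000, rep(50000, 7), 50000, 50000),          # t01 at boundary
    n_variants = c(2e6, 1e6, rep(2e6, 8)),             # t02 at boundary
    stringsAsFactors = FALSE)
  meta$n[3] <- 2999                                    # t03 under
  meta$n_variants[4] <- 5e5                            # t04 under
  got <- eligibility_filter(meta)
  expect_setequal(got, sprintf("t%02d", 5:8))
  rep_counts <- attr(got, "report")
  expect_equal(unname(rep_counts["ancestry"]), 2L)
  expect_equal(unname(rep_counts["sample_size"]), 2L)  # strict "over 3000"
  expect_equal(unname(rep_counts["variants"]), 2L)

  empty <- eligibility_filter(meta[0, ])
  expect_length(empty, 0L)
})

test_that("bonferroni_threshold reproduces the screen thresholds", {
  expect_equal(bonferroni_threshold(5048), 1e-5)
  expect_equal(bonferroni_threshold(10308), 5e-6)
  expect_equal(bonferroni_threshold(1, 0.05, Inf), 0.05)
  expect_error(bonferroni_threshold(0), "n_tests")
})

test_that("three-stage verdict applies count, sign and threshold rules", {
  mk <- function(method, est, se, n_snp, estimable = TRUE) {
    r <- data.frame(method = method, estimate = est, se = se,
                    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                    pval = 2 * pnorm(-abs(est / se)), n_snp = n_snp,
                    q = NA_real_, q_df = NA_real_,
                    egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                    estimable = estimable, reason = "")
    r
  }
  # 3-SNP instrument: stage 1 fails regardless of p
  res <- rbind(mk("ivw", 0.5, 0.01, 3), mk("weighted_median", 0.5, 0.02, 3),
               mk("steiger_ivw", 0.5, 0.01, 3))
  v <- three_stage_verdict(res, 1e-5, 10)
  expect_false(v$stage1_pass)
  expect_equal(v$stage1_reason, "fewer_than_4_snps")
  expect_false(v$final_pass)

  # concordant signs but median p = 0.06: stage 2 fails (boundary strict)
  wm_est <- 0.02; wm_se <- wm_est / abs(qnorm(0.06 / 2))
  res <- rbind(mk("ivw", 0.5, 0.01, 10),
               mk("weighted_median", wm_est, wm_se, 10),
               mk("steiger_ivw", 0.5, 0.01, 10))
  v <- three_stage_verdict(res, 1e-5, 10)
  expect_true(v$stage1_pass)
  expect_false(v$stage2_pass)
  expect_equal(v$stage2_reason, "median_p_above_0.05")

  # discordant steiger sign: stage 3 fails
  res <- rbind(mk("ivw", 0.5, 0.01, 10),
               mk("weighted_median", 0.5, 0.02, 10),
               mk("steiger_ivw", -0.5, 0.01, 10))
  v <- three_stage_verdict(res, 1e-5, 10)
  expect_false(v$stage3_pass)
  expect_equal(v$stage3_reason, "steiger_discordant_sign")
  expect_equal(v$stage3_threshold, 0.005)

  # strong causal pair passes end to end
  truth <- sim_truth(n_snp = 50, theta = 0.3, seed = 19)
  h <- sim_harmonized(truth)
  res <- run_all_methods(h, seed = 19, n_boot = 200)
  v <- three_stage_verdict(res, 1e-5, 5)
  expect_true(v$final_pass)
})

test_that("forward screen recovers planted causal traits deterministically", {
  ph <- simulate_phenome(n_traits = 40, frac_causal = 0.1, seed = 23)
  cfg <- screen_config(seed = 23, n_boot = 200)
  v1 <- forward_screen(ph$exposures, ph$outcome, ph$meta, cfg,
                       loci = ph$loci, ld = ph$ld)
  causal <- ph$truth$causal[match(v1$exposure, ph$truth$trait_id)]
  expect_gte(sum(v1$final_pass & causal), sum(causal) - 1)
  expect_lte(sum(v1$final_pass & !causal), 1)

  v2 <- forward_screen(ph$exposures, ph$outcome, ph$meta, cfg,
                       loci = ph$loci, ld = ph$ld)
  expect_identical(v1, v2)   # bit-identical rerun, manifest included

  man <- attr(v1, "manifest")
  expect_equal(man$screen_threshold, bonferroni_threshold(40))

  # display layer: non-passing pairs shown at p = 1, stored values intact
  disp <- display_pvalues(v1)
  expect_true(all(disp[!v1$final_pass] == 1))
  expect_true(all(disp[v1$final_pass] == v1$pval[v1$final_pass]))
})

test_that("causal proteins pass the cis arm and colocalize", {
  ph <- simulate_phenome(n_traits = 20, frac_causal = 0.5,
                         frac_protein = 0.6, seed = 57)
  cfg <- screen_config(seed = 57, n_boot = 200)
  v <- forward_screen(ph$exposures, ph$outcome, ph$meta, cfg,
                      loci = ph$loci, ld = ph$ld)
  tr <- ph$truth[match(v$exposure, ph$truth$trait_id), ]
  prot_causal <- tr$type == "protein" & tr$causal
  prot_null <- tr$type == "protein" & !tr$causal
  expect_true(any(prot_causal))
  expect_true(all(v$final_pass[prot_causal]))
  expect_false(any(v$final_pass[prot_null]))
  cl <- attr(v, "coloc")
  expect_setequal(names(cl), v$exposure[prot_causal])
  for (cr in cl) {
    expect_s3_class(cr, "coloc_result")
    expect_gt(cr$pp["pp4"], 0.8)  # shared causal variant by construction
  }
})

test_that("self-on-self exposure is removed by Steiger filtering", {
  truth <- sim_truth(n_snp = 30, theta = 1, seed = 91)
  tabs <- simulate_two_sample(truth)
  # outcome IS the exposure GWAS: same betas, same sample size
  exposures <- list(self = tabs$exposure)
  outcome <- tabs$exposure
  meta <- data.frame(trait_id = "self", type = "quantitative", n = truth$n_x,
                     n_variants = 1.1e7, ancestry = "European",
                     linear_scale = FALSE, stringsAsFactors = FALSE)
  v <- forward_screen(exposures, outcome, meta,
                      screen_config(seed = 91, n_boot = 100), n_tests = 100)
  expect_false(v$final_pass)
  expect_false(v$stage3_pass)
})

test_that("reverse screen reuses one clumped instrument across outcomes", {
  truth <- sim_truth(n_snp = 111, theta = 0, n_x = 1030836, n_y = 1e5,
                     seed = 47)
  thetas <- setNames(rep(0, 30), sprintf("out%02d", 1:30))
  thetas[c(4, 18, 25)] <- 0.25
  rs <- simulate_reverse_set(truth, thetas, seed = 47)
  meta <- data.frame(trait_id = names(thetas), linear_scale = FALSE,
                     stringsAsFactors = FALSE)
  v <- reverse_screen(rs$exposure, rs$outcomes, meta,
                      config = screen_config(seed = 47, n_boot = 200))
  expect_setequal(v$outcome[v$final_pass], c("out04", "out18", "out25"))
  man <- attr(v, "manifest")
  expect_equal(man$clump_calls, 1L)
  expect_equal(man$screen_threshold, bonferroni_threshold(30))
  expect_gt(man$n_instruments, 100)
})

test_that("proxy substitution rescues instruments absent from the outcome", {
  truth <- sim_truth(n_snp = 12, theta = 0.3, seed = 61)
  tabs <- simulate_two_sample(truth)
  ex <- tabs$exposure; ou <- tabs$outcome
  # rs1 vanishes from the outcome; rs1b is a near-perfect negative proxy
  proxy_row <- ou[1, ]
  proxy_row$variant_id <- "rs1b"
  proxy_row$beta <- -proxy_row$beta
  proxy_row$eaf <- 1 - proxy_row$eaf
  ou <- rbind(ou[-1, ], proxy_row)
  ids <- c(ex$variant_id, "rs1b")
  r <- diag(length(ids))
  i <- match("rs1", ids); j <- match("rs1b", ids)
  r[i, j] <- r[j, i] <- -0.98
  ld <- ld_ref(ids, r, positions = c(ex$pos, ex$pos[1] + 500),
               chrom = c(ex$chrom, ex$chrom[1]))
  cfg <- screen_config(seed = 61, n_boot = 100)
  h <- mrphenome:::prepare_pair(ex, ou, ex$variant_id, ld, cfg)
  expect_equal(nrow(h), 12L)
  expect_true(h$proxy_used[h$variant_id == "rs1"])
  counts <- attr(h, "proxy_counts")
  expect_equal(unname(counts["proxy_used"]), 1L)
  # the rescued beta carries the LD sign back to the target orientation
  expect_equal(h$beta_y[h$variant_id == "rs1"], tabs$outcome$beta[1],
               tolerance = 1e-12)
})

test_that("family-wise any-pass rate under a global null stays controlled", {
  any_pass <- logical(60)
  for (r in seq_along(any_pass)) {
    ph <- simulate_phenome(n_traits = 20, frac_causal = 0, frac_protein = 0,
                           n_snp_per_trait = 10, seed = 7000 + r)
    v <- forward_screen(ph$exposures, ph$outcome, ph$meta,
                        screen_config(seed = 7000 + r, n_boot = 100),
                        n_tests = 20)
    any_pass[r] <- any(v$final_pass)
  }
  expect_lte(mean(any_pass), 0.10)
})
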