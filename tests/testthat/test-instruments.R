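test_that("clump keeps independent SNPs and absorbs linked ones", {
  tab <- make_assoc(3, beta = c(0.1, 0.11, 0.12))
  r <- diag(3)
  ld <- ld_ref(tab$variant_id, r, positions = tab$pos, chrom = tab$chrom)
  expect_setequal(clump(tab, ld), tab$variant_id)

  # B (p = 1e-9-ish) absorbed by stronger A 1 kb away at r2 = 0.5
  tab <- make_assoc(2, beta = c(0.2, 0.15), se = 0.02,
                    pos = c(1e6, 1e6 + 1000))
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  ld <- ld_ref(tab$variant_id, r, positions = tab$pos, chrom = tab$chrom)
  expect_equal(clump(tab, ld), "rs1")
})

test_that("clump output is independent of input row order", {
  set.seed(11)
  n <- 30
  pos <- sort(sample.int(5e6, n))
  rho <- 0.8
  r <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  ids <- paste0("s", seq_len(n))
  tab <- make_assoc(n, beta = runif(n, 0.05, 0.2), se = 0.01,
                    pos = pos, ids = ids)
  ld <- ld_ref(ids, r, positions = pos, chrom = "1")
  base <- clump(tab, ld, p_index = 1)
  for (k in 1:5) {
    perm <- tab[sample.int(n), , drop = FALSE]
    expect_identical(clump(perm, ld, p_index = 1), base)
  }
  # post-hoc invariant: retained indices pairwise below the threshold
  idx <- match(base, ids)
  off <- r[idx, idx]^2; diag(off) <- 0
  expect_true(all(off < 0.001 |
                    abs(outer(pos[idx], pos[idx], "-")) > 1e7))
})

test_that("clump matches the brute-force oracle on AR(1) chromosomes", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    pos <- sort(sample.int(2e7, n))
    rho <- runif(1, 0.2, 0.95)
    r <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
    ids <- paste0("v", seq_len(n))
    tab <- make_assoc(n, beta = rnorm(n, 0, 0.1), se = 0.01,
                      pos = pos, ids = ids)
    ld <- ld_ref(ids, r, positions = pos, chrom = "1")
    p_index <- 0.05
    expect_identical(clump(tab, ld, p_index = p_index, r2_max = 0.1,
                           window_bp = 5e6),
                     oracle_clump(tab, ld, p_index, 0.1, 5e6))
  }
})

test_that("missing-LD SNPs are conservatively absorbed within 1 Mb", {
  tab <- make_assoc(3, beta = c(0.2, 0.15, 0.14),
                    pos = c(1e6, 1.5e6, 5e6))
  got <- clump(tab, ld = NULL)   # no panel at all
  expect_identical(got, c("rs1", "rs3"))  # rs2 within 1 Mb of rs1
})

test_that("find_proxy honours threshold, tie-break and reason codes", {
  cand <- make_assoc(3, beta = c(0.1, 0.2, 0.2), se = 0.02,
                     ids = c("c1", "c2", "c3"))
  ids <- c("t", "c1", "c2", "c3")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- sqrt(0.9)
  ld1 <- ld_ref(ids, r)
  got <- find_proxy("t", cand, ld1)
  expect_equal(got$variant_id, "c1")
  expect_equal(got$r2, 0.9, tolerance = 1e-12)

  r2 <- diag(4)
  r2[1, 2] <- r2[2, 1] <- sqrt(0.6)
  r2[1, 3] <- r2[3, 1] <- sqrt(0.7)
  got <- find_proxy("t", cand, ld_ref(ids, r2))
  expect_true(is.na(got$variant_id))
  expect_equal(got$reason, "no_proxy_above_threshold")

  # tie at r2 = 0.85: smaller p wins (c2 and c3 tie on p -> id breaks it)
  r3 <- diag(4)
  r3[1, 3] <- r3[3, 1] <- -sqrt(0.85)
  r3[1, 4] <- r3[4, 1] <- sqrt(0.85)
  got <- find_proxy("t", cand, ld_ref(ids, r3))
  expect_equal(got$variant_id, "c2")
  expect_equal(got$r_sign, -1)

  got <- find_proxy("absent", cand, ld1)
  expect_true(is.na(got$variant_id))
  expect_equal(got$reason, "target_not_in_ld_reference")
})

test_that("variance_explained follows t2/(t2 + n - 2)", {
  expect_equal(variance_explained(0, 0.1, 100), 0)
  expect_equal(variance_explained(0.5, 0.1, 1000), 25 / 1023)
  # monotone increasing in |t| at fixed n
  r2 <- variance_explained(seq(0, 1, by = 0.1), 0.1, 500)
  expect_true(all(diff(r2) > 0))
  expect_error(variance_explained(0.1, 0.1, 2), "n > 2")
})

test_that("steiger_filter applies strict direction and Fisher z test", {
  # equal explained variance: direction false, p = 1
  h <- make_harmonized(bx = 0.1, sx = 0.01, by = 0.1, sy = 0.01,
                       n_x = 1000, n_y = 1000)
  st <- steiger_filter(h)
  expect_false(st$detail$steiger_direction)
  expect_equal(st$detail$steiger_p, 1)
  expect_equal(nrow(st$filtered), 0L)

  # filtering is idempotent and never increases the SNP count
  truth <- sim_truth(n_snp = 40, theta = 0.2, seed = 8)
  h <- sim_harmonized(truth)
  st1 <- steiger_filter(h)
  expect_lte(nrow(st1$filtered), nrow(h))
  st2 <- steiger_filter(st1$filtered)
  expect_equal(nrow(st2$filtered), nrow(st1$filtered))
  expect_equal(st2$filtered$beta_x, st1$filtered$beta_x)
})

test_that("instrument F statistics follow (beta/se)^2", {
  got <- instrument_strength(make_assoc(1, beta = 0.1, se = 0.02))
  expect_equal(unname(got$f), 25)
  got <- instrument_strength(make_assoc(2, beta = c(0.1, 0.06), se = 0.02))
  expect_equal(got$mean_f, 17)
  # genome-wide significance implies F above the p = 5e-8 z-square
  z2 <- qnorm(1 - 5e-8 / 2)^2
  truth <- sim_truth(n_snp = 100, seed = 4)
  tabs <- simulate_two_sample(truth)
  sig <- tabs$exposure[tabs$exposure$pval <= 5e-8, ]
  expect_true(all(instrument_strength(sig)$f >= z2))
  expect_gt(z2, 29.7)
})

test_that("cis instrument selection applies window, p and Steiger rules", {
  locus <- list(chrom = "7", start = 5e6, end = 5.05e6)
  # one strong SNP in window, one 150 kb beyond the flank, one weak
  ptab <- make_assoc(3, beta = c(0.5, 0.5, 0.05), se = 0.02,
                     chrom = "7", pos = c(5.02e6, 5.05e6 + 1.5e5, 5.03e6),
                     n_sample = 3301)
  otab <- make_assoc(3, beta = c(0.05, 0.05, 0.01), se = 0.004,
                     chrom = "7", pos = ptab$pos, n_sample = 1e6)
  h <- harmonize(ptab, otab)
  ids <- select_cis_instruments(ptab, locus, h, flank_bp = 1e5)
  expect_identical(as.character(ids), "rs1")

  # two independent cis signals survive within-window clumping
  ptab2 <- make_assoc(2, beta = c(0.5, 0.4), se = 0.02, chrom = "7",
                      pos = c(5.01e6, 5.04e6), n_sample = 3301)
  otab2 <- make_assoc(2, beta = 0.01, se = 0.004, chrom = "7",
                      pos = ptab2$pos, n_sample = 1e6)
  ld <- ld_ref(ptab2$variant_id, diag(2), positions = ptab2$pos,
               chrom = "7")
  h2 <- harmonize(ptab2, otab2)
  ids2 <- select_cis_instruments(ptab2, locus, h2, ld = ld)
  expect_setequal(as.character(ids2), c("rs1", "rs2"))

  # no qualifying SNP -> empty set
  far <- make_assoc(1, beta = 0.5, se = 0.02, chrom = "7", pos = 9e6,
                    n_sample = 3301)
  h3 <- harmonize(far, otab)
  expect_length(select_cis_instruments(far, locus, h3), 0L)
})
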