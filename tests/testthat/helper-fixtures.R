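# Small programmatic fixtures shared across tests. All data is built in
# code; nothing is read from disk except files the tests themselves write.

# hand-built association table; defaults give clean, independent SNPs
make_assoc <- function(n = 3, beta = 0.1, se = 0.01, n_sample = 10000,
                       eaf = 0.3, chrom = "1", pos = NULL,
                       ea = "A", oa = "G", ids = NULL) {
  ids <- ids %||% paste0("rs", seq_len(n))
  pos <- pos %||% (1e6 + (seq_len(n) - 1) * 2e7)
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  data.frame(variant_id = ids, chrom = rep_len(chrom, n), pos = pos,
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = rep_len(eaf, n), beta = beta, se = se,
             pval = 2 * stats::pnorm(-abs(beta / se)),
             n = rep_len(n_sample, n),
             n_case = NA_real_, n_control = NA_real_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized set straight from beta vectors (bypasses allele bookkeeping)
make_harmonized <- function(bx, sx, by, sy, n_x = 50000, n_y = 100000) {
  j <- length(bx)
  h <- data.frame(variant_id = paste0("rs", seq_len(j)),
                  chrom = "1", pos = 1e6 + seq_len(j) * 2e7,
                  effect_allele = "A", other_allele = "G",
                  beta_x = bx, se_x = rep_len(sx, j),
                  pval_x = 2 * stats::pnorm(-abs(bx / rep_len(sx, j))),
                  beta_y = by, se_y = rep_len(sy, j),
                  pval_y = 2 * stats::pnorm(-abs(by / rep_len(sy, j))),
                  eaf_x = 0.3, eaf_y = 0.3,
                  n_x = n_x, n_y = n_y,
                  flipped = FALSE, proxy_used = FALSE, palindromic = FALSE,
                  stringsAsFactors = FALSE)
  class(h) <- c("harmonized_set", "data.frame")
  h
}

# harmonized set drawn from a sim_truth (clean alleles, no swaps)
sim_harmonized <- function(truth) {
  tabs <- simulate_two_sample(truth)
  harmonize(tabs$exposure, tabs$outcome)
}

write_sumstats_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write_summary_stats(df, path)
  path
}

# independent brute-force greedy clumping oracle: materializes the full
# pairwise r2 matrix (with the missing-pair distance rule) and walks it
oracle_clump <- function(assocs, ld, p_index, r2_max, window_bp) {
  a <- assocs[assocs$pval <= p_index, , drop = FALSE]
  if (nrow(a) == 0) return(character(0))
  n <- nrow(a)
  r2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { r2[i, j] <- 1; next }
    same <- a$chrom[i] == a$chrom[j]
    d <- abs(a$pos[i] - a$pos[j])
    if (!same || d > window_bp) { r2[i, j] <- 0; next }
    r <- ld_r(ld, a$variant_id[i], a$variant_id[j])
    r2[i, j] <- if (is.na(r)) (if (d <= 1e6) 1 else 0) else r^2
  }
  cn <- suppressWarnings(as.numeric(a$chrom)); cn[is.na(cn)] <- 1e6
  rank <- order(a$pval, cn, a$pos, a$variant_id)
  alive <- rep(TRUE, n)
  out <- character(0)
  for (i in rank) {
    if (!alive[i]) next
    out <- c(out, a$variant_id[i])
    alive[r2[i, ] >= r2_max] <- FALSE
  }
  out
}
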