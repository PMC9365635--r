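## Orchestration of the bidirectional phenome-wide screens: eligibility
## filtering, Bonferroni control, the three-stage robustness verdict, the
## protein (cis-pQTL + colocalization) arm, and run manifests.

#' Screen configuration
#'
#' Collects every tunable threshold of the screens in one place.
#'
#' @param p_index instrument significance threshold (default `5e-8`).
#' @param r2_clump clumping LD threshold (default 0.001).
#' @param window_bp clumping window (default 10 Mb).
#' @param proxy_r2 minimum proxy LD `r^2` (default 0.8).
#' @param palindrome_maf_limit see [harmonize()].
#' @param alpha family-wise error level for the Bonferroni screen
#'   threshold (default 0.05).
#' @param round_sig significant figures for the rounded Bonferroni
#'   threshold (default 1, matching heuristic usage).
#' @param flank_bp cis flank for protein instruments (default 100 kb).
#' @param coloc_flank_bp flank around the leading cis-pQTL for
#'   colocalization (default 100 kb).
#' @param n_boot bootstrap draws for median/mode SEs (default 1000).
#' @param seed integer seed for all stochastic steps.
#' @return a named list of class `screen_config`.
#' @export
screen_config <- function(p_index = 5e-8, r2_clump = 0.001, window_bp = 1e7,
                          proxy_r2 = 0.8, palindrome_maf_limit = 0.42,
                          alpha = 0.05, round_sig = 1, flank_bp = 1e5,
                          coloc_flank_bp = 1e5, n_boot = 1000L, seed = 1L) {
  structure(list(p_index = p_index, r2_clump = r2_clump,
                 window_bp = window_bp, proxy_r2 = proxy_r2,
                 palindrome_maf_limit = palindrome_maf_limit,
                 alpha = alpha, round_sig = round_sig, flank_bp = flank_bp,
                 coloc_flank_bp = coloc_flank_bp, n_boot = n_boot,
                 seed = seed),
            class = "screen_config")
}

#' Trait eligibility filter for a phenome-wide screen
#'
#' Keeps traits that are primarily of the requested ancestry, have sample
#' size strictly over `min_n`, and strictly over `min_variants` variants
#' in the source GWAS.
#'
#' @param meta trait-metadata data.frame with `trait_id`, `ancestry`, `n`,
#'   `n_variants`.
#' @param min_n minimum sample size, exclusive (default 3000).
#' @param min_variants minimum variant count, exclusive (default `1e6`).
#' @param ancestry required ancestry label (default `"European"`).
#' @return character vector of eligible trait ids with attribute
#'   `"report"` counting exclusions per rule.
#' @export
eligibility_filter <- function(meta, min_n = 3000, min_variants = 1e6,
                               ancestry = "European") {
  if (nrow(meta) == 0L) {
    out <- character(0)
    attr(out, "report") <- c(ancestry = 0L, sample_size = 0L, variants = 0L)
    return(out)
  }
  anc_ok <- meta$ancestry == ancestry
  n_ok <- meta$n > min_n
  v_ok <- meta$n_variants > min_variants
  keep <- anc_ok & n_ok & v_ok
  out <- meta$trait_id[keep]
  attr(out, "report") <- c(ancestry = sum(!anc_ok),
                           sample_size = sum(anc_ok & !n_ok),
                           variants = sum(anc_ok & n_ok & !v_ok))
  out
}

#' Bonferroni screen threshold, rounded as used in practice
#'
#' `alpha / n_tests`, rounded to `round_sig` significant figures. With the
#' default one significant figure, 5048 tests give `1e-5` and 10 308 tests
#' give `5e-6`.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise level (default 0.05).
#' @param round_sig significant figures to round to; `Inf` for no
#'   rounding.
#' @return the threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05, round_sig = 1) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("bonferroni_threshold requires n_tests >= 1")
  thr <- alpha / n_tests
  if (is.finite(round_sig)) thr <- signif(thr, round_sig)
  thr
}

method_row <- function(results, method) {
  r <- results[results$method == method, , drop = FALSE]
  if (nrow(r) == 0L) NULL else r[1L, , drop = FALSE]
}

#' Three-stage robustness verdict for one exposure-outcome pair
#'
#' Stage 1: at least 4 instrument SNPs (the minimum needed to run all five
#' univariable methods) and primary IVW `p <` the Bonferroni screen
#' threshold. Stage 2: weighted-median estimate directionally concordant
#' with IVW and median `p < 0.05`. Stage 3: Steiger-filtered IVW
#' directionally concordant with IVW and Steiger-IVW
#' `p < 0.05 / n_stage12_passers` (the threshold is data-dependent: the
#' divisor counts pairs passing stages 1 and 2 across the whole screen, so
#' the screen evaluates stage 3 in a second pass). `final_pass` requires
#' all three.
#'
#' @param results method table from [run_all_methods()] (the primary may
#'   be `"ivw"` or a single-SNP `"wald_ratio"`).
#' @param screen_threshold Bonferroni threshold for stage 1.
#' @param n_stage12_passers divisor of the stage-3 threshold (default 1).
#' @return one-row `data.frame` with the primary estimate, per-stage
#'   passes and reasons, and `final_pass`.
#' @export
three_stage_verdict <- function(results, screen_threshold,
                                n_stage12_passers = 1L) {
  primary <- method_row(results, "ivw") %||% method_row(results, "wald_ratio")
  if (is.null(primary)) stop("three_stage_verdict requires a primary result")
  wm <- method_row(results, "weighted_median")
  st <- method_row(results, "steiger_ivw")
  s1 <- FALSE; s1r <- ""
  if (is.na(primary$n_snp) || primary$n_snp < 4L) {
    s1r <- "fewer_than_4_snps"
  } else if (!isTRUE(primary$estimable) || is.na(primary$pval)) {
    s1r <- "primary_not_estimable"
  } else if (primary$pval >= screen_threshold) {
    s1r <- "primary_p_above_threshold"
  } else s1 <- TRUE
  s2 <- FALSE; s2r <- ""
  if (is.null(wm) || !isTRUE(wm$estimable) || is.na(wm$pval)) {
    s2r <- "weighted_median_missing"
  } else if (sign(wm$estimate) != sign(primary$estimate)) {
    s2r <- "median_discordant_sign"
  } else if (wm$pval >= 0.05) {
    s2r <- "median_p_above_0.05"
  } else s2 <- TRUE
  stage3_threshold <- 0.05 / max(1L, n_stage12_passers)
  s3 <- FALSE; s3r <- ""
  if (is.null(st) || !isTRUE(st$estimable) || is.na(st$pval)) {
    s3r <- "steiger_ivw_missing"
  } else if (sign(st$estimate) != sign(primary$estimate)) {
    s3r <- "steiger_discordant_sign"
  } else if (st$pval >= stage3_threshold) {
    s3r <- "steiger_p_above_threshold"
  } else s3 <- TRUE
  data.frame(method = primary$method, estimate = primary$estimate,
             se = primary$se, pval = primary$pval, n_snp = primary$n_snp,
             stage1_pass = s1, stage1_reason = s1r,
             stage2_pass = s2, stage2_reason = s2r,
             stage3_pass = s3, stage3_reason = s3r,
             final_pass = s1 && s2 && s3,
             screen_threshold = screen_threshold,
             stage3_threshold = stage3_threshold,
             stringsAsFactors = FALSE)
}

## build the harmonized set for one exposure against the outcome table,
## with proxy substitution for instruments absent from the outcome
prepare_pair <- function(ex_tab, outcome, instrument_ids, ld, config) {
  counts <- c(proxy_used = 0L, proxy_failed = 0L)
  rows <- ex_tab[ex_tab$variant_id %in% instrument_ids, , drop = FALSE]
  present <- rows$variant_id %in% outcome$variant_id
  out_use <- outcome
  out_use$proxy_used <- FALSE
  if (any(!present)) {
    for (vid in rows$variant_id[!present]) {
      pr <- if (is.null(ld))
        list(variant_id = NA_character_, reason = "no_ld_reference") else
        find_proxy(vid, outcome, ld, r2_min = config$proxy_r2)
      if (is.na(pr$variant_id)) {
        counts["proxy_failed"] <- counts["proxy_failed"] + 1L
      } else {
        ## substitute: relabel the proxy's outcome row as the target,
        ## orienting the sign by the LD correlation
        prow <- out_use[out_use$variant_id == pr$variant_id, , drop = FALSE]
        erow <- rows[rows$variant_id == vid, , drop = FALSE]
        prow$variant_id <- vid
        prow$effect_allele <- erow$effect_allele
        prow$other_allele <- erow$other_allele
        prow$beta <- prow$beta * pr$r_sign
        prow$eaf <- if (pr$r_sign < 0) 1 - prow$eaf else prow$eaf
        prow$proxy_used <- TRUE
        out_use <- rbind(out_use, prow)
        counts["proxy_used"] <- counts["proxy_used"] + 1L
      }
    }
  }
  h <- harmonize(rows, out_use,
                 palindrome_maf_limit = config$palindrome_maf_limit)
  attr(h, "proxy_counts") <- counts
  h
}

screen_one <- function(tid, ex_tab, outcome, meta_row, ld, config,
                       threshold) {
  if (isTRUE(meta_row$linear_scale)) ex_tab <- scale_assoc_table(ex_tab)
  instruments <- clump(ex_tab, ld = ld, p_index = config$p_index,
                       r2_max = config$r2_clump,
                       window_bp = config$window_bp)
  if (length(instruments) == 0L) {
    return(list(verdict = NULL, reason = "no_instruments"))
  }
  h <- prepare_pair(ex_tab, outcome, instruments, ld, config)
  if (nrow(h) == 0L) return(list(verdict = NULL, reason = "no_overlap"))
  ## lazy evaluation: the expensive bootstrap methods are only needed for
  ## pairs clearing stage 1, which the IVW fit alone decides
  primary <- if (nrow(h) == 1L)
    wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y) else ivw(h)
  stage1_possible <- nrow(h) >= 4L && isTRUE(primary$estimable) &&
    !is.na(primary$pval) && primary$pval < threshold
  results <- if (stage1_possible) {
    run_all_methods(h, seed = child_seed(config$seed, tid),
                    n_boot = config$n_boot)
  } else primary
  list(verdict = results, h = h, reason = "")
}

finalize_verdicts <- function(partials, threshold) {
  ## two-pass stage-3 thresholding: count stage-1&2 passers first
  pre <- lapply(partials, function(p) {
    if (is.null(p$verdict)) return(NULL)
    three_stage_verdict(p$verdict, threshold, n_stage12_passers = 1L)
  })
  n12 <- sum(vapply(pre, function(v)
    !is.null(v) && v$stage1_pass && v$stage2_pass, logical(1)))
  rows <- list()
  for (tid in names(partials)) {
    p <- partials[[tid]]
    if (is.null(p$verdict)) {
      rows[[tid]] <- data.frame(
        exposure = tid, method = NA_character_, estimate = NA_real_,
        se = NA_real_, pval = NA_real_, n_snp = 0L,
        stage1_pass = FALSE, stage1_reason = p$reason,
        stage2_pass = FALSE, stage2_reason = p$reason,
        stage3_pass = FALSE, stage3_reason = p$reason,
        final_pass = FALSE, screen_threshold = threshold,
        stage3_threshold = NA_real_, stringsAsFactors = FALSE)
    } else {
      v <- three_stage_verdict(p$verdict, threshold,
                               n_stage12_passers = max(1L, n12))
      rows[[tid]] <- cbind(data.frame(exposure = tid,
                                      stringsAsFactors = FALSE), v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_stage12_passers") <- n12
  out
}

#' Forward phenome-wide screen: many exposures against one outcome
#'
#' For every eligible non-protein exposure: rescale linear-scale binary
#' traits to log odds, clump instruments, substitute proxies for
#' instruments missing from the outcome GWAS (dropping those without a
#' proxy), harmonize, run the MR method suite, and issue the three-stage
#' verdict against the Bonferroni threshold `alpha / n_exposures`
#' (rounded to one significant figure). Protein exposures are routed to
#' [protein_screen()]. Stage 3 is evaluated in a second pass once the
#' number of stage-1/2 passers is known. The returned table is a pure
#' function of (inputs, config, seed); a run manifest with seeds,
#' thresholds and drop counts is attached as attribute `"manifest"`.
#'
#' @param exposures named list of exposure summary tables.
#' @param outcome outcome summary table (log-odds scale, or flagged
#'   linear-scale binary in `outcome_meta`).
#' @param meta trait metadata (see [eligibility_filter()]; also needs
#'   `type` and `linear_scale`).
#' @param config a [screen_config()].
#' @param loci named list of coding-gene loci for protein traits.
#' @param ld named list of [ld_ref()]s per trait (regional for proteins);
#'   traits without an entry are clumped by the distance rule alone.
#' @param n_tests Bonferroni divisor; defaults to the number of exposures.
#' @return a verdict data.frame, one row per exposure, with the protein
#'   arm's colocalization results in attribute `"coloc"`.
#' @export
forward_screen <- function(exposures, outcome, meta, config = screen_config(),
                           loci = list(), ld = list(), n_tests = NULL) {
  stopifnot(is.list(exposures), !is.null(names(exposures)))
  n_tests <- n_tests %||% length(exposures)
  threshold <- bonferroni_threshold(n_tests, config$alpha, config$round_sig)
  meta <- meta[match(names(exposures), meta$trait_id), , drop = FALSE]
  is_protein <- meta$type == "protein"
  partials <- list()
  for (tid in names(exposures)[!is_protein]) {
    mrow <- meta[meta$trait_id == tid, , drop = FALSE]
    partials[[tid]] <- screen_one(tid, exposures[[tid]], outcome, mrow,
                                  ld[[tid]], config, threshold)
  }
  verdicts <- finalize_verdicts(partials, threshold)
  n12 <- attr(verdicts, "n_stage12_passers")
  coloc_results <- list()
  if (any(is_protein)) {
    prot <- protein_screen(exposures[is_protein], outcome,
                           meta[is_protein, , drop = FALSE],
                           loci = loci, ld = ld, config = config,
                           threshold = threshold)
    verdicts <- rbind(verdicts, prot$verdicts)
    coloc_results <- prot$coloc
  }
  verdicts <- verdicts[match(names(exposures), verdicts$exposure), ,
                       drop = FALSE]
  rownames(verdicts) <- NULL
  attr(verdicts, "coloc") <- coloc_results
  attr(verdicts, "manifest") <- list(
    seed = config$seed, n_tests = n_tests, screen_threshold = threshold,
    n_stage12_passers = n12,
    config = unclass(config))
  verdicts
}

#' Protein arm of the forward screen: cis-pQTL MR plus colocalization
#'
#' For each protein with a known coding-gene locus: select cis instruments
#' ([select_cis_instruments()]), estimate the causal effect by Wald ratio
#' (single variant) or IVW, call the protein a candidate when the primary
#' `p <` the exposure-screen Bonferroni threshold, and colocalize
#' candidates with the outcome in the region 100 kb either side of the
#' leading cis-pQTL (the smallest-p cis variant). The outcome trait is
#' case-control, so its colocalization effect prior SD is 0.2 (log-odds
#' scale) against 0.15 for the protein.
#'
#' @param proteins named list of protein summary tables (dense cis
#'   regions).
#' @param outcome outcome summary table.
#' @param meta metadata rows for the proteins.
#' @param loci named list of `list(chrom, start, end)` gene loci.
#' @param ld named list of regional [ld_ref()]s.
#' @param config a [screen_config()].
#' @param threshold exposure-screen Bonferroni threshold.
#' @return list with `verdicts` (data.frame; stages 2/3 are not applicable
#'   to the cis arm and are recorded as such) and `coloc` (named list of
#'   `coloc_result`).
#' @export
protein_screen <- function(proteins, outcome, meta, loci, ld,
                           config = screen_config(), threshold = 1e-5) {
  rows <- list()
  coloc_results <- list()
  for (tid in names(proteins)) {
    ptab <- proteins[[tid]]
    locus <- loci[[tid]]
    if (is.null(locus)) {
      rows[[tid]] <- protein_row(tid, NULL, FALSE, "no_locus_metadata",
                                 threshold)
      next
    }
    h_all <- harmonize(ptab, outcome,
                       palindrome_maf_limit = config$palindrome_maf_limit)
    ids <- select_cis_instruments(ptab, locus, h_all, ld = ld[[tid]],
                                  flank_bp = config$flank_bp,
                                  p_max = config$p_index,
                                  r2_max = config$r2_clump)
    if (length(ids) == 0L) {
      rows[[tid]] <- protein_row(tid, NULL, FALSE, "no_cis_instrument",
                                 threshold)
      next
    }
    h <- h_all[h_all$variant_id %in% ids, , drop = FALSE]
    primary <- if (nrow(h) == 1L)
      wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y) else ivw(h)
    pass <- isTRUE(primary$estimable) && !is.na(primary$pval) &&
      primary$pval < threshold
    rows[[tid]] <- protein_row(tid, primary, pass,
                               if (pass) "" else "primary_p_above_threshold",
                               threshold)
    if (pass) {
      ## colocalize around the leading cis-pQTL
      lo <- locus$start - config$flank_bp
      hi <- locus$end + config$flank_bp
      cis <- ptab[ptab$chrom == as.character(locus$chrom) &
                    ptab$pos >= lo & ptab$pos <= hi, , drop = FALSE]
      lead <- cis[which.min(cis$pval), , drop = FALSE]
      w_lo <- lead$pos - config$coloc_flank_bp
      w_hi <- lead$pos + config$coloc_flank_bp
      rx <- ptab[ptab$chrom == lead$chrom & ptab$pos >= w_lo &
                   ptab$pos <= w_hi, , drop = FALSE]
      ry <- outcome[outcome$variant_id %in% rx$variant_id, , drop = FALSE]
      coloc_results[[tid]] <- tryCatch(
        colocalize(rx, ry, prior_sd_x = 0.15, prior_sd_y = 0.2),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "coloc_failure"))
    }
  }
  verdicts <- do.call(rbind, rows)
  rownames(verdicts) <- NULL
  list(verdicts = verdicts, coloc = coloc_results)
}

protein_row <- function(tid, primary, pass, reason, threshold) {
  data.frame(
    exposure = tid,
    method = if (is.null(primary)) NA_character_ else primary$method,
    estimate = if (is.null(primary)) NA_real_ else primary$estimate,
    se = if (is.null(primary)) NA_real_ else primary$se,
    pval = if (is.null(primary)) NA_real_ else primary$pval,
    n_snp = if (is.null(primary)) 0L else primary$n_snp,
    stage1_pass = pass, stage1_reason = reason,
    stage2_pass = NA, stage2_reason = "not_applicable_cis_arm",
    stage3_pass = NA, stage3_reason = "not_applicable_cis_arm",
    final_pass = pass, screen_threshold = threshold,
    stage3_threshold = NA_real_, stringsAsFactors = FALSE)
}

#' Reverse screen: one exposure against many outcomes
#'
#' The exposure instrument is clumped exactly once and reused across all
#' outcomes (the manifest records the call count). Binary outcomes flagged
#' as linear-scale are rescaled to log odds before estimation. The
#' Bonferroni threshold is `alpha / n_outcomes` rounded to one significant
#' figure, and the same three-stage verdict machinery applies.
#'
#' @param exposure exposure summary table (e.g. a disease-liability GWAS).
#' @param outcomes named list of outcome summary tables.
#' @param meta metadata for the outcomes (`trait_id`, `linear_scale`).
#' @param config a [screen_config()].
#' @param ld optional [ld_ref()] for clumping the exposure.
#' @param n_tests Bonferroni divisor; defaults to the number of outcomes.
#' @return verdict data.frame (one row per outcome, in the `exposure`
#'   column slot) with attribute `"manifest"`.
#' @export
reverse_screen <- function(exposure, outcomes, meta = NULL,
                           config = screen_config(), ld = NULL,
                           n_tests = NULL) {
  stopifnot(is.list(outcomes), !is.null(names(outcomes)))
  n_tests <- n_tests %||% length(outcomes)
  threshold <- bonferroni_threshold(n_tests, config$alpha, config$round_sig)
  instruments <- clump(exposure, ld = ld, p_index = config$p_index,
                       r2_max = config$r2_clump,
                       window_bp = config$window_bp)
  partials <- list()
  for (tid in names(outcomes)) {
    ot <- outcomes[[tid]]
    if (!is.null(meta)) {
      mrow <- meta[meta$trait_id == tid, , drop = FALSE]
      if (nrow(mrow) == 1L && isTRUE(mrow$linear_scale))
        ot <- scale_assoc_table(ot)
    }
    if (length(instruments) == 0L) {
      partials[[tid]] <- list(verdict = NULL, reason = "no_instruments")
      next
    }
    h <- prepare_pair(exposure, ot, instruments, ld, config)
    if (nrow(h) == 0L) {
      partials[[tid]] <- list(verdict = NULL, reason = "no_overlap")
      next
    }
    primary <- if (nrow(h) == 1L)
      wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y) else ivw(h)
    stage1_possible <- nrow(h) >= 4L && isTRUE(primary$estimable) &&
      !is.na(primary$pval) && primary$pval < threshold
    results <- if (stage1_possible) {
      run_all_methods(h, seed = child_seed(config$seed, tid),
                      n_boot = config$n_boot)
    } else primary
    partials[[tid]] <- list(verdict = results, reason = "")
  }
  verdicts <- finalize_verdicts(partials, threshold)
  names(verdicts)[names(verdicts) == "exposure"] <- "outcome"
  attr(verdicts, "manifest") <- list(
    seed = config$seed, n_tests = n_tests, screen_threshold = threshold,
    clump_calls = 1L, n_instruments = length(instruments),
    n_stage12_passers = attr(verdicts, "n_stage12_passers"),
    config = unclass(config))
  verdicts
}

#' Display-layer p-values for screen summary plots
#'
#' For plotting only (never in stored results): pairs not supported by the
#' three-stage verdict have their p-value set to 1, indicating absence of
#' reliable evidence.
#'
#' @param verdicts a verdict data.frame from a screen.
#' @return numeric vector of display p-values.
#' @export
display_pvalues <- function(verdicts) {
  ifelse(verdicts$final_pass %in% TRUE, verdicts$pval, 1)
}

#' Static summary plot of a screen (-log10 p against trait index)
#'
#' @param verdicts verdict data.frame.
#' @param threshold horizontal reference line (defaults to the stored
#'   screen threshold).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted display p-values.
#' @export
screen_plot <- function(verdicts, threshold = NULL, ...) {
  p <- display_pvalues(verdicts)
  thr <- threshold %||% verdicts$screen_threshold[1]
  graphics::plot(seq_along(p), -log10(p), xlab = "trait index",
                 ylab = "-log10 p (display)", pch = 19, ...)
  graphics::abline(h = -log10(thr), lty = 2)
  invisible(p)
}
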