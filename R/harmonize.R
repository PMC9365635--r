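## Allele harmonization: align exposure and outcome associations to a shared
## effect allele per SNP before any MR estimation.

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared SNP to the exposure's
#' effect allele. When the outcome's effect allele equals the exposure's
#' other allele (and vice versa) the outcome beta sign is flipped and its
#' effect-allele frequency complemented. Palindromic SNPs (A/T or C/G) are
#' ambiguous to strand: those whose minor-allele frequency exceeds
#' `palindrome_maf_limit` are dropped; the rest are aligned by frequency
#' when both frequencies are available. SNPs whose allele pairs neither
#' match nor swap are dropped with a reason code.
#'
#' Harmonization is idempotent: harmonizing an already-aligned pair again is
#' a no-op, and downstream MR estimates are invariant to relabeling
#' effect/other alleles in the outcome file.
#'
#' @param exposure,outcome summary-statistics data.frames keyed by
#'   `variant_id` with uppercase alleles.
#' @param palindrome_maf_limit palindromic SNPs with
#'   `min(eaf, 1 - eaf)` above this limit are dropped (default 0.42).
#' @return a `harmonized_set`: data.frame with one row per retained SNP
#'   (`beta_x`, `se_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `n_x`, `n_y`,
#'   exposure-orientation alleles, and provenance flags `flipped`,
#'   `proxy_used`, `palindromic`), plus a `"dropped"` attribute listing
#'   excluded SNPs with reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  ids <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(ids, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(ids, outcome$variant_id), , drop = FALSE]
  n <- length(ids)
  flipped <- logical(n)
  keep <- rep(TRUE, n)
  reason <- character(n)

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  mismatch <- !same & !swapped
  keep[mismatch] <- FALSE
  reason[mismatch] <- "allele_mismatch"

  beta_y <- ou$beta
  eaf_y <- ou$eaf
  ## palindromic pairs: "swapped" labels are strand-indistinguishable from
  ## matching labels, so alignment is driven by frequency alone below
  do_flip <- swapped & !pal & keep
  beta_y[do_flip] <- -beta_y[do_flip]
  eaf_y[do_flip] <- 1 - eaf_y[do_flip]
  flipped[do_flip] <- TRUE

  if (any(pal & keep)) {
    maf <- pmin(ex$eaf, 1 - ex$eaf)
    ambiguous <- pal & keep & !is.na(maf) & maf > palindrome_maf_limit
    keep[ambiguous] <- FALSE
    reason[ambiguous] <- "dropped_palindromic"
    ## align the informative ones by frequency when both eafs known
    fixable <- pal & keep & !is.na(ex$eaf) & !is.na(eaf_y)
    disc <- fixable & ((ex$eaf - 0.5) * (eaf_y - 0.5) < 0)
    beta_y[disc] <- -beta_y[disc]
    eaf_y[disc] <- 1 - eaf_y[disc]
    flipped[disc] <- TRUE
  }

  h <- data.frame(
    variant_id = ids,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval,
    beta_y = beta_y, se_y = ou$se, pval_y = ou$pval,
    eaf_x = ex$eaf, eaf_y = eaf_y,
    n_x = ex$n, n_y = ou$n,
    flipped = flipped,
    proxy_used = if (!is.null(ou$proxy_used)) ou$proxy_used else FALSE,
    palindromic = pal,
    stringsAsFactors = FALSE
  )
  complete <- !is.na(h$se_x) & !is.na(h$se_y)
  keep2 <- keep & complete
  reason[keep & !complete] <- "missing_se"
  dropped <- data.frame(variant_id = ids[!keep2], reason = reason[!keep2],
                        stringsAsFactors = FALSE)
  h <- h[keep2, , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "dropped") <- dropped
  class(h) <- c("harmonized_set", "data.frame")
  h
}

#' Convert a harmonized set back into exposure/outcome tables
#'
#' Utility used mainly to verify that harmonization is idempotent.
#'
#' @param h a `harmonized_set`.
#' @return list of two summary-statistics data.frames sharing the
#'   harmonized effect-allele orientation.
#' @export
harmonized_to_tables <- function(h) {
  base <- data.frame(variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
                     effect_allele = h$effect_allele,
                     other_allele = h$other_allele,
                     stringsAsFactors = FALSE)
  ex <- cbind(base, data.frame(eaf = h$eaf_x, beta = h$beta_x, se = h$se_x,
                               pval = h$pval_x, n = h$n_x,
                               n_case = NA_real_, n_control = NA_real_))
  ou <- cbind(base, data.frame(eaf = h$eaf_y, beta = h$beta_y, se = h$se_y,
                               pval = h$pval_y, n = h$n_y,
                               n_case = NA_real_, n_control = NA_real_))
  list(exposure = ex, outcome = ou)
}
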