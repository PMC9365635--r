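## Instrument selection: greedy LD clumping, proxy substitution, cis-window
## selection for proteins, variance explained, Steiger filtering, F stats.

chrom_order_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), 1e6, num)
}

## deterministic ranking: p ascending, then chrom, position, id
clump_order <- function(tab) {
  order(tab$pval, chrom_order_key(tab$chrom), tab$pos, tab$variant_id)
}

#' Greedy LD clumping of GWAS associations
#'
#' Reduces an association table to approximately independent index variants.
#' Index variants are chosen greedily by ascending p-value among SNPs with
#' `pval <= p_index`; after each selection, all unassigned SNPs on the same
#' chromosome within `window_bp` of the index with LD `r^2 >= r2_max` to it
#' are absorbed into the clump. Ties at equal p are broken by chromosome,
#' then position, then variant id, so the output is independent of input
#' row order.
#'
#' A SNP pair absent from the LD reference is treated conservatively: `r^2`
#' = 1 when within 1 Mb of each other (absorbed), unlinked beyond.
#'
#' @param assocs summary-statistics data.frame.
#' @param ld an [ld_ref()] sharing the id space, or `NULL` when no panel is
#'   available (the distance rule above then decides alone).
#' @param p_index index-variant significance threshold (default `5e-8`).
#' @param r2_max maximum LD between retained indices (default `0.001`).
#' @param window_bp clumping window around each index (default 10 Mb).
#' @return character vector of index variant ids in selection order.
#' @export
clump <- function(assocs, ld = NULL, p_index = 5e-8, r2_max = 0.001,
                  window_bp = 1e7) {
  cand <- assocs[!is.na(assocs$pval) & assocs$pval <= p_index, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  cand <- cand[clump_order(cand), , drop = FALSE]
  unassigned <- rep(TRUE, nrow(cand))
  index <- character(0)
  while (any(unassigned)) {
    i <- which(unassigned)[1L]
    index <- c(index, cand$variant_id[i])
    unassigned[i] <- FALSE
    j <- which(unassigned)
    if (length(j) == 0L) break
    same_chr <- cand$chrom[j] == cand$chrom[i]
    dist <- abs(cand$pos[j] - cand$pos[i])
    in_window <- same_chr & dist <= window_bp
    if (!any(in_window)) next
    jj <- j[in_window]
    r <- vapply(cand$variant_id[jj], function(id)
      ld_r(ld, cand$variant_id[i], id), numeric(1))
    r2 <- r^2
    ## pair missing from the panel: conservative absorption within 1 Mb
    miss <- is.na(r2)
    r2[miss] <- ifelse(abs(cand$pos[jj][miss] - cand$pos[i]) <= 1e6, 1, 0)
    unassigned[jj[r2 >= r2_max]] <- FALSE
  }
  index
}

#' Find an LD proxy for a missing instrument variant
#'
#' When an instrument SNP is absent from the outcome GWAS, the candidate in
#' highest LD with it (among variants present in the outcome table) may be
#' substituted. Candidates must exceed `r2_min`; ties on `r^2` are broken by
#' smaller p-value, then variant id. The sign of r is recorded so the
#' proxy's alleles can be oriented relative to the target.
#'
#' @param target variant id of the missing instrument.
#' @param candidates summary-statistics data.frame of variants available in
#'   the outcome GWAS.
#' @param ld an [ld_ref()] covering target and candidates.
#' @param r2_min minimum LD `r^2` for a usable proxy (default 0.8).
#' @return list with `variant_id`, `r2`, `r_sign` and an empty `reason`;
#'   when no proxy qualifies, `variant_id` is `NA` and `reason` holds a
#'   machine-readable code.
#' @export
find_proxy <- function(target, candidates, ld, r2_min = 0.8) {
  fail <- function(reason)
    list(variant_id = NA_character_, r2 = NA_real_, r_sign = NA_real_,
         reason = reason)
  if (is.null(ld) || !target %in% ld$variant_ids)
    return(fail("target_not_in_ld_reference"))
  cand <- candidates[candidates$variant_id %in% ld$variant_ids &
                       candidates$variant_id != target, , drop = FALSE]
  if (nrow(cand) == 0L) return(fail("no_candidates"))
  r <- vapply(cand$variant_id, function(id) ld_r(ld, target, id), numeric(1))
  r2 <- unname(r^2)
  ok <- !is.na(r2) & r2 > r2_min
  if (!any(ok)) return(fail("no_proxy_above_threshold"))
  cand <- cand[ok, , drop = FALSE]
  r <- unname(r[ok]); r2 <- r2[ok]
  best <- order(-r2, cand$pval, cand$variant_id)[1L]
  list(variant_id = cand$variant_id[best], r2 = r2[best],
       r_sign = sign(r[best]), reason = "")
}

#' Variance in a trait explained by a single variant
#'
#' From summary statistics only: `r^2 = t^2 / (t^2 + n - 2)` with
#' `t = beta / se`.
#'
#' @param beta,se association estimate and standard error.
#' @param n sample size (> 2).
#' @return `r^2` in `[0, 1)`.
#' @export
variance_explained <- function(beta, se, n) {
  if (any(n <= 2, na.rm = TRUE)) stop("variance_explained requires n > 2")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality filter
#'
#' For each SNP, compares the variance explained in the exposure with that
#' explained in the outcome. The assumed causal direction is supported when
#' `r2_x > r2_y` (strict). A two-sample z-test on the Fisher-transformed
#' correlations gives a per-SNP p-value:
#' `z = (atanh|r_x| - atanh|r_y|) / sqrt(1/(n_x - 3) + 1/(n_y - 3))`.
#' SNPs with `n <= 3` on either side are dropped with a reason.
#'
#' Re-filtering a filtered set is a no-op.
#'
#' @param h a `harmonized_set` with per-SNP sample sizes.
#' @return list with `filtered` (the direction-true subset, still a
#'   `harmonized_set`) and `detail` (per-SNP `r2_x`, `r2_y`,
#'   `steiger_direction`, `steiger_p`, `reason`).
#' @export
steiger_filter <- function(h) {
  n <- nrow(h)
  detail <- data.frame(variant_id = h$variant_id,
                       r2_x = NA_real_, r2_y = NA_real_,
                       steiger_direction = FALSE, steiger_p = NA_real_,
                       reason = "", stringsAsFactors = FALSE)
  usable <- !is.na(h$n_x) & !is.na(h$n_y) & h$n_x > 3 & h$n_y > 3
  detail$reason[!usable] <- "sample_size_too_small"
  if (any(usable)) {
    i <- which(usable)
    r2x <- variance_explained(h$beta_x[i], h$se_x[i], h$n_x[i])
    r2y <- variance_explained(h$beta_y[i], h$se_y[i], h$n_y[i])
    rx <- sqrt(r2x); ry <- sqrt(r2y)
    z <- (atanh(rx) - atanh(ry)) /
      sqrt(1 / (h$n_x[i] - 3) + 1 / (h$n_y[i] - 3))
    detail$r2_x[i] <- r2x
    detail$r2_y[i] <- r2y
    detail$steiger_direction[i] <- r2x > r2y
    detail$steiger_p[i] <- 2 * pnorm(-abs(z))
    detail$reason[i][r2x <= r2y] <- "direction_false"
  }
  filtered <- h[detail$steiger_direction, , drop = FALSE]
  rownames(filtered) <- NULL
  attr(filtered, "dropped") <- attr(h, "dropped")
  class(filtered) <- class(h)
  list(filtered = filtered, detail = detail)
}

#' Per-SNP and mean instrument F statistics
#'
#' `F_j = (beta_j / se_j)^2`; the summary is the arithmetic mean. Values
#' below ~10 conventionally flag weak instruments.
#'
#' @param assocs summary-statistics (or harmonized, via `beta_x`/`se_x`)
#'   table for the instrument SNPs.
#' @return list with `f` (per SNP, named by variant id) and `mean_f`.
#' @export
instrument_strength <- function(assocs) {
  if (nrow(assocs) == 0L) stop("instrument_strength requires >= 1 SNP")
  beta <- assocs$beta %||% assocs$beta_x
  se <- assocs$se %||% assocs$se_x
  f <- (beta / se)^2
  names(f) <- assocs$variant_id
  list(f = f, mean_f = mean(f))
}

#' Select cis instruments for a protein exposure
#'
#' Instruments for circulating proteins are restricted to the cis region:
#' SNPs within `flank_bp` of the protein's coding gene, associated with the
#' protein at `pval <= p_max`, and explaining more variance in the protein
#' than in the outcome trait (per-SNP Steiger condition). Qualifying SNPs
#' are LD-clumped within the window before return.
#'
#' @param protein_assocs protein summary-statistics data.frame.
#' @param gene_locus list/row with `chrom`, `start`, `end` of the coding
#'   gene (1-based inclusive bp).
#' @param harmonized `harmonized_set` of the protein against the outcome
#'   (supplies the outcome-side variance-explained comparison).
#' @param ld optional [ld_ref()] for within-window clumping.
#' @param flank_bp cis flank around the gene body (default 100 kb).
#' @param p_max association threshold (default `5e-8`).
#' @param r2_max clumping threshold within the window (default 0.001).
#' @return character vector of instrument variant ids (possibly empty),
#'   with attribute `n_candidates`.
#' @export
select_cis_instruments <- function(protein_assocs, gene_locus, harmonized,
                                   ld = NULL, flank_bp = 1e5, p_max = 5e-8,
                                   r2_max = 0.001) {
  lo <- gene_locus$start - flank_bp
  hi <- gene_locus$end + flank_bp
  in_cis <- protein_assocs$chrom == as.character(gene_locus$chrom) &
    protein_assocs$pos >= lo & protein_assocs$pos <= hi &
    protein_assocs$pval <= p_max
  cand <- protein_assocs[in_cis, , drop = FALSE]
  ## Steiger condition: more variance explained in the protein than outcome
  hm <- harmonized[match(cand$variant_id, harmonized$variant_id), , drop = FALSE]
  ok <- !is.na(hm$variant_id)
  if (any(ok)) {
    r2x <- variance_explained(hm$beta_x[ok], hm$se_x[ok], hm$n_x[ok])
    r2y <- variance_explained(hm$beta_y[ok], hm$se_y[ok], hm$n_y[ok])
    keep <- ok
    keep[ok] <- r2x > r2y
  } else keep <- ok
  cand <- cand[keep, , drop = FALSE]
  n_candidates <- nrow(cand)
  if (n_candidates == 0L) {
    out <- character(0)
    attr(out, "n_candidates") <- 0L
    return(out)
  }
  out <- clump(cand, ld = ld, p_index = p_max, r2_max = r2_max,
               window_bp = hi - lo + 1)
  attr(out, "n_candidates") <- n_candidates
  out
}
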