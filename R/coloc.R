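## Bayesian colocalization of two traits at a locus via per-SNP approximate
## Bayes factors, under the single-causal-variant assumption. Produces the
## posterior probabilities of the five hypotheses:
##   H0 no association with either trait; H1/H2 association with one trait
##   only; H3 two distinct causal variants; H4 one shared causal variant.

#' Log approximate Bayes factor for a single association
#'
#' Wakefield's approximation to the Bayes factor comparing a normal effect
#' prior (sd `prior_sd`) with the point null, given an estimate and its SE:
#' with `V = se^2`, `W = prior_sd^2`, `z = beta/se`,
#' `log ABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W))`.
#' Computed in log space so z up to 50 stays finite.
#'
#' @param beta association estimate.
#' @param se standard error (> 0).
#' @param prior_sd prior effect standard deviation (> 0); 0.15 is the
#'   conventional default for quantitative traits and 0.2 for case-control
#'   traits on the log-odds scale.
#' @return the log approximate Bayes factor (vectorized).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("log_abf requires se > 0")
  if (any(prior_sd <= 0)) stop("log_abf requires prior_sd > 0")
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(v / (v + w)) + z2 * w / (v + w))
}

#' Colocalization of two traits at a shared locus
#'
#' Intersects the two regional summary tables on variant id, computes
#' per-SNP log-ABFs for each trait, and combines them into the posterior
#' probabilities of hypotheses H0-H4 using per-SNP priors `p1` (causal for
#' trait x only), `p2` (trait y only) and `p12` (shared). All hypothesis
#' sums are accumulated on the log scale (log-sum-exp), so extreme z-scores
#' do not overflow. Posteriors are invariant to SNP order and sum to 1.
#'
#' @param region_x,region_y summary-statistics data.frames for the locus
#'   (must share >= 10 variant ids).
#' @param p1,p2,p12 per-SNP prior probabilities (defaults `1e-4`, `1e-4`,
#'   `1e-5`).
#' @param prior_sd_x,prior_sd_y effect-prior SDs per trait (defaults 0.15
#'   quantitative-scale).
#' @return a `coloc_result` list: `pp` (named numeric, `pp0`..`pp4`),
#'   `n_snp`, `priors`, and `abf` (per-SNP log-ABF pairs).
#' @export
colocalize <- function(region_x, region_y, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd_x = 0.15, prior_sd_y = 0.15) {
  ids <- intersect(region_x$variant_id, region_y$variant_id)
  if (length(ids) < 10L)
    stop("colocalize requires >= 10 shared SNPs; got ", length(ids))
  rx <- region_x[match(ids, region_x$variant_id), , drop = FALSE]
  ry <- region_y[match(ids, region_y$variant_id), , drop = FALSE]
  lx <- log_abf(rx$beta, rx$se, prior_sd_x)
  ly <- log_abf(ry$beta, ry$se, prior_sd_y)
  lsx <- logsumexp(lx)                 # log sum_j ABF_xj
  lsy <- logsumexp(ly)
  lsxy <- logsumexp(lx + ly)           # log sum_j ABF_xj ABF_yj
  lh0 <- 0
  lh1 <- log(p1) + lsx
  lh2 <- log(p2) + lsy
  ## sum over ordered pairs j != k factorizes as (sum_j)(sum_k) - sum_j(both)
  lh3 <- log(p1) + log(p2) + logdiffexp(lsx + lsy, lsxy)
  lh4 <- log(p12) + lsxy
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("pp", 0:4)
  structure(list(pp = pp, n_snp = length(ids),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 abf = data.frame(variant_id = ids, log_abf_x = lx,
                                  log_abf_y = ly,
                                  stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>", x$n_snp, "shared SNPs\n")
  print(round(x$pp, 4))
  invisible(x)
}
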