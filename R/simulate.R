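## Synthetic two-sample GWAS summary statistics with known ground truth.
##
## Summary-level only: per-SNP standard errors follow the standard
## large-sample approximation se = 1/sqrt(2 maf (1-maf) n) for a trait in
## SD units, observed betas are drawn around the true per-SNP effects, and
## binary traits can be emitted on the linear (0/1) scale so the log-odds
## rescaling is exercised end to end.

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)

#' Ground truth for a simulated two-sample MR dataset
#'
#' Describes the data-generating world: true causal effect `theta`, per-SNP
#' instrument effects `gamma` (drawn `N(0, gamma_sd^2)` and, when
#' `strong = TRUE`, resampled until each passes genome-wide significance
#' `p < 5e-8` at the exposure sample size), per-SNP pleiotropy `alpha`
#' according to `pleiotropy_mode`, minor-allele frequencies
#' `Uniform(0.05, 0.5)`, and the two sample sizes. Identical truth + seed
#' reproduces identical summary tables.
#'
#' Pleiotropy modes: `"none"` (`alpha = 0`), `"balanced"`
#' (`alpha ~ N(0, alpha_sd^2)` on all SNPs), `"directional"`
#' (`alpha = alpha_mean`, signed to the exposure-raising allele, on a
#' fraction `frac_pleiotropic` of SNPs), `"reverse"` (the variant acts on
#' the outcome first:
#' roles of the two traits swap in the generator).
#'
#' @param n_snp number of instrument SNPs.
#' @param theta true causal effect of exposure on outcome.
#' @param n_x,n_y exposure and outcome GWAS sample sizes.
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"reverse"`.
#' @param alpha_mean directional pleiotropy magnitude (default 0.05).
#' @param alpha_sd balanced pleiotropy SD (default 0.01).
#' @param frac_pleiotropic fraction of SNPs carrying directional
#'   pleiotropy (default 1).
#' @param gamma_sd SD of the instrument-effect distribution (default
#'   0.03).
#' @param strong truncate `gamma` so each SNP passes `p < 5e-8` at `n_x`.
#' @param seed integer seed; all draws fan out from it.
#' @return an object of class `sim_truth` (list of the fields above plus
#'   `gamma`, `alpha`, `maf`).
#' @export
sim_truth <- function(n_snp = 50L, theta = 0.3, n_x = 50000, n_y = 100000,
                      pleiotropy_mode = c("none", "balanced", "directional",
                                          "reverse"),
                      alpha_mean = 0.05, alpha_sd = 0.01,
                      frac_pleiotropic = 1, gamma_sd = 0.03,
                      strong = TRUE, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_x > 10, n_y > 10)
  withr::with_seed(child_seed(seed, "truth"), {
    maf <- runif(n_snp, 0.05, 0.5)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_x)
    gamma <- rnorm(n_snp, 0, gamma_sd)
    if (strong) {
      zmin <- qnorm(1 - 5e-8 / 2)
      for (iter in 1:200) {
        weak <- abs(gamma) / se_x < zmin
        if (!any(weak)) break
        gamma[weak] <- rnorm(sum(weak), 0, gamma_sd)
      }
      ## give up on stubborn SNPs by pushing them just past the threshold
      weak <- abs(gamma) / se_x < zmin
      gamma[weak] <- sign(gamma[weak] + (gamma[weak] == 0)) *
        zmin * se_x[weak] * 1.05
    }
    alpha <- switch(pleiotropy_mode,
      none = rep(0, n_snp),
      reverse = rep(0, n_snp),
      balanced = rnorm(n_snp, 0, alpha_sd),
      directional = {
        ## aligned with the exposure-raising allele, the convention under
        ## which a constant offset shows up as the Egger intercept
        a <- rep(0, n_snp)
        k <- round(frac_pleiotropic * n_snp)
        if (k > 0) {
          sel <- sample.int(n_snp, k)
          a[sel] <- alpha_mean * sign(gamma[sel])
        }
        a
      })
    structure(list(n_snp = n_snp, theta = theta, n_x = n_x, n_y = n_y,
                   pleiotropy_mode = pleiotropy_mode, gamma = gamma,
                   alpha = alpha, maf = maf, seed = seed),
              class = "sim_truth")
  })
}

## id, chrom, pos layout: SNPs cycle over 22 chromosomes, 20 Mb apart on a
## chromosome, so default-window clumping treats them as independent
snp_layout <- function(n_snp, prefix = "rs") {
  j <- seq_len(n_snp)
  list(variant_id = paste0(prefix, j),
       chrom = as.character(((j - 1) %% 22) + 1),
       pos = 1e6 + ((j - 1) %/% 22) * 2e7)
}

assoc_table <- function(layout, ea, oa, eaf, beta, se, n,
                        n_case = NA_real_, n_control = NA_real_) {
  data.frame(variant_id = layout$variant_id, chrom = layout$chrom,
             pos = layout$pos, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), n = n,
             n_case = n_case, n_control = n_control,
             stringsAsFactors = FALSE)
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Draws observed associations around the truth:
#' `se_x = 1/sqrt(2 maf (1-maf) n_x)` (analogously for y),
#' `beta_x ~ N(gamma, se_x^2)`, `beta_y ~ N(theta*gamma + alpha, se_y^2)`;
#' p-values from the normal z. Under `pleiotropy_mode = "reverse"` the
#' variant acts on the outcome first (`beta_y ~ N(gamma, .)`,
#' `beta_x ~ N(theta*gamma, .)`). A configurable fraction of SNPs gets
#' palindromic allele pairs, and a fraction has effect/other labels
#' swapped between the two files, to exercise harmonization; both default
#' to 0 so estimator studies see exactly `n_snp` clean instruments.
#'
#' @param truth a [sim_truth()].
#' @param frac_palindromic fraction of SNPs given A/T or C/G alleles.
#' @param frac_swapped fraction of SNPs whose allele labels are swapped in
#'   the outcome file (with beta sign and eaf adjusted accordingly, so the
#'   underlying association is unchanged).
#' @param id_prefix prefix for the generated variant ids.
#' @return list with `exposure` and `outcome` summary-statistics
#'   data.frames.
#' @export
simulate_two_sample <- function(truth, frac_palindromic = 0,
                                frac_swapped = 0, id_prefix = "rs") {
  stopifnot(inherits(truth, "sim_truth"))
  if (any(truth$maf <= 0 | truth$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  withr::with_seed(child_seed(truth$seed, "tables"), {
    n_snp <- truth$n_snp
    lay <- snp_layout(n_snp, prefix = id_prefix)
    se_x <- 1 / sqrt(2 * truth$maf * (1 - truth$maf) * truth$n_x)
    se_y <- 1 / sqrt(2 * truth$maf * (1 - truth$maf) * truth$n_y)
    mu_x <- truth$gamma
    mu_y <- truth$theta * truth$gamma + truth$alpha
    if (truth$pleiotropy_mode == "reverse") {
      mu_y <- truth$gamma
      mu_x <- truth$theta * truth$gamma
    }
    beta_x <- rnorm(n_snp, mu_x, se_x)
    beta_y <- rnorm(n_snp, mu_y, se_y)
    pal <- runif(n_snp) < frac_palindromic
    pair <- matrix(NA_character_, n_snp, 2)
    pick_np <- sample.int(nrow(NONPALINDROMIC_PAIRS), n_snp, replace = TRUE)
    pick_p <- sample.int(nrow(PALINDROMIC_PAIRS), n_snp, replace = TRUE)
    pair[!pal, ] <- NONPALINDROMIC_PAIRS[pick_np[!pal], , drop = FALSE]
    pair[pal, ] <- PALINDROMIC_PAIRS[pick_p[pal], , drop = FALSE]
    eaf <- truth$maf
    exposure <- assoc_table(lay, pair[, 1], pair[, 2], eaf,
                            beta_x, se_x, truth$n_x)
    ## swapped labels in the outcome file: same association, relabeled
    swap <- runif(n_snp) < frac_swapped
    ea_y <- ifelse(swap, pair[, 2], pair[, 1])
    oa_y <- ifelse(swap, pair[, 1], pair[, 2])
    outcome <- assoc_table(lay, ea_y, oa_y,
                           ifelse(swap, 1 - eaf, eaf),
                           ifelse(swap, -beta_y, beta_y),
                           se_y, truth$n_y)
    list(exposure = exposure, outcome = outcome)
  })
}

#' Simulate a binary trait analysed on the linear scale
#'
#' Generates a log-odds-scale truth via [simulate_two_sample()] and emits
#' the outcome-side table with betas and SEs multiplied by
#' `mu * (1 - mu)` (the inverse of the log-odds scaling factor), as a
#' linear-model GWAS of a 0/1 trait would report them. By construction,
#' [scale_linear_to_logodds()] inverts the transformation exactly.
#'
#' @param truth a [sim_truth()]; its outcome side is interpreted on the
#'   log-odds scale.
#' @param n_case,n_control case/control counts (sum replaces `truth$n_y`).
#' @return the linear-scale summary table, with the log-odds-scale table
#'   attached as attribute `"logodds"`.
#' @export
simulate_binary_linear <- function(truth, n_case, n_control) {
  stopifnot(n_case > 0, n_control > 0)
  truth$n_y <- n_case + n_control
  tabs <- simulate_two_sample(truth)
  lo <- tabs$outcome
  mu <- n_case / (n_case + n_control)
  lin <- lo
  lin$beta <- lo$beta * mu * (1 - mu)
  lin$se <- lo$se * mu * (1 - mu)
  lin$n_case <- n_case
  lin$n_control <- n_control
  lo$n_case <- n_case
  lo$n_control <- n_control
  attr(lin, "logodds") <- lo
  lin
}

#' Simulate a locus for colocalization analysis
#'
#' Builds an AR(1) LD reference (`r[i, j] = rho^|i-j|`) over `n_snp`
#' consecutive variants and draws regional z-score vectors for two traits
#' from `Normal(R lambda, R)`, where `lambda` carries the non-centrality
#' `beta/se` at the causal index of each trait (shared index or two
#' distinct indices). Betas and SEs are back-computed from z and the
#' sample sizes.
#'
#' @param n_snp number of variants in the region (>= 20).
#' @param rho AR(1) LD correlation between adjacent variants, in `[0, 1)`.
#' @param shared single shared causal variant (`TRUE`) or two distinct
#'   ones (`FALSE`).
#' @param n_x,n_y sample sizes of the two regional GWAS.
#' @param beta_x,beta_y causal-variant effect sizes (per-allele, SD
#'   units); set one to 0 for a one-sided signal.
#' @param causal_x,causal_y causal indices; defaults: the region centre
#'   when shared, indices at 20% and 80% of the region otherwise.
#' @param chrom,start locus coordinates (1 kb variant spacing).
#' @param seed integer seed.
#' @param id_prefix prefix for variant ids.
#' @return list with `region_x`, `region_y` (summary tables), `ld` (an
#'   [ld_ref()]), and `causal` (the two indices).
#' @export
simulate_coloc_region <- function(n_snp = 50L, rho = 0.9, shared = TRUE,
                                  n_x = 10000, n_y = 10000,
                                  beta_x = 0.15, beta_y = 0.15,
                                  causal_x = NULL, causal_y = NULL,
                                  chrom = "1", start = 1e6, seed = 1L,
                                  id_prefix = "loc") {
  stopifnot(n_snp >= 20L)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (is.null(causal_x))
    causal_x <- if (shared) round(n_snp / 2) else round(0.2 * n_snp)
  if (is.null(causal_y))
    causal_y <- if (shared) causal_x else round(0.8 * n_snp)
  withr::with_seed(child_seed(seed, "coloc_region"), {
    r <- rho^abs(outer(seq_len(n_snp), seq_len(n_snp), "-"))
    cr <- chol(r)
    maf <- runif(n_snp, 0.1, 0.5)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_x)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_y)
    lam_x <- rep(0, n_snp); lam_x[causal_x] <- beta_x / se_x[causal_x]
    lam_y <- rep(0, n_snp); lam_y[causal_y] <- beta_y / se_y[causal_y]
    z_x <- drop(r %*% lam_x) + drop(crossprod(cr, rnorm(n_snp)))
    z_y <- drop(r %*% lam_y) + drop(crossprod(cr, rnorm(n_snp)))
    ids <- paste0(id_prefix, seq_len(n_snp))
    pos <- start + (seq_len(n_snp) - 1) * 1000
    lay <- list(variant_id = ids, chrom = rep(chrom, n_snp), pos = pos)
    region_x <- assoc_table(lay, "A", "G", maf, z_x * se_x, se_x, n_x)
    region_y <- assoc_table(lay, "A", "G", maf, z_y * se_y, se_y, n_y)
    list(region_x = region_x, region_y = region_y,
         ld = ld_ref(ids, r, positions = pos, chrom = chrom),
         causal = c(x = causal_x, y = causal_y))
  })
}

#' Simulate a synthetic phenome against one outcome GWAS
#'
#' Desk-scale stand-in for a phenome-wide screen: a mixture of
#' quantitative, binary (linear-scale, UK Biobank style) and protein
#' traits, each with its own instrument SNPs, plus a single case-control
#' outcome GWAS covering all instrument SNPs on the log-odds scale. A
#' fraction of the traits is truly causal for the outcome, with `theta`
#' drawn `N(0.3, 0.05^2)` with random sign. Proteins get a coding-gene
#' locus and an AR(1)-correlated cis region; causal proteins share their
#' causal cis variant with the outcome (so MR and colocalization should
#' both fire), non-causal proteins have a protein-only signal.
#'
#' @param n_traits number of exposure traits (>= 10).
#' @param frac_causal fraction of traits truly causal for the outcome.
#' @param frac_protein fraction of traits that are proteins.
#' @param frac_binary fraction of the non-protein traits that are binary.
#' @param n_snp_per_trait instrument SNPs per non-protein trait.
#' @param n_region_snp cis-region size for proteins.
#' @param outcome_n_case,outcome_n_control outcome GWAS case/control
#'   counts; defaults emulate a large AF case-control GWAS (60 620 cases,
#'   970 216 controls).
#' @param n_x sample size of non-protein exposure GWAS (default 50 000;
#'   proteins use 3301, a proteomics-GWAS scale).
#' @param seed integer seed; every trait has its own child stream, so
#'   adding a trait does not perturb the others.
#' @return list with `exposures` (named list of summary tables), `outcome`
#'   (summary table), `meta` (trait-metadata data.frame), `loci` (named
#'   list of gene loci for proteins), `ld` (named list of regional
#'   [ld_ref()]s for proteins), and `truth` (ledger data.frame with
#'   `trait_id`, `type`, `causal`, `theta`).
#' @export
simulate_phenome <- function(n_traits = 100L, frac_causal = 0.05,
                             frac_protein = 0.2, frac_binary = 0.3,
                             n_snp_per_trait = 30L, n_region_snp = 40L,
                             outcome_n_case = 60620,
                             outcome_n_control = 970216,
                             n_x = 50000, seed = 1L) {
  stopifnot(n_traits >= 10L)
  n_out <- outcome_n_case + outcome_n_control
  n_causal <- round(frac_causal * n_traits)
  asg <- withr::with_seed(child_seed(seed, "phenome_assign"), {
    type <- sample(c("protein", "binary", "quantitative"), n_traits,
                   replace = TRUE,
                   prob = c(frac_protein,
                            (1 - frac_protein) * frac_binary,
                            (1 - frac_protein) * (1 - frac_binary)))
    causal <- rep(FALSE, n_traits)
    if (n_causal > 0) causal[sample.int(n_traits, n_causal)] <- TRUE
    theta <- ifelse(causal, rnorm(n_traits, 0.3, 0.05) *
                      sample(c(-1, 1), n_traits, replace = TRUE), 0)
    list(type = type, causal = causal, theta = theta)
  })
  exposures <- list()
  outcome_rows <- list()
  loci <- list()
  ld <- list()
  meta_rows <- list()
  for (t in seq_len(n_traits)) {
    tid <- sprintf("trait%03d", t)
    tseed <- child_seed(seed, tid)
    if (asg$type[t] == "protein") {
      ## cis region on its own pseudo-chromosome to keep loci disjoint
      chrom <- as.character(100 + t)
      reg <- simulate_coloc_region(
        n_snp = n_region_snp, rho = 0.9,
        shared = TRUE, n_x = 3301, n_y = n_out,
        beta_x = 0.8,
        beta_y = if (asg$causal[t]) asg$theta[t] * 0.8 else 0,
        chrom = chrom, start = 5e6, seed = tseed,
        id_prefix = paste0(tid, "_")
      )
      exposures[[tid]] <- reg$region_x
      outcome_rows[[tid]] <- reg$region_y
      ld[[tid]] <- reg$ld
      centre <- 5e6 + (round(n_region_snp / 2) - 1) * 1000
      loci[[tid]] <- list(chrom = chrom, start = centre - 10000,
                          end = centre + 10000)
      n_trait <- 3301
      linear_scale <- FALSE
      units <- "SD"
    } else {
      truth <- sim_truth(n_snp = n_snp_per_trait, theta = asg$theta[t],
                         n_x = n_x, n_y = n_out, seed = tseed)
      if (asg$type[t] == "binary") {
        ## exposure itself is a UKB-style binary trait run as linear
        ## regression; the outcome side still carries theta * gamma
        tabs <- simulate_two_sample(truth, id_prefix = paste0(tid, "_rs"))
        mu <- 0.1
        ex <- tabs$exposure
        ex$beta <- ex$beta * mu * (1 - mu)
        ex$se <- ex$se * mu * (1 - mu)
        ex$n_case <- round(mu * n_x)
        ex$n_control <- n_x - round(mu * n_x)
        exposures[[tid]] <- ex
        outcome_rows[[tid]] <- tabs$outcome
        linear_scale <- TRUE
        units <- "logodds"
      } else {
        tabs <- simulate_two_sample(truth, id_prefix = paste0(tid, "_rs"))
        exposures[[tid]] <- tabs$exposure
        outcome_rows[[tid]] <- tabs$outcome
        linear_scale <- FALSE
        units <- "SD"
      }
      ## place each trait's SNPs on distinct coordinates
      shift <- t * 3e8
      exposures[[tid]]$pos <- exposures[[tid]]$pos + shift
      outcome_rows[[tid]]$pos <- outcome_rows[[tid]]$pos + shift
      n_trait <- n_x
    }
    meta_rows[[tid]] <- data.frame(
      trait_id = tid, type = asg$type[t], n = n_trait,
      n_case = if (asg$type[t] == "binary") round(0.1 * n_x) else NA_real_,
      n_control = if (asg$type[t] == "binary") n_x - round(0.1 * n_x)
                  else NA_real_,
      n_variants = 1.1e7, ancestry = "European", units = units,
      linear_scale = linear_scale, stringsAsFactors = FALSE)
  }
  outcome <- do.call(rbind, outcome_rows)
  rownames(outcome) <- NULL
  outcome$n_case <- outcome_n_case
  outcome$n_control <- outcome_n_control
  outcome$n <- n_out
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  truth_ledger <- data.frame(trait_id = names(exposures),
                             type = asg$type, causal = asg$causal,
                             theta = asg$theta, stringsAsFactors = FALSE)
  list(exposures = exposures, outcome = outcome, meta = meta,
       loci = loci, ld = ld, truth = truth_ledger, seed = seed)
}

#' Simulate a set of outcome traits downstream of one exposure
#'
#' Companion to the reverse screen: given one exposure truth (e.g. a
#' 111-SNP liability instrument), generates the exposure table once and
#' one outcome table per requested trait, each with its own causal effect
#' `theta` (0 for traits not downstream).
#'
#' @param truth a [sim_truth()] for the exposure (its `theta` is ignored).
#' @param thetas named numeric vector, one causal effect per outcome
#'   trait.
#' @param n_y outcome GWAS sample size (recycled).
#' @param seed integer seed.
#' @return list with `exposure` (summary table) and `outcomes` (named list
#'   of summary tables).
#' @export
simulate_reverse_set <- function(truth, thetas, n_y = 100000, seed = 1L) {
  base <- simulate_two_sample(truth)
  exposure <- base$exposure
  n_y <- rep_len(n_y, length(thetas))
  outcomes <- list()
  for (i in seq_along(thetas)) {
    ti <- truth
    ti$theta <- thetas[[i]]
    ti$n_y <- n_y[i]
    ti$seed <- child_seed(seed, paste0("rev_", names(thetas)[i] %||% i, i))
    outcomes[[i]] <- simulate_two_sample(ti)$outcome
  }
  names(outcomes) <- names(thetas) %||% paste0("outcome", seq_along(thetas))
  list(exposure = exposure, outcomes = outcomes)
}
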