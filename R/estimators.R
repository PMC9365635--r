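## Univariable two-sample MR estimator suite.
##
## Every result is a one-row data.frame (class mr_result) with method,
## estimate, se, ci_low, ci_high, pval, n_snp, heterogeneity Q and df, and
## (Egger only) the intercept and its SE. p-values are two-sided normal
## throughout, consistent with summary-data asymptotics. Random-effects
## convention: multiplicative variance inflation floored at 1 (no
## under-dispersion).

mr_result <- function(method, estimate = NA_real_, se = NA_real_,
                      n_snp = NA_integer_, q = NA_real_, q_df = NA_real_,
                      egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_,
                      estimable = TRUE, reason = "") {
  zc <- qnorm(0.975)
  pval <- if (estimable && is.finite(se) && se > 0)
    two_sided_p(estimate, se) else NA_real_
  if (estimable && !is.na(estimate) && estimate == 0 && is.na(pval))
    pval <- 1
  out <- data.frame(
    method = method, estimate = estimate, se = se,
    ci_low = estimate - zc * se, ci_high = estimate + zc * se,
    pval = pval, n_snp = as.integer(n_snp), q = q, q_df = q_df,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    estimable = estimable, reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_result", "data.frame")
  out
}

hs_fields <- function(h) {
  list(bx = h$beta_x, sx = h$se_x, by = h$beta_y, sy = h$se_y)
}

#' Wald ratio causal estimate from a single variant
#'
#' `estimate = beta_y / beta_x`; first-order delta-method
#' `se = |se_y / beta_x|`; normal-theory CI and p-value. Jointly flipping
#' the signs of `beta_x` and `beta_y` (an allele relabeling) leaves the
#' estimate unchanged.
#'
#' @param beta_x,se_x SNP-exposure association (beta_x must be nonzero).
#' @param beta_y,se_y SNP-outcome association.
#' @return an `mr_result` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (is.na(beta_x) || beta_x == 0)
    stop("wald_ratio requires beta_x != 0")
  mr_result("wald_ratio", estimate = beta_y / beta_x,
            se = abs(se_y / beta_x), n_snp = 1L)
}

#' Inverse-variance weighted (IVW) causal estimate
#'
#' Weighted least squares of `beta_y` on `beta_x` through the origin with
#' weights `1/se_y^2`:
#' `theta = sum(w bx by) / sum(w bx^2)`, base variance `1 / sum(w bx^2)`,
#' inflated multiplicatively by `max(1, Q/(J - 1))` where
#' `Q = sum(w (by - theta bx)^2)` is Cochran's heterogeneity statistic.
#' With a single SNP the Wald ratio is returned (with a notice in
#' `reason`).
#'
#' @param h a `harmonized_set` (or data.frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @return an `mr_result` with method `"ivw"`.
#' @export
ivw <- function(h) {
  d <- hs_fields(h)
  j <- length(d$bx)
  if (j == 0L) return(mr_result("ivw", estimable = FALSE, reason = "no_snps",
                                n_snp = 0L))
  if (j == 1L) {
    res <- wald_ratio(d$bx, d$sx, d$by, d$sy)
    res$method <- "ivw"
    res$reason <- "single_snp_wald_fallback"
    return(res)
  }
  w <- 1 / d$sy^2
  sww <- sum(w * d$bx^2)
  theta <- sum(w * d$bx * d$by) / sww
  q <- sum(w * (d$by - theta * d$bx)^2)
  infl <- max(1, q / (j - 1))
  se <- sqrt(infl / sww)
  mr_result("ivw", estimate = theta, se = se, n_snp = j, q = q, q_df = j - 1)
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` with an intercept
#' (weights `1/se_y^2`), after orienting all `beta_x >= 0` by jointly
#' flipping pairs. The slope is the causal estimate; the intercept
#' estimates the average directional pleiotropy. Variance is inflated
#' multiplicatively by `max(1, Q/(J - 2))`. Requires >= 3 SNPs and
#' non-degenerate spread in `|beta_x|`.
#'
#' @inheritParams ivw
#' @return an `mr_result` with method `"egger"` carrying the intercept and
#'   its SE.
#' @export
egger <- function(h) {
  d <- hs_fields(h)
  j <- length(d$bx)
  if (j < 3L)
    return(mr_result("egger", estimable = FALSE, reason = "fewer_than_3_snps",
                     n_snp = j))
  flip <- sign(d$bx) < 0
  bx <- abs(d$bx)
  by <- ifelse(flip, -d$by, d$by)
  w <- 1 / d$sy^2
  x <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x, w * x)
  if (abs(det(xtwx)) < 1e-300 || sd(bx) < 1e-12 ||
      kappa(xtwx) > 1e12)
    return(mr_result("egger", estimable = FALSE,
                     reason = "degenerate_beta_x", n_snp = j))
  a <- solve(xtwx)
  coefs <- drop(a %*% crossprod(x, w * by))
  resid <- by - drop(x %*% coefs)
  q <- sum(w * resid^2)
  infl <- max(1, q / (j - 2))
  ses <- sqrt(infl * diag(a))
  mr_result("egger", estimate = coefs["slope"], se = ses["slope"],
            n_snp = j, q = q, q_df = j - 2,
            egger_intercept = coefs["intercept"],
            egger_intercept_se = ses["intercept"])
}

## interpolated weighted median of ratio estimates
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(h, n_boot, seed, point_fun) {
  if (is.null(n_boot) || n_boot < 2L) return(NA_real_)
  d <- hs_fields(h)
  j <- length(d$bx)
  est <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(j, d$bx, d$sx)
      by <- rnorm(j, d$by, d$sy)
      point_fun(bx, d$sx, by, d$sy)
    }, numeric(1))
  })
  sd(est)
}

#' Weighted median causal estimate
#'
#' Consistent when SNPs carrying at least half the weight are valid
#' instruments. Per-SNP ratio estimates `theta_j = beta_y/beta_x` are
#' sorted; weights `w_j = (beta_x/se_y)^2` (the inverse variance of each
#' ratio) are normalized, and the estimate is the linear interpolation of
#' theta across the centred cumulative weights at 0.5. The SE is the
#' standard deviation of the estimate over `n_boot` parametric bootstrap
#' draws (resampling `beta_x`, `beta_y` from normal distributions centred
#' at the observations).
#'
#' @inheritParams ivw
#' @param n_boot number of parametric bootstrap draws for the SE
#'   (default 1000; `0` skips the bootstrap and reports `NA` SE).
#' @param seed integer seed for the bootstrap (mandatory in pipeline runs).
#' @return an `mr_result` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  d <- hs_fields(h)
  j <- length(d$bx)
  if (j < 3L)
    return(mr_result("weighted_median", estimable = FALSE,
                     reason = "fewer_than_3_snps", n_snp = j))
  point <- function(bx, sx, by, sy)
    weighted_median_point(by / bx, (bx / sy)^2)
  est <- point(d$bx, d$sx, d$by, d$sy)
  se <- boot_se(h, n_boot, seed, point)
  mr_result("weighted_median", estimate = est, se = se, n_snp = j)
}

mode_point <- function(bx, sx, by, sy, weighted, bandwidth_factor) {
  theta <- by / bx
  jn <- length(theta)
  w <- if (weighted) (bx / sy)^2 else rep(1, jn)
  w <- w / sum(w)
  s <- min(sd(theta), mad(theta))      # mad default constant = mad/0.6745
  h_bw <- bandwidth_factor * 0.9 * s * jn^(-1 / 5)
  if (!is.finite(h_bw) || h_bw <= 0) return(sort(theta)[1])
  grid <- seq(min(theta) - 3 * h_bw, max(theta) + 3 * h_bw, length.out = 512L)
  dens <- vapply(grid, function(g)
    sum(w * dnorm((g - theta) / h_bw)) / h_bw, numeric(1))
  grid[which.max(dens)]                # which.max -> smallest grid value wins
}

#' Mode-based causal estimate (simple or weighted)
#'
#' The estimate is the argmax of a normal-kernel-smoothed density of the
#' per-SNP ratio estimates, evaluated on a 512-point grid spanning
#' `[min - 3h, max + 3h]`. Bandwidth
#' `h = bandwidth_factor * 0.9 * min(sd, mad) * J^(-1/5)` (mad with the
#' usual 1.4826 consistency constant). Weights are uniform (simple mode)
#' or the inverse variance of the ratio estimates (weighted mode). Ties in
#' the argmax resolve to the smallest grid value; if all ratios coincide
#' the common value is returned. SE via parametric bootstrap as in
#' [weighted_median()].
#'
#' @inheritParams weighted_median
#' @param weighted use inverse-variance weights (`TRUE`) or uniform
#'   (`FALSE`).
#' @param bandwidth_factor multiplier on the default bandwidth (default 1).
#' @return an `mr_result` with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mode_estimator <- function(h, weighted = FALSE, bandwidth_factor = 1,
                           n_boot = 1000L, seed = 1L) {
  method <- if (weighted) "weighted_mode" else "simple_mode"
  d <- hs_fields(h)
  j <- length(d$bx)
  if (j < 3L)
    return(mr_result(method, estimable = FALSE,
                     reason = "fewer_than_3_snps", n_snp = j))
  point <- function(bx, sx, by, sy)
    mode_point(bx, sx, by, sy, weighted, bandwidth_factor)
  est <- point(d$bx, d$sx, d$by, d$sy)
  se <- boot_se(h, n_boot, seed, point)
  mr_result(method, estimate = est, se = se, n_snp = j)
}

#' Run the full univariable MR method suite
#'
#' Runs every estimator applicable to the instrument size: Wald ratio (1
#' SNP), IVW (>= 2), MR-Egger, weighted median, simple and weighted mode
#' (>= 3). Methods not applicable are recorded as not-estimable rows rather
#' than omitted. A sixth result, `"steiger_ivw"`, is the IVW (or Wald)
#' estimate on the Steiger-filtered subset of SNPs. Deterministic given
#' `seed`.
#'
#' @inheritParams ivw
#' @param seed integer seed controlling the bootstrap SEs.
#' @param n_boot bootstrap draws for median/mode SEs.
#' @return a data.frame of `mr_result` rows (one per method), with the
#'   Steiger detail table as attribute `"steiger_detail"`.
#' @export
run_all_methods <- function(h, seed = 1L, n_boot = 1000L) {
  j <- nrow(h)
  if (j == 0L) {
    out <- mr_result("ivw", estimable = FALSE, reason = "empty_instrument",
                     n_snp = 0L)
    return(out[0, ])
  }
  res <- list()
  if (j == 1L) {
    res$wald <- wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y)
  } else {
    res$ivw <- ivw(h)
  }
  res$egger <- egger(h)
  res$wmedian <- weighted_median(h, n_boot = n_boot,
                                 seed = child_seed(seed, "wmedian"))
  res$smode <- mode_estimator(h, weighted = FALSE, n_boot = n_boot,
                              seed = child_seed(seed, "smode"))
  res$wmode <- mode_estimator(h, weighted = TRUE, n_boot = n_boot,
                              seed = child_seed(seed, "wmode"))
  st <- steiger_filter(h)
  if (nrow(st$filtered) == 0L) {
    res$steiger <- mr_result("steiger_ivw", estimable = FALSE,
                             reason = "no_snps_after_steiger", n_snp = 0L)
  } else if (nrow(st$filtered) == 1L) {
    res$steiger <- wald_ratio(st$filtered$beta_x, st$filtered$se_x,
                              st$filtered$beta_y, st$filtered$se_y)
    res$steiger$method <- "steiger_ivw"
    res$steiger$reason <- "single_snp_wald_fallback"
  } else {
    res$steiger <- ivw(st$filtered)
    res$steiger$method <- "steiger_ivw"
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "steiger_detail") <- st$detail
  out
}
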