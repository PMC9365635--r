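## Multivariable MR on summary statistics plus conditional instrument
## strength, and the staged category -> final model builder.

#' Bundle summary data for a multivariable MR model
#'
#' @param B_x J x K matrix of SNP-exposure betas (columns named by
#'   exposure).
#' @param se_x J x K matrix of corresponding SEs.
#' @param b_y length-J vector of SNP-outcome betas.
#' @param se_y length-J vector of SNP-outcome SEs.
#' @param variant_ids optional ids for the J instruments.
#' @return an object of class `mvmr_input`.
#' @export
mvmr_input <- function(B_x, se_x, b_y, se_y, variant_ids = NULL) {
  B_x <- as.matrix(B_x); se_x <- as.matrix(se_x)
  stopifnot(nrow(B_x) == length(b_y), length(b_y) == length(se_y),
            all(dim(B_x) == dim(se_x)))
  if (is.null(colnames(B_x)))
    colnames(B_x) <- paste0("exposure", seq_len(ncol(B_x)))
  colnames(se_x) <- colnames(B_x)
  structure(list(B_x = B_x, se_x = se_x, b_y = b_y, se_y = se_y,
                 variant_ids = variant_ids %||%
                   paste0("snp", seq_along(b_y))),
            class = "mvmr_input")
}

#' Multivariable MR direct effects
#'
#' Weighted least squares of the SNP-outcome betas on the K columns of
#' SNP-exposure betas, no intercept, weights `1/se_y^2`. Per-exposure SEs
#' come from the weighted regression with multiplicative variance inflation
#' floored at 1 (df `J - K`). Cross-exposure sampling covariance is taken
#' as zero (no overlap information is available from summary data). With
#' K = 1 this reduces exactly to univariable IVW.
#'
#' @param input an [mvmr_input()].
#' @param kappa_max condition-number threshold above which the design is
#'   declared collinear (default `1e8`).
#' @return data.frame with one row per exposure: `exposure`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `pval`, plus attributes `q`, `q_df`.
#' @export
mvmr_fit <- function(input, kappa_max = 1e8) {
  x <- input$B_x
  jn <- nrow(x); k <- ncol(x)
  if (jn <= k) stop("mvmr_fit requires more instruments than exposures")
  w <- 1 / input$se_y^2
  xtwx <- crossprod(x, w * x)
  if (kappa(xtwx, exact = TRUE) > kappa_max)
    stop("collinear exposure betas: condition number above threshold")
  a <- solve(xtwx)
  est <- drop(a %*% crossprod(x, w * input$b_y))
  resid <- input$b_y - drop(x %*% est)
  q <- sum(w * resid^2)
  infl <- max(1, q / (jn - k))
  ses <- sqrt(infl * diag(a))
  zc <- qnorm(0.975)
  out <- data.frame(exposure = colnames(x), estimate = est, se = ses,
                    ci_low = est - zc * ses, ci_high = est + zc * ses,
                    pval = two_sided_p(est, ses),
                    n_snp = jn, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "q") <- q
  attr(out, "q_df") <- jn - k
  out
}

#' Conditional F statistics for MVMR exposures
#'
#' For exposure k, the instrument betas are regressed (no intercept,
#' weights `1/se_xk^2`) on the betas of the other exposures; the weighted
#' residual sum of squares `Q_k` gives the conditional
#' `F_k = Q_k / (J - K + 1)`. This measures instrument strength for
#' exposure k once the other exposures are accounted for; shared or
#' correlated instruments drive it below the univariable F, which is
#' reported alongside (`mean (beta/se)^2`). With K = 1 the conditional F
#' equals the univariable mean F.
#'
#' @param input an [mvmr_input()].
#' @return data.frame with `exposure`, `conditional_f`, `univariable_f`.
#' @export
conditional_f <- function(input) {
  x <- input$B_x
  jn <- nrow(x); k <- ncol(x)
  if (jn <= k) stop("conditional_f requires more instruments than exposures")
  out <- data.frame(exposure = colnames(x),
                    conditional_f = NA_real_, univariable_f = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    w <- 1 / input$se_x[, i]^2
    y <- x[, i]
    if (k == 1L) {
      resid <- y
    } else {
      z <- x[, -i, drop = FALSE]
      a <- solve(crossprod(z, w * z))
      resid <- y - drop(z %*% (a %*% crossprod(z, w * y)))
    }
    out$conditional_f[i] <- sum(w * resid^2) / (jn - k + 1)
    out$univariable_f[i] <- mean((y / input$se_x[, i])^2)
  }
  out
}

subset_input <- function(input, exposures) {
  mvmr_input(input$B_x[, exposures, drop = FALSE],
             input$se_x[, exposures, drop = FALSE],
             input$b_y, input$se_y, input$variant_ids)
}

fit_stage <- function(input, exposures) {
  sub <- subset_input(input, exposures)
  fit <- mvmr_fit(sub)
  fit$conditional_f <- conditional_f(sub)$conditional_f
  fit
}

#' Staged multivariable model building across exposure categories
#'
#' Mirrors the category-wise workflow used when many correlated risk
#' factors pass a univariable screen: (A/B) fit an MVMR model within each
#' category and keep exposures with direct-effect `p < 0.05` (strict);
#' (C) pool the within-category survivors with any listed singleton
#' factors and fit a joint model; (D) refit on the stage-C survivors. The
#' full audit trail of every stage is returned.
#'
#' @param input an [mvmr_input()] whose columns cover every exposure.
#' @param categories named list of character vectors grouping exposures
#'   that share a feature (e.g. anthropometry, blood pressure).
#' @param singletons exposures entering stage C directly, outside any
#'   category.
#' @param p_keep survival threshold between stages (default 0.05, strict
#'   `<`).
#' @return list with `final` (the stage-D fit), `stages` (named list of
#'   per-stage fits), and `survivors` (per-stage character vectors).
#' @export
staged_model_builder <- function(input, categories, singletons = character(0),
                                 p_keep = 0.05) {
  stages <- list()
  survivors <- list()
  stage_ab <- character(0)
  for (nm in names(categories)) {
    ex <- categories[[nm]]
    if (length(ex) == 1L) {
      fit <- fit_stage(input, ex)
    } else {
      fit <- fit_stage(input, ex)
    }
    stages[[paste0("category_", nm)]] <- fit
    keep <- fit$exposure[!is.na(fit$pval) & fit$pval < p_keep]
    survivors[[paste0("category_", nm)]] <- keep
    stage_ab <- c(stage_ab, keep)
  }
  pool <- unique(c(stage_ab, singletons))
  if (length(pool) == 0L)
    stop("no exposure survived the within-category stage")
  fit_c <- fit_stage(input, pool)
  stages[["stage_C"]] <- fit_c
  keep_c <- fit_c$exposure[!is.na(fit_c$pval) & fit_c$pval < p_keep]
  survivors[["stage_C"]] <- keep_c
  if (length(keep_c) == 0L)
    stop("no exposure survived the pooled stage-C model")
  fit_d <- fit_stage(input, keep_c)
  stages[["stage_D"]] <- fit_d
  survivors[["stage_D"]] <-
    fit_d$exposure[!is.na(fit_d$pval) & fit_d$pval < p_keep]
  list(final = fit_d, stages = stages, survivors = survivors)
}
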