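#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm rnorm runif rbinom sd mad median dnorm
#'   setNames complete.cases
#' @importFrom utils head
NULL

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b")
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

#' Derive a reproducible child seed from a parent seed
#'
#' One global seed fans out to independent per-component streams so that
#' adding a trait or stage to a simulation does not perturb the draws of the
#' others. The mixing is a small integer hash kept below 2^31.
#'
#' @param seed parent integer seed.
#' @param key character or integer label of the component stream.
#' @return an integer seed.
#' @export
child_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  key <- as.character(key)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 2654435 + h * 97 + 13) %% 2147483629)
}

two_sided_p <- function(est, se) {
  p <- 2 * pnorm(-abs(est / se))
  p[!is.finite(est / se)] <- NA_real_
  ## guard p = 0 underflow is acceptable; keep within (0, 1]
  pmax(pmin(p, 1), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
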