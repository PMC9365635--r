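## Data model and I/O for GWAS summary statistics.
##
## A summary-statistics table is a plain data.frame with one row per variant
## association: variant_id, chrom, pos (1-based bp), effect_allele,
## other_allele, eaf, beta, se, pval, n, n_case, n_control. Optional fields
## may be NA. Invariants: se > 0, pval in (0, 1], 0 < eaf < 1 when present,
## effect_allele != other_allele, n_case + n_control == n when both present.

#' Default column map for tab-delimited GWAS summary files
#'
#' Maps the common GWAS header names to the internal field names. Override
#' individual entries to read files with non-standard headers.
#'
#' @return named character vector `internal_field = file_column`.
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N",
    n_case = "NCASE", n_control = "NCONTROL")
}

required_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "pval", "n")
optional_fields <- c("eaf", "n_case", "n_control")

#' Read and validate a GWAS summary-statistics file
#'
#' Reads a tab-delimited file with a header, renames columns according to
#' `column_map`, validates every row against the field invariants, drops
#' invalid rows, and resolves duplicated variant ids by keeping the record
#' with the smallest p-value. The number of rows dropped per reason is
#' attached as the `"report"` attribute.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param column_map named character vector mapping internal field names to
#'   file column names; defaults to [default_column_map()]. Optional fields
#'   (`eaf`, `n_case`, `n_control`) may be absent from the file.
#' @return a validated summary-statistics `data.frame` with a `"report"`
#'   attribute (named integer vector of drop counts).
#' @export
read_summary_stats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  missing_req <- required_fields[!map[required_fields] %in% names(raw)]
  if (length(missing_req) > 0L) {
    stop("missing required column(s): ",
         paste(map[missing_req], collapse = ", "))
  }
  cols <- lapply(c(required_fields, optional_fields), function(f) {
    col <- map[[f]]
    if (col %in% names(raw)) raw[[col]] else rep(NA, nrow(raw))
  })
  names(cols) <- c(required_fields, optional_fields)
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  out$variant_id <- as.character(out$variant_id)
  out$chrom <- as.character(out$chrom)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control"))
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  validate_assoc_table(out)
}

#' Validate a summary-statistics table against the field invariants
#'
#' @param tab a summary-statistics data.frame.
#' @return the table with invalid rows dropped and a `"report"` attribute.
#' @export
validate_assoc_table <- function(tab) {
  report <- c(bad_se = 0L, bad_pval = 0L, bad_eaf = 0L, bad_alleles = 0L,
              bad_n = 0L, missing_core = 0L, duplicate_id = 0L)
  core_ok <- !is.na(tab$variant_id) & !is.na(tab$beta) & !is.na(tab$se) &
    !is.na(tab$pval) & !is.na(tab$n)
  report["missing_core"] <- sum(!core_ok)
  se_ok <- !is.na(tab$se) & tab$se > 0
  p_ok <- !is.na(tab$pval) & tab$pval > 0 & tab$pval <= 1
  eaf_ok <- is.na(tab$eaf) | (tab$eaf > 0 & tab$eaf < 1)
  al_ok <- !is.na(tab$effect_allele) & !is.na(tab$other_allele) &
    tab$effect_allele != tab$other_allele
  n_ok <- is.na(tab$n_case) | is.na(tab$n_control) |
    abs(tab$n_case + tab$n_control - tab$n) < 0.5
  report["bad_se"] <- sum(core_ok & !se_ok)
  report["bad_pval"] <- sum(core_ok & se_ok & !p_ok)
  report["bad_eaf"] <- sum(core_ok & se_ok & p_ok & !eaf_ok)
  report["bad_alleles"] <- sum(core_ok & se_ok & p_ok & eaf_ok & !al_ok)
  report["bad_n"] <- sum(core_ok & se_ok & p_ok & eaf_ok & al_ok & !n_ok)
  keep <- core_ok & se_ok & p_ok & eaf_ok & al_ok & n_ok
  tab <- tab[keep, , drop = FALSE]
  ## duplicate variant ids: keep the smallest p
  if (anyDuplicated(tab$variant_id)) {
    ord <- order(tab$pval, seq_len(nrow(tab)))
    tab <- tab[ord, , drop = FALSE]
    dup <- duplicated(tab$variant_id)
    report["duplicate_id"] <- sum(dup)
    tab <- tab[!dup, , drop = FALSE]
    tab <- tab[order(tab$chrom, tab$pos, tab$variant_id), , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "report") <- report
  tab
}

#' Write a summary-statistics table in the tab-delimited interchange format
#'
#' @param tab summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(tab, path) {
  map <- default_column_map()
  out <- tab[, intersect(names(map), names(tab)), drop = FALSE]
  names(out) <- map[names(out)]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Rescale a linear-model effect for a binary trait to the log-odds scale
#'
#' GWAS of binary traits run as linear regressions (as in UK Biobank rapid
#' pipelines) report effects on the 0/1 scale. These are converted to
#' approximate log odds by multiplying beta and SE by
#' `1 / (mu * (1 - mu))` where `mu = n_case / (n_case + n_control)` is the
#' case fraction. The factor is symmetric in `mu <-> 1 - mu`.
#'
#' @param beta linear-model effect estimate.
#' @param se linear-model standard error.
#' @param n_case,n_control case and control counts (both > 0).
#' @return list with `beta`, `se` on the log-odds scale, the `factor`
#'   applied, and `scaled = TRUE`.
#' @export
scale_linear_to_logodds <- function(beta, se, n_case, n_control) {
  if (any(is.na(n_case)) || any(is.na(n_control)) ||
      any(n_case <= 0) || any(n_control <= 0)) {
    stop("scale_linear_to_logodds requires n_case > 0 and n_control > 0")
  }
  mu <- n_case / (n_case + n_control)
  fac <- 1 / (mu * (1 - mu))
  list(beta = beta * fac, se = se * fac, factor = fac, scaled = TRUE)
}

#' Rescale all rows of a binary-trait summary table to log odds
#'
#' Applies [scale_linear_to_logodds()] row-wise using the table's case and
#' control counts. A `"logodds_scaled"` attribute guards against double
#' scaling: tables already scaled are returned unchanged.
#'
#' @param tab summary-statistics data.frame with `n_case`, `n_control`.
#' @return the rescaled table, flagged with `attr(, "logodds_scaled")`.
#' @export
scale_assoc_table <- function(tab) {
  if (isTRUE(attr(tab, "logodds_scaled"))) return(tab)
  sc <- scale_linear_to_logodds(tab$beta, tab$se, tab$n_case, tab$n_control)
  tab$beta <- sc$beta
  tab$se <- sc$se
  attr(tab, "logodds_scaled") <- TRUE
  tab
}
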