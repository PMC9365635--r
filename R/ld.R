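## LD reference: an ordered variant-id list with a signed correlation matrix
## and bp positions. Stands in for an external panel such as 1000 Genomes.

#' Construct an LD reference
#'
#' @param variant_ids ordered character vector of variant ids.
#' @param r square matrix of signed LD correlations, rows/cols in the order
#'   of `variant_ids`; must be symmetric with unit diagonal and entries in
#'   `[-1, 1]`.
#' @param positions bp coordinates aligned to `variant_ids` (optional).
#' @param chrom chromosome labels aligned to `variant_ids` (optional;
#'   recycled if length 1).
#' @return an object of class `ld_ref`.
#' @export
ld_ref <- function(variant_ids, r, positions = NULL, chrom = NULL) {
  variant_ids <- as.character(variant_ids)
  r <- as.matrix(r)
  stopifnot(nrow(r) == length(variant_ids), ncol(r) == length(variant_ids))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (any(r > 1 + 1e-8) || any(r < -1 - 1e-8))
    stop("LD correlations must lie in [-1, 1]")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r = r,
                 positions = positions,
                 chrom = if (!is.null(chrom)) rep_len(chrom, length(variant_ids))),
            class = "ld_ref")
}

#' @export
print.ld_ref <- function(x, ...) {
  cat("<ld_ref>", length(x$variant_ids), "variants\n")
  invisible(x)
}

#' Signed LD correlation between two variants
#'
#' @param ld an `ld_ref` or `NULL` (no panel available).
#' @param id1,id2 variant ids.
#' @return the signed correlation, or `NA` if either variant is absent from
#'   the reference (or the reference is `NULL`).
#' @export
ld_r <- function(ld, id1, id2) {
  if (is.null(ld)) return(NA_real_)
  i <- match(id1, ld$variant_ids)
  j <- match(id2, ld$variant_ids)
  if (is.na(i) || is.na(j)) return(NA_real_)
  ld$r[i, j]
}

#' Read an LD reference from a dense matrix file
#'
#' Expects a variant-id list file (one id per line, optionally with a second
#' and third whitespace-separated column giving chromosome and bp position)
#' and a whitespace-delimited square matrix file of signed correlations.
#'
#' @param ids_path path to the variant-id list.
#' @param matrix_path path to the dense correlation matrix.
#' @return an `ld_ref`.
#' @export
read_ld_matrix <- function(ids_path, matrix_path) {
  ids <- utils::read.table(ids_path, header = FALSE,
                           stringsAsFactors = FALSE)
  r <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  ld_ref(ids[[1]], r,
         positions = if (ncol(ids) >= 3) as.numeric(ids[[3]]),
         chrom = if (ncol(ids) >= 2) as.character(ids[[2]]))
}

#' Read an LD reference from a long-format triplet file
#'
#' Each row is `id1 id2 r` (whitespace-delimited, no header). Diagonal
#' entries are implied; unlisted pairs are taken as r = 0.
#'
#' @param path path to the triplet file.
#' @param positions optional named vector of bp positions.
#' @return an `ld_ref`.
#' @export
read_ld_triplets <- function(path, positions = NULL) {
  tr <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id1", "id2", "r"))
  ids <- sort(unique(c(tr$id1, tr$id2)))
  r <- diag(length(ids))
  dimnames(r) <- list(ids, ids)
  for (k in seq_len(nrow(tr))) {
    r[tr$id1[k], tr$id2[k]] <- tr$r[k]
    r[tr$id2[k], tr$id1[k]] <- tr$r[k]
  }
  ld_ref(ids, r,
         positions = if (!is.null(positions)) unname(positions[ids]))
}
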