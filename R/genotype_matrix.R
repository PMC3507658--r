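#' Construct a genotype matrix
#'
#' The sole real input of the detection pipeline: unphased SNP genotypes on one
#' chromosome for a set of closely related individuals, together with a
#' disease-status label per individual. Genotypes are coded per site as
#' 0 (homozygous for allele 0), 1 (homozygous for allele 1) or 2
#' (heterozygous); `NA` marks a missing call, which must be removed with
#' [drop_missing_sites()] before any analysis.
#'
#' @param codes integer matrix, sites x individuals, values in \{0, 1, 2, NA\}.
#'   Row names (SNP ids) and column names (individual ids) are used when
#'   present; defaults are generated otherwise.
#' @param status character vector, one of `"affected"`/`"unaffected"` per
#'   individual (recycled names from `codes` columns when unnamed).
#' @param snp_index integer vector of 1-based ordinals identifying each site in
#'   the original (pre-filtering) site list. Defaults to `1:nrow(codes)`.
#' @param allow_missing logical; if `FALSE` (default) any `NA` code is an
#'   error. Readers construct with `allow_missing = TRUE` and callers filter
#'   with [drop_missing_sites()].
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `status`, `snp_index`.
#' @export
genotype_matrix <- function(codes, status, snp_index = NULL,
                            allow_missing = FALSE) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) < 1L) stop("genotype matrix needs at least one SNP site")
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("ind", seq_len(ncol(codes)))
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("snp", seq_len(nrow(codes)))
  if (anyDuplicated(colnames(codes)))
    stop("duplicate individual ids")
  if (anyDuplicated(rownames(codes)))
    stop("duplicate SNP ids")
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!allow_missing && anyNA(codes))
    stop("missing genotype codes present; run drop_missing_sites() first")
  status <- match.arg(status, c("affected", "unaffected"), several.ok = TRUE)
  status <- rep_len(status, ncol(codes))
  if (!any(status == "affected") || !any(status == "unaffected"))
    stop("need at least one affected and one unaffected individual")
  if (is.null(snp_index)) snp_index <- seq_len(nrow(codes))
  snp_index <- as.integer(snp_index)
  if (length(snp_index) != nrow(codes) || is.unsorted(snp_index, strictly = TRUE))
    stop("snp_index must be strictly increasing, one per site")
  names(status) <- colnames(codes)
  structure(
    list(codes = codes, status = status, snp_index = snp_index),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d SNP sites x %d individuals (%d affected, %d unaffected)\n",
    nrow(x$codes), ncol(x$codes),
    sum(x$status == "affected"), sum(x$status == "unaffected")
  ))
  if (anyNA(x$codes))
    cat(sprintf("  %d sites contain missing calls\n",
                sum(apply(is.na(x$codes), 1L, any))))
  invisible(x)
}

#' Number of sites / individuals in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer count
#' @export
n_sites <- function(gm) nrow(gm$codes)

#' @rdname n_sites
#' @export
n_individuals <- function(gm) ncol(gm$codes)

#' Indices of affected individuals (columns), affected first ordering helper
#' @param gm a [genotype_matrix()]
#' @return integer column indices
#' @keywords internal
affected_cols <- function(gm) which(gm$status == "affected")

#' @keywords internal
unaffected_cols <- function(gm) which(gm$status == "unaffected")

#' Remove sites with missing genotype calls
#'
#' Deletes every SNP site at which any individual has a missing call; the
#' standard pre-processing step before window phasing. By default the
#' surviving sites are re-indexed 1..S' and all downstream coordinates refer
#' to this filtered frame; the original ordinals remain available in the
#' `original_index` attribute (and via `report = "original"` in
#' [detect_regions()]).
#'
#' @param gm a [genotype_matrix()]
#' @return a `genotype_matrix` without missing calls; attribute
#'   `original_index` maps the filtered sites back to the input ordinals.
#' @export
drop_missing_sites <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- !apply(is.na(gm$codes), 1L, any)
  if (!any(keep)) stop("no usable sites: every SNP has a missing call")
  orig <- gm$snp_index[keep]
  out <- genotype_matrix(gm$codes[keep, , drop = FALSE], gm$status,
                         snp_index = seq_len(sum(keep)))
  attr(out, "original_index") <- orig
  out
}
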