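# File formats: genotype TSV, region report TSV, pedigree TSV, genetic map TSV,
# and biallelic VCF input. The TSV grammars are documented in the README.

#' Read a genotype TSV file
#'
#' Format (tab separated, UTF-8):
#' ```
#' #STATUS  D        U        ...
#' snp_id   ind1     ind2     ...
#' rs1      0        2        ...
#' ```
#' Line 1 gives the disease status per individual (`D` affected,
#' `U` unaffected); line 2 the individual ids; each following row one SNP.
#' Codes are `0`, `1`, `2` or `N` (missing). Missing calls are retained as
#' `NA`; filter with [drop_missing_sites()].
#'
#' @param path file path
#' @return a [genotype_matrix()] (possibly containing missing calls)
#' @export
read_genotype_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("genotype file must have a #STATUS line, a header line and >= 1 SNP row")
  st <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (st[1L] != "#STATUS")
    stop("line 1 must start with #STATUS")
  hd <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (hd[1L] != "snp_id")
    stop("line 2 must be a header starting with snp_id")
  ids <- hd[-1L]
  if (length(st) - 1L != length(ids))
    stop("status line and header disagree on the number of individuals")
  stat <- st[-1L]
  if (!all(stat %in% c("D", "U")))
    stop("statuses must be D or U")
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(ids) + 1L))
    stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                 which(nf != length(ids) + 1L)[1L] + 2L,
                 length(ids) + 1L, nf[nf != length(ids) + 1L][1L]))
  snp_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(snp_ids))
    stop(sprintf("duplicate snp_id '%s'", snp_ids[duplicated(snp_ids)][1L]))
  cells <- t(vapply(rows, function(r) r[-1L], character(length(ids))))
  if (length(ids) == 1L) cells <- matrix(cells, ncol = 1L)
  ok <- cells %in% c("0", "1", "2", "N")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(cells)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code '%s' at line %d",
                 cells[bad[1L], bad[2L]], bad[1L] + 2L))
  }
  codes <- matrix(NA_integer_, nrow(cells), ncol(cells))
  codes[cells == "0"] <- 0L
  codes[cells == "1"] <- 1L
  codes[cells == "2"] <- 2L
  rownames(codes) <- snp_ids
  colnames(codes) <- ids
  genotype_matrix(codes, ifelse(stat == "D", "affected", "unaffected"),
                  allow_missing = TRUE)
}

#' Write a genotype TSV file
#'
#' Inverse of [read_genotype_tsv()]; `read(write(x))` round-trips byte for
#' byte on canonical input.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cells <- matrix(as.character(gm$codes), nrow = nrow(gm$codes))
  cells[is.na(gm$codes)] <- "N"
  lines <- c(
    paste(c("#STATUS", ifelse(gm$status == "affected", "D", "U")),
          collapse = "\t"),
    paste(c("snp_id", colnames(gm$codes)), collapse = "\t"),
    paste(rownames(gm$codes),
          apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a biallelic VCF
#'
#' Converts unphased or phased GT fields of biallelic SNP records to ternary
#' codes: `0/0` -> 0, `1/1` -> 1, `0/1` or `1/0` -> 2, `./.` or `.` -> missing.
#' Multi-allelic records are skipped (a message reports how many).
#'
#' @param path VCF file path (plain or bgzipped)
#' @param sample_status named character vector mapping sample id to
#'   `"affected"`/`"unaffected"`; every name must be a sample in the VCF.
#'   Samples absent from the map are dropped.
#' @return a [genotype_matrix()] (possibly containing missing calls)
#' @export
read_vcf_genotypes <- function(path, sample_status) {
  if (is.null(names(sample_status)) || any(!nzchar(names(sample_status))))
    stop("sample_status must be a named vector (names are VCF sample ids)")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_samples <- setdiff(names(sample_status), colnames(gt))
  if (length(missing_samples))
    stop("samples not in VCF: ", paste(missing_samples, collapse = ", "))
  bi <- vcfR::is.biallelic(vcf)
  n_skip <- sum(!bi)
  if (n_skip > 0L)
    message(sprintf("skipping %d multi-allelic record(s)", n_skip))
  gt <- gt[bi, names(sample_status), drop = FALSE]
  norm <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow(norm), ncol(norm),
                  dimnames = dimnames(norm))
  codes[norm %in% "0/0"] <- 0L
  codes[norm %in% "1/1"] <- 1L
  codes[norm %in% c("0/1", "1/0")] <- 2L
  unknown <- !is.na(norm) & !(norm %in% c("0/0", "1/1", "0/1", "1/0", "./."))
  if (any(unknown))
    stop("unexpected GT value: ", norm[unknown][1L])
  if (anyDuplicated(rownames(codes)))
    rownames(codes) <- make.unique(rownames(codes))
  genotype_matrix(codes, sample_status, allow_missing = TRUE)
}

#' Write a mutation-region report
#'
#' TSV with columns `start`, `end`, `length`, `dh`, `score`; coordinates are
#' 1-based inclusive SNP ordinals. Rows are written in input order (callers
#' sort by descending score; equal scores keep their order).
#'
#' @param regions data frame with columns `start`, `end`, `dh`, `score`
#'   (a `length` column is recomputed)
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_regions <- function(regions, path) {
  stopifnot(all(c("start", "end", "dh", "score") %in% names(regions)))
  df <- data.frame(
    start = as.integer(regions$start),
    end = as.integer(regions$end),
    length = as.integer(regions$end - regions$start + 1L),
    dh = as.integer(regions$dh),
    score = as.integer(regions$score)
  )
  lines <- c("start\tend\tlength\tdh\tscore",
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mutation-region report written by [write_regions()]
#' @param path file path
#' @return data frame with columns start, end, length, dh, score
#' @export
read_regions <- function(path) {
  utils::read.delim(path, colClasses = "integer")
}

#' Inclusive SNP count of a region
#'
#' Number of SNP sites in the closed interval `[start, end]` of 1-based
#' ordinals; the LENGTH term of the region score.
#'
#' @param start,end 1-based inclusive SNP ordinals, `start <= end`
#' @return integer site count
#' @export
region_length <- function(start, end) {
  stopifnot(all(start <= end))
  as.integer(end - start + 1L)
}
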