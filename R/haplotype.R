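# Partial haplotypes are integer vectors over {0, 1, NA}; NA is the wild card
# (a position not yet forced by any genotype). Genotype segments are integer
# vectors over {0, 1, 2}. String forms ("10*11", "10211") are accepted by the
# user-facing helpers for convenience in worked examples and the CLI.

#' Convert between string and vector forms of segments
#'
#' `as_genotype_seg()` parses a genotype string over `0/1/2`;
#' `as_haplotype_seg()` parses a haplotype string over `0/1/*` (wild card);
#' `seg_string()` renders an integer vector back to a string, writing `*` for
#' `NA`.
#'
#' @param x a character scalar or an integer vector (returned unchanged after
#'   validation)
#' @return integer vector (or character scalar for `seg_string`)
#' @export
as_genotype_seg <- function(x) {
  v <- parse_seg(x, c("0", "1", "2"))
  if (!all(v %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  v
}

#' @rdname as_genotype_seg
#' @export
as_haplotype_seg <- function(x) {
  v <- parse_seg(x, c("0", "1", "*"))
  if (!all(v %in% c(0L, 1L) | is.na(v))) stop("haplotype values must be 0, 1 or *")
  v
}

parse_seg <- function(x, alphabet) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    bad <- !(ch %in% alphabet)
    if (any(bad)) stop(sprintf("invalid symbol '%s'", ch[bad][1L]))
    v <- match(ch, c("0", "1", "2")) - 1L  # "*" -> NA
    v
  } else {
    as.integer(x)
  }
}

#' @rdname as_genotype_seg
#' @export
seg_string <- function(x) {
  ch <- as.character(x)
  ch[is.na(x)] <- "*"
  paste(ch, collapse = "")
}

#' Compute the center haplotype shared by all affected individuals
#'
#' Position-wise over the window: if any affected individual is homozygous 0
#' (and none homozygous 1) the center is 0; symmetrically for 1; if all are
#' heterozygous the value is a wild card (`NA`); if both a homozygous 0 and a
#' homozygous 1 occur among the affected, no center exists and the first such
#' conflicting position is reported.
#'
#' @param affected_segs list/character vector of genotype segments (equal
#'   length), or an integer matrix with one column per segment
#' @return on success, an integer partial haplotype; on conflict, an object of
#'   class `center_conflict` carrying `$position` (1-based within the window)
#' @export
compute_center <- function(affected_segs) {
  m <- segs_to_matrix(affected_segs)
  if (ncol(m) < 1L) stop("need at least one affected segment")
  has0 <- rowSums(m == 0L) > 0L
  has1 <- rowSums(m == 1L) > 0L
  conflict <- has0 & has1
  if (any(conflict)) {
    return(structure(list(position = which(conflict)[1L]),
                     class = "center_conflict"))
  }
  out <- rep(NA_integer_, nrow(m))
  out[has0] <- 0L
  out[has1] <- 1L
  out
}

#' @export
print.center_conflict <- function(x, ...) {
  cat(sprintf("center conflict: affected genotypes carry both 0 and 1 at position %d\n",
              x$position))
  invisible(x)
}

segs_to_matrix <- function(segs) {
  if (is.matrix(segs)) {
    storage.mode(segs) <- "integer"
    return(segs)
  }
  if (is.character(segs)) segs <- lapply(segs, as_genotype_seg)
  if (!is.list(segs)) segs <- list(as.integer(segs))
  lens <- lengths(segs)
  if (length(unique(lens)) != 1L) stop("segments must have equal length")
  matrix(unlist(lapply(segs, as.integer)), nrow = lens[1L])
}

#' Complementary haplotype of a genotype given one haplotype
#'
#' Applies the explanation rules: where the genotype is homozygous both
#' haplotypes equal it; where heterozygous the complement is `1 - h` when `h`
#' is determined and a wild card otherwise.
#'
#' @param g genotype segment (string or integer vector)
#' @param h partial haplotype (string or integer vector), position-wise
#'   consistent with `g`
#' @return integer partial haplotype
#' @export
complement_pair <- function(g, h) {
  g <- as_genotype_seg(g); h <- as_haplotype_seg(h)
  stopifnot(length(g) == length(h))
  bad <- !is.na(h) & g != 2L & g != h
  if (any(bad))
    stop(sprintf("haplotype inconsistent with genotype at position %d",
                 which(bad)[1L]))
  out <- h
  hom <- g != 2L
  out[hom] <- g[hom]
  het <- g == 2L & !is.na(h)
  out[het] <- 1L - h[het]
  out[g == 2L & is.na(h)] <- NA_integer_
  out
}

#' Can a partial haplotype solve a genotype segment?
#'
#' TRUE iff at every position a determined haplotype value is compatible with
#' the genotype (0 needs genotype 0 or 2; 1 needs 1 or 2). Wild card
#' positions impose no constraint.
#'
#' @param h partial haplotype
#' @param g genotype segment
#' @return logical scalar
#' @export
can_solve <- function(h, g) {
  h <- as_haplotype_seg(h); g <- as_genotype_seg(g)
  stopifnot(length(g) == length(h))
  !any(!is.na(h) & ((h == 0L & g == 1L) | (h == 1L & g == 0L)))
}

#' Merge two compatible partial haplotypes
#'
#' Two partial haplotypes are compatible when no position carries a determined
#' 0 in one and a determined 1 in the other. The merge takes the determined
#' value wherever at least one side has it, keeping wild cards only where both
#' are undetermined.
#'
#' @param h1,h2 partial haplotypes of equal length
#' @return the merged integer partial haplotype, or `NULL` when incompatible
#' @export
merge_compatible <- function(h1, h2) {
  h1 <- as_haplotype_seg(h1); h2 <- as_haplotype_seg(h2)
  stopifnot(length(h1) == length(h2))
  if (any(!is.na(h1) & !is.na(h2) & h1 != h2)) return(NULL)
  out <- h1
  fill <- is.na(h1) & !is.na(h2)
  out[fill] <- h2[fill]
  out
}

#' Infer a shared haplotype from a pair of genotype segments
#'
#' Two genotype segments can share a haplotype when no position has a
#' homozygous 0 in one and a homozygous 1 in the other. The shared haplotype
#' takes the homozygous value wherever either segment has one and a wild card
#' where both are heterozygous; each segment's other haplotype is the
#' complement.
#'
#' @param g1,g2 genotype segments of equal length
#' @return `NULL` when the pair cannot share, otherwise a list with elements
#'   `shared`, `other1`, `other2` (integer partial haplotypes)
#' @export
infer_shared_pair <- function(g1, g2) {
  g1 <- as_genotype_seg(g1); g2 <- as_genotype_seg(g2)
  stopifnot(length(g1) == length(g2))
  if (any((g1 == 0L & g2 == 1L) | (g1 == 1L & g2 == 0L))) return(NULL)
  shared <- rep(NA_integer_, length(g1))
  shared[g1 == 0L | g2 == 0L] <- 0L
  shared[g1 == 1L | g2 == 1L] <- 1L
  list(shared = shared,
       other1 = complement_pair(g1, shared),
       other2 = complement_pair(g2, shared))
}
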