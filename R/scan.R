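# Whole-chromosome scan: tile into fixed-length windows, phase each, merge
# valid windows across gaps of unavoidable-sharing windows, refine boundaries,
# extend position by position, and score the resulting candidate regions.
# All user-facing coordinates are 1-based inclusive SNP ordinals.

# Phase a span of a genotype matrix. Duplicate genotype segments within the
# affected set (and within the unaffected set) are collapsed before phasing —
# the model assumes distinct segments, and duplicates carry the same haplotype
# pair so the distinct-haplotype count is unchanged.
phase_span <- function(gm, from, to) {
  aff <- affected_cols(gm)
  una <- unaffected_cols(gm)
  sub <- gm$codes[from:to, c(aff, una), drop = FALSE]
  k <- length(aff)
  keyA <- apply(sub[, seq_len(k), drop = FALSE], 2L, paste, collapse = "")
  keyB <- if (length(una))
    apply(sub[, k + seq_along(una), drop = FALSE], 2L, paste, collapse = "")
  else character(0)
  selA <- !duplicated(keyA)
  selB <- !duplicated(keyB)
  ph <- phase_window_int(
    cbind(sub[, seq_len(k), drop = FALSE][, selA, drop = FALSE],
          sub[, k + seq_along(una), drop = FALSE][, selB, drop = FALSE]),
    sum(selA))
  # map original individuals (affected first) to phased columns
  map <- c(match(keyA, keyA[selA]),
           if (length(una)) sum(selA) + match(keyB, keyB[selB]))
  list(phase = ph, map = map, cols = c(aff, una))
}

# Expand a deduplicated phase back to one haplotype pair per input individual
# (rows: individual-1 haplotype 1, individual-1 haplotype 2, ... in the
# affected-first column order returned by phase_span).
expand_haplotypes <- function(sp) {
  stopifnot(sp$phase$status == "valid")
  rows <- as.vector(rbind(2L * sp$map - 1L, 2L * sp$map))
  sp$phase$haplotypes[rows, , drop = FALSE]
}

#' Tile a chromosome into windows and phase each
#'
#' Decomposes the site range into consecutive windows of `L` sites (the last
#' window may be shorter) and classifies each with [phase_window()].
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param L window length in SNP sites (default 500)
#' @return object of class `window_grid`: list with `grid` (data frame with
#'   columns `start`, `end`, `status`) and `L`
#' @export
scan_windows <- function(gm, L = 500L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (anyNA(gm$codes)) stop("missing calls present; run drop_missing_sites()")
  L <- as.integer(L)
  if (L < 2L) stop("window length must be at least 2")
  S <- n_sites(gm)
  starts <- seq.int(1L, S, by = L)
  ends <- pmin(starts + L - 1L, S)
  status <- character(length(starts))
  for (w in seq_along(starts)) {
    status[w] <- phase_span(gm, starts[w], ends[w])$phase$status
  }
  structure(list(grid = data.frame(start = starts, end = ends,
                                   status = status),
                 L = L),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of length %d (%d valid, %d case_conflict, %d control_shares_center)\n",
              nrow(x$grid), x$L,
              sum(x$grid$status == "valid"),
              sum(x$grid$status == "case_conflict"),
              sum(x$grid$status == "control_shares_center")))
  invisible(x)
}

#' Merge valid windows into longer candidate spans
#'
#' Two valid (or already merged) spans are merged when the gap between them is
#' at most `2L` SNP sites and every grid window inside the gap has status
#' `control_shares_center` (an affected-genotype conflict in the gap blocks the
#' merge). Merging proceeds left to right until no further merge applies.
#'
#' @param grid a [scan_windows()] result
#' @return data frame with columns `start`, `end` (1-based inclusive spans)
#' @export
merge_valid <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  g <- grid$grid
  L <- grid$L
  vi <- which(g$status == "valid")
  if (!length(vi)) return(data.frame(start = integer(0), end = integer(0)))
  spans <- lapply(vi, function(i) c(i, i))  # window-index ranges
  out <- list(spans[[1L]])
  for (sp in spans[-1L]) {
    last <- out[[length(out)]]
    gap_windows <- if (sp[1L] > last[2L] + 1L) (last[2L] + 1L):(sp[1L] - 1L)
                   else integer(0)
    gap_sites <- g$start[sp[1L]] - g$end[last[2L]] - 1L
    if (gap_sites <= 2L * L &&
        all(g$status[gap_windows] == "control_shares_center")) {
      out[[length(out)]] <- c(last[1L], sp[2L])
    } else {
      out[[length(out) + 1L]] <- sp
    }
  }
  data.frame(
    start = vapply(out, function(sp) g$start[sp[1L]], integer(1L)),
    end = vapply(out, function(sp) g$end[sp[2L]], integer(1L))
  )
}

#' Refine the boundaries of a merged span
#'
#' Tries, longest first, the span widened by half a window on each side, by a
#' fifth of a window, and the span itself (all clamped to the chromosome), and
#' keeps the longest candidate that still phases as valid.
#'
#' @param start,end 1-based inclusive bounds of a merged span
#' @param gm the [genotype_matrix()]
#' @param L window length used in the scan
#' @return list with `b`, `e` (refined bounds), `phase` (the `phase_span`
#'   result on them), or `NULL` when no candidate phases as valid
#' @export
refine_boundaries <- function(start, end, gm, L = 500L) {
  S <- n_sites(gm)
  exts <- c(L %/% 2L, L %/% 5L, 0L)
  cand <- unique(data.frame(b = pmax(1L, start - exts),
                            e = pmin(S, end + exts)))
  cand <- cand[order(cand$e - cand$b, decreasing = TRUE), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    sp <- phase_span(gm, cand$b[r], cand$e[r])
    if (sp$phase$status == "valid")
      return(list(b = cand$b[r], e = cand$e[r], phase = sp))
  }
  NULL
}

#' Extend a refined region position by position
#'
#' Starting from the identity classes of identical resolved haplotypes on the
#' refined region, each flanking position is annexed in turn (leftwards from
#' `b - 1`, then rightwards from `e + 1`). At a position, any class in which
#' some member's genotype is homozygous takes that allele; complements of the
#' members' genotypes propagate the value recursively through the other
#' classes. A contradiction (two members homozygous for opposite alleles, or a
#' propagated value clashing with an already-set one) makes the position
#' conflicting: it is excluded and extension in that direction stops. A
#' position where every genotype is heterozygous imposes no constraint and is
#' annexed.
#'
#' @param b,e refined region bounds (1-based inclusive)
#' @param haplotypes 2n x (e-b+1) matrix of resolved haplotypes on `[b, e]`
#'   in slot order (see [phase_window()]), individuals ordered as
#'   affected-first
#' @param gm the [genotype_matrix()] (columns reordered internally to match)
#' @param cols column indices of `gm$codes` matching the haplotype rows
#'   (default affected first)
#' @return integer vector `c(rb, re)`, the maximal extended closed interval
#' @export
extend_region <- function(b, e, haplotypes, gm,
                          cols = c(affected_cols(gm), unaffected_cols(gm))) {
  codes <- gm$codes[, cols, drop = FALSE]
  S <- nrow(codes)
  nslot <- nrow(haplotypes)
  key <- apply(haplotypes, 1L, paste, collapse = "")
  cls <- match(key, unique(key))
  m <- max(cls)
  seg <- slot_seg(seq_len(nslot))
  partner_cls <- cls[slot_partner(seq_len(nslot))]
  members <- split(seq_len(nslot), cls)

  pos_ok <- function(p) {
    vals <- rep(NA_integer_, m)
    stack <- list()
    for (cid in seq_len(m)) {
      gv <- codes[p, seg[members[[cid]]]]
      h0 <- any(gv == 0L); h1 <- any(gv == 1L)
      if (h0 && h1) return(FALSE)
      if (h0) stack[[length(stack) + 1L]] <- c(cid, 0L)
      else if (h1) stack[[length(stack) + 1L]] <- c(cid, 1L)
    }
    while (length(stack)) {
      it <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      cid <- it[1L]; v <- it[2L]
      if (!is.na(vals[cid])) {
        if (vals[cid] != v) return(FALSE)
        next
      }
      vals[cid] <- v
      for (s in members[[cid]]) {
        gs <- codes[p, seg[s]]
        if (gs != 2L) {
          if (gs != v) return(FALSE)
        } else {
          stack[[length(stack) + 1L]] <- c(partner_cls[s], 1L - v)
        }
      }
    }
    TRUE
  }

  rb <- b
  p <- b - 1L
  while (p >= 1L && pos_ok(p)) {
    rb <- p
    p <- p - 1L
  }
  re <- e
  p <- e + 1L
  while (p <= S && pos_ok(p)) {
    re <- p
    p <- p + 1L
  }
  c(rb, re)
}

#' Score a candidate region
#'
#' `SCORE = (2n - DH) * LENGTH`: a region is ranked higher the longer it is
#' and the fewer distinct haplotypes it takes to explain all `n` input
#' genotypes on it (`DH` distinct haplotypes out of a possible `2n`).
#'
#' @param n number of input individuals
#' @param dh number of distinct haplotypes on the region, `1 <= dh <= 2n`
#' @param rb,re 1-based inclusive region bounds
#' @return integer score
#' @export
score_region <- function(n, dh, rb, re) {
  if (any(dh > 2L * n)) stop("dh cannot exceed 2n")
  stopifnot(all(dh >= 1L), all(rb <= re))
  as.integer((2L * n - dh) * region_length(rb, re))
}

#' Detect candidate mutation regions on a chromosome
#'
#' Full pipeline: window scan, merging of valid windows, boundary refinement,
#' position-wise extension, and scoring. All detected regions are reported,
#' sorted by descending score (equal scores keep left-to-right order). The
#' distinct-haplotype count of a region is recomputed on the extended interval
#' when it phases as valid, and falls back to the refined interval's count
#' otherwise (the extension applies only conflict checks, not the full
#' sharing conditions).
#'
#' @param gm a [genotype_matrix()] without missing calls
#' @param L window length in SNP sites (default 500)
#' @param bridge_gap merge reported regions separated by at most this many
#'   sites before scoring (0 = off). A single genotyping error inside a true
#'   region splits it into two reported regions separated by one conflicting
#'   site; `bridge_gap = 1` glues such pairs back together.
#' @param report `"filtered"` (default) reports ordinals in the current site
#'   frame; `"original"` maps them through the pre-filtering ordinals stored
#'   by [drop_missing_sites()].
#' @return data frame with columns `start`, `end`, `length`, `dh`, `score`,
#'   sorted by descending score; attribute `"details"` keeps the merged and
#'   refined bounds per region.
#' @export
detect_regions <- function(gm, L = 500L, bridge_gap = 0L,
                           report = c("filtered", "original")) {
  report <- match.arg(report)
  n <- n_individuals(gm)
  grid <- scan_windows(gm, L)
  spans <- merge_valid(grid)
  regions <- list()
  for (r in seq_len(nrow(spans))) {
    ref <- refine_boundaries(spans$start[r], spans$end[r], gm, L)
    if (is.null(ref)) {
      warning(sprintf("span [%d,%d] failed re-validation; dropped",
                      spans$start[r], spans$end[r]))
      next
    }
    haps <- expand_haplotypes(ref$phase)
    ext <- extend_region(ref$b, ref$e, haps, gm, cols = ref$phase$cols)
    dh <- ref$phase$phase$dh
    if (ext[1L] < ref$b || ext[2L] > ref$e) {
      rp <- phase_span(gm, ext[1L], ext[2L])
      if (rp$phase$status == "valid") dh <- rp$phase$dh
    }
    regions[[length(regions) + 1L]] <-
      list(sb = spans$start[r], se = spans$end[r],
           b = ref$b, e = ref$e, rb = ext[1L], re = ext[2L], dh = dh)
  }
  if (!length(regions)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), dh = integer(0),
                      score = integer(0))
    attr(out, "details") <- data.frame()
    return(out)
  }
  # keep reported regions disjoint: clip overlapping extensions at the
  # midpoint of the overlap
  ord <- order(vapply(regions, `[[`, integer(1L), "rb"))
  regions <- regions[ord]
  for (i in seq_along(regions)[-1L]) {
    prev <- regions[[i - 1L]]
    cur <- regions[[i]]
    if (cur$rb <= prev$re) {
      mid <- (prev$re + cur$rb) %/% 2L
      regions[[i - 1L]]$re <- min(prev$re, mid)
      regions[[i]]$rb <- max(cur$rb, mid + 1L)
    }
  }
  if (bridge_gap > 0L && length(regions) > 1L) {
    merged <- list(regions[[1L]])
    for (i in seq_along(regions)[-1L]) {
      last <- merged[[length(merged)]]
      cur <- regions[[i]]
      if (cur$rb - last$re - 1L <= bridge_gap) {
        last$re <- cur$re
        rp <- phase_span(gm, last$rb, last$re)
        last$dh <- if (rp$phase$status == "valid") rp$phase$dh
                   else max(last$dh, cur$dh)
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- cur
      }
    }
    regions <- merged
  }
  det <- do.call(rbind, lapply(regions, function(x)
    data.frame(merged_start = x$sb, merged_end = x$se,
               refined_start = x$b, refined_end = x$e,
               start = x$rb, end = x$re, dh = x$dh)))
  det$score <- score_region(n, det$dh, det$start, det$end)
  det <- det[order(-det$score, det$start), , drop = FALSE]
  out <- data.frame(start = det$start, end = det$end,
                    length = region_length(det$start, det$end),
                    dh = det$dh, score = det$score)
  if (report == "original") {
    orig <- attr(gm, "original_index")
    if (is.null(orig))
      stop("no original index available; matrix was not filtered")
    out$start <- orig[out$start]
    out$end <- orig[out$end]
  }
  rownames(out) <- NULL
  attr(out, "details") <- det
  out
}
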