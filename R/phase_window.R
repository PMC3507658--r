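# Window phasing under the parsimony sharing model.
#
# A window is phased so that (1) every affected individual carries one common
# "center" haplotype, (2) no unaffected individual carries it, and (3) the
# number of distinct haplotypes stays small, by propagating Clark's inference
# rule through a system of identity classes. Each individual contributes two
# haplotype "slots"; slots constrained to be identical share a class holding a
# partial haplotype (0/1/NA with NA the wild card). Determining a wild card in
# one class propagates through the complement relation of every explained
# genotype until fixpoint.
#
# Slots are numbered 2i-1 (first haplotype) and 2i (second) for individual i;
# affected individuals occupy columns 1..k of the genotype matrix.

slot_seg <- function(s) (s + 1L) %/% 2L
slot_partner <- function(s) s + ifelse(s %% 2L == 1L, 1L, -1L)

new_phase_state <- function(gen, k) {
  n <- ncol(gen)
  list(
    L = nrow(gen), n = n, k = k, gen = gen,
    class_of = integer(2L * n),
    members = list(), values = list(), alive = logical(0),
    solved = c(rep(TRUE, k), rep(FALSE, n - k)),
    queue = integer(0),
    P = if (n > k) (k + 1L):n else integer(0)
  )
}

ps_new_class <- function(st, slots, value) {
  id <- length(st$values) + 1L
  st$values[[id]] <- as.integer(value)
  st$members[[id]] <- as.integer(slots)
  st$alive[id] <- TRUE
  st$class_of[slots] <- id
  list(st = st, id = id)
}

# Assign values at positions of a class, propagating through complements.
# Returns the updated state, or NULL on contradiction.
ps_assign <- function(st, cls, pos, val) {
  wl <- list(list(cls, as.integer(pos), as.integer(val)))
  while (length(wl)) {
    it <- wl[[length(wl)]]
    wl[[length(wl)]] <- NULL
    cls <- it[[1L]]; pos <- it[[2L]]; val <- it[[3L]]
    cur <- st$values[[cls]][pos]
    known <- !is.na(cur)
    if (any(known & cur != val)) return(NULL)
    todo <- !known
    if (!any(todo)) next
    pos <- pos[todo]; val <- val[todo]
    v <- st$values[[cls]]
    v[pos] <- val
    st$values[[cls]] <- v
    for (s in st$members[[cls]]) {
      g <- st$gen[pos, slot_seg(s)]
      if (any(g != 2L & g != val)) return(NULL)
      het <- g == 2L
      if (any(het)) {
        wl[[length(wl) + 1L]] <-
          list(st$class_of[slot_partner(s)], pos[het], 1L - val[het])
      }
    }
  }
  st
}

# After a slot joins a class, mirror the class's already-determined values
# onto the slot's partner through the complement rules.
ps_enforce_slot <- function(st, cls, s) {
  v <- st$values[[cls]]
  g <- st$gen[, slot_seg(s)]
  det <- !is.na(v)
  if (any(det & g != 2L & g != v)) return(NULL)
  het <- det & g == 2L
  if (any(het)) {
    st <- ps_assign(st, st$class_of[slot_partner(s)], which(het), 1L - v[het])
  }
  st
}

# Merge class `from` into class `to`. Refuses merges that would place both
# slots of one individual in the same class (their haplotypes must be
# complementary at heterozygous sites, not identical). NULL on contradiction.
ps_merge <- function(st, from, to) {
  if (from == to) return(st)
  v_to <- st$values[[to]]; v_from <- st$values[[from]]
  if (any(!is.na(v_to) & !is.na(v_from) & v_to != v_from)) return(NULL)
  ms <- c(st$members[[to]], st$members[[from]])
  if (anyDuplicated(slot_seg(ms))) return(NULL)
  moved <- st$members[[from]]
  st$class_of[moved] <- to
  st$members[[to]] <- ms
  st$members[[from]] <- integer(0)
  st$alive[from] <- FALSE
  st$queue <- st$queue[st$queue != from]
  fill <- !is.na(v_from) & is.na(v_to)
  if (any(fill)) {
    st <- ps_assign(st, to, which(fill), v_from[fill])
    if (is.null(st)) return(NULL)
  }
  for (s in moved) {
    st <- ps_enforce_slot(st, to, s)
    if (is.null(st)) return(NULL)
  }
  st
}

# Attempt to solve unaffected segment j with class `cls` (Clark's rule).
# Returns list(st, new_class) or NULL if the class cannot solve j.
ps_try_solve <- function(st, cls, j) {
  h <- st$values[[cls]]
  g <- st$gen[, j]
  if (any(!is.na(h) & ((h == 0L & g == 1L) | (h == 1L & g == 0L))))
    return(NULL)
  s1 <- 2L * j - 1L
  s2 <- s1 + 1L
  st$class_of[s1] <- cls
  st$members[[cls]] <- c(st$members[[cls]], s1)
  h2 <- h
  hom <- g != 2L
  h2[hom] <- g[hom]
  het_det <- g == 2L & !is.na(h)
  h2[het_det] <- 1L - h[het_det]
  h2[g == 2L & is.na(h)] <- NA_integer_
  res <- ps_new_class(st, s2, h2)
  st <- res$st
  st$solved[j] <- TRUE
  det_g <- hom & is.na(h)
  if (any(det_g)) {
    st <- ps_assign(st, cls, which(det_g), g[det_g])
    if (is.null(st)) return(NULL)
  }
  list(st = st, new_class = res$id)
}

# Merge a freshly created class with the earliest compatible class currently
# in the queue, or enqueue it as new. Always succeeds (falls back to enqueue).
ps_absorb_into_queue <- function(st, newc) {
  for (qc in st$queue) {
    st2 <- ps_merge(st, newc, qc)
    if (!is.null(st2)) return(st2)
  }
  st$queue <- c(st$queue, newc)
  st
}

# Phase the remaining unsolved segments so neither haplotype can match the
# center: pick determined mismatches with the current center value where they
# exist; leave positions heterozygous against a center wild card undetermined
# (the resolution step separates them, or fails the window).
ps_finalize_unsolved <- function(st) {
  cvec <- st$values[[1L]]
  for (j in st$P) {
    g <- st$gen[, j]
    cdet <- !is.na(cvec)
    typeA <- any(g != 2L & cdet & cvec != g)
    typeB <- which(g == 2L & cdet)
    h1 <- h2 <- rep(NA_integer_, st$L)
    hom <- g != 2L
    h1[hom] <- h2[hom] <- g[hom]
    if (length(typeB)) {
      h1[typeB] <- cvec[typeB]
      h2[typeB] <- 1L - cvec[typeB]
      if (!typeA) {
        h1[typeB[1L]] <- 1L - cvec[typeB[1L]]
        h2[typeB[1L]] <- cvec[typeB[1L]]
      }
    }
    s1 <- 2L * j - 1L
    res <- ps_new_class(st, s1, h1); st <- res$st
    res <- ps_new_class(st, s1 + 1L, h2); st <- res$st
    st$solved[j] <- TRUE
  }
  st$P <- integer(0)
  st
}

# ---------------------------------------------------------------------------
# Wild-card resolution.
#
# Undetermined positions of linked classes are coupled: wherever an explained
# genotype is heterozygous and both of its classes are undetermined, the two
# classes must take complementary values (a parity/XOR constraint). Per
# position, linked components get the orientation producing more zeros (ties:
# the component representative takes 0). A greedy repair pass then flips
# component orientations so that no unaffected individual's haplotype equals
# the resolved center; if it cannot, the window has no admissible phasing.
# ---------------------------------------------------------------------------

ps_resolve <- function(st) {
  n <- st$n; k <- st$k; L <- st$L
  cls_ids <- which(st$alive & lengths(st$members) > 0L)
  nc <- length(cls_ids)
  row_of <- integer(length(st$values))
  row_of[cls_ids] <- seq_len(nc)

  # defensive closure: mirror any lone determined value across complements
  for (i in seq_len(n)) {
    c1 <- st$class_of[2L * i - 1L]; c2 <- st$class_of[2L * i]
    v1 <- st$values[[c1]]; v2 <- st$values[[c2]]
    g <- st$gen[, i]
    het <- g == 2L
    one_det <- het & xor(is.na(v1), is.na(v2))
    if (any(one_det)) {
      p1 <- which(one_det & is.na(v1))
      if (length(p1)) st <- ps_assign(st, c1, p1, 1L - st$values[[c2]][p1])
      if (is.null(st)) return(NULL)
      p2 <- which(one_det & !is.na(st$values[[c1]]) &
                    is.na(st$values[[c2]]))
      if (length(p2)) st <- ps_assign(st, c2, p2, 1L - st$values[[c1]][p2])
      if (is.null(st)) return(NULL)
    }
    v1 <- st$values[[c1]]; v2 <- st$values[[c2]]
    both <- het & !is.na(v1) & !is.na(v2)
    if (any(v1[both] + v2[both] != 1L)) return(NULL)
    hom <- !het
    if (any(!is.na(v1[hom]) & v1[hom] != g[hom])) return(NULL)
    if (any(!is.na(v2[hom]) & v2[hom] != g[hom])) return(NULL)
  }

  vals <- do.call(rbind, lapply(cls_ids, function(cid) st$values[[cid]]))
  vals <- matrix(as.integer(vals), nrow = nc)
  slots_per_row <- lengths(st$members[cls_ids])

  # per-position parity components over undetermined classes
  na_pos <- which(colSums(is.na(vals)) > 0L)
  comp <- vector("list", length(na_pos))   # per position: root & parity per row
  names(comp) <- as.character(na_pos)
  orient <- list()                          # "<pos>:<root>" -> 0/1 flip state
  res <- vals

  for (pi in seq_along(na_pos)) {
    p <- na_pos[pi]
    und <- which(is.na(vals[, p]))
    root <- seq_len(nc); par <- integer(nc)  # over row indices; only und used
    ufind <- function(x) {
      pr <- 0L
      while (root[x] != x) { pr <- bitwXor(pr, par[x]); x <- root[x] }
      c(x, pr)
    }
    for (i in seq_len(n)) {
      if (st$gen[p, i] != 2L) next
      r1 <- row_of[st$class_of[2L * i - 1L]]
      r2 <- row_of[st$class_of[2L * i]]
      if (!is.na(vals[r1, p]) || !is.na(vals[r2, p])) next
      if (r1 == r2) return(NULL)  # class complementary to itself
      f1 <- ufind(r1); f2 <- ufind(r2)
      if (f1[1L] == f2[1L]) {
        if (bitwXor(f1[2L], f2[2L]) != 1L) return(NULL)  # odd cycle
      } else {
        root[f2[1L]] <- f1[1L]
        par[f2[1L]] <- bitwXor(1L, bitwXor(f1[2L], f2[2L]))
      }
    }
    fr <- t(vapply(und, ufind, integer(2L)))
    comp[[pi]] <- list(rows = und, root = fr[, 1L], par = fr[, 2L])
    for (r in unique(fr[, 1L])) {
      sel <- fr[, 1L] == r
      w0 <- sum(slots_per_row[und[sel][fr[sel, 2L] == 0L]])
      w1 <- sum(slots_per_row[und[sel][fr[sel, 2L] == 1L]])
      a <- if (w1 > w0) 1L else 0L
      orient[[paste0(p, ":", r)]] <- a
      res[und[sel], p] <- bitwXor(a, fr[sel, 2L])
    }
  }

  center_row <- row_of[1L]
  normal_rows <- which(vapply(cls_ids, function(cid) {
    any(slot_seg(st$members[[cid]]) > k)
  }, logical(1L)))
  normal_rows <- setdiff(normal_rows, center_row)

  dangerous <- function(res) {
    cr <- res[center_row, ]
    normal_rows[vapply(normal_rows, function(r) all(res[r, ] == cr),
                       logical(1L))]
  }

  flip <- function(res, p, r0) {
    key <- paste0(p, ":", r0)
    orient[[key]] <<- 1L - orient[[key]]
    ci <- comp[[as.character(p)]]
    sel <- ci$root == r0
    res[ci$rows[sel], p] <- bitwXor(orient[[key]], ci$par[sel])
    res
  }

  dang <- dangerous(res)
  guard <- 0L
  while (length(dang)) {
    guard <- guard + 1L
    if (guard > nc + 5L) return(NULL)
    d <- dang[1L]
    fixed <- FALSE
    # candidate flips: components of d's own wild cards not containing the
    # center, then components of the center's wild cards
    cand <- list()
    for (p in na_pos[is.na(vals[d, na_pos])]) {
      ci <- comp[[as.character(p)]]
      r0 <- ci$root[match(d, ci$rows)]
      in_comp <- ci$rows[ci$root == r0]
      if (center_row %in% in_comp) next
      cand[[length(cand) + 1L]] <- c(p, r0)
    }
    for (p in na_pos[is.na(vals[center_row, na_pos])]) {
      ci <- comp[[as.character(p)]]
      r0 <- ci$root[match(center_row, ci$rows)]
      cand[[length(cand) + 1L]] <- c(p, r0)
    }
    for (cd in cand) {
      res2 <- flip(res, cd[1L], cd[2L])
      dang2 <- dangerous(res2)
      if (length(dang2) < length(dang)) {
        res <- res2; dang <- dang2; fixed <- TRUE
        break
      }
      res <- flip(res2, cd[1L], cd[2L])  # revert
    }
    if (!fixed) return(NULL)
  }

  hap <- matrix(NA_integer_, 2L * n, L)
  for (s in seq_len(2L * n)) hap[s, ] <- res[row_of[st$class_of[s]], ]
  list(haplotypes = hap,
       center = res[center_row, ],
       dh = nrow(unique(hap)))
}

# ---------------------------------------------------------------------------

#' Phase one window under the parsimony sharing model
#'
#' Runs the full window-phasing procedure: computes the center haplotype from
#' the affected genotype segments, derives their complements, solves the
#' unaffected segments with Clark's inference rule (re-using and merging
#' partial haplotypes to keep the number of distinct haplotypes small), falls
#' back to shared-pair inference when no known haplotype applies, and finally
#' resolves remaining wild cards.
#'
#' @param affected_segs,unaffected_segs genotype segments (character vector of
#'   strings over 0/1/2, list of integer vectors, or integer matrix with one
#'   column per segment). Segments within each set must be pairwise distinct;
#'   a segment may appear in both sets.
#' @return an object of class `window_phase` with elements:
#'   * `status`: `"valid"` (a phasing satisfying the sharing conditions was
#'     found), `"case_conflict"` (two affected genotypes are homozygous for
#'     opposite alleles at some position, so no shared haplotype exists), or
#'     `"control_shares_center"` (every phasing forces some unaffected
#'     individual to carry the center haplotype);
#'   * `conflict_position`: 1-based window position of the first affected
#'     conflict (only for `case_conflict`);
#'   * `haplotypes`: 2n x L integer matrix of resolved haplotypes in slot
#'     order (individual 1 haplotype 1, individual 1 haplotype 2, ...), only
#'     for `valid`;
#'   * `center`: the resolved center haplotype (only for `valid`);
#'   * `dh`: number of distinct resolved haplotypes (only for `valid`);
#'   * `k`, `n`: affected and total segment counts.
#' @examples
#' out <- phase_window(c("10211", "12221", "10221"), "10121")
#' out$status   # "valid"
#' out$dh       # 4
#' @export
phase_window <- function(affected_segs, unaffected_segs = NULL) {
  A <- segs_to_matrix(affected_segs)
  if (!is.null(unaffected_segs) && length(unaffected_segs)) {
    B <- segs_to_matrix(unaffected_segs)
    if (nrow(B) != nrow(A)) stop("segments must have equal length")
  } else {
    B <- matrix(integer(0), nrow = nrow(A), ncol = 0L)
  }
  if (anyDuplicated(t(A)) || (ncol(B) > 1L && anyDuplicated(t(B))))
    stop("segments within one set must be pairwise distinct")
  phase_window_int(cbind(A, B), ncol(A))
}

phase_window_int <- function(gen, k) {
  n <- ncol(gen)
  center <- compute_center(gen[, seq_len(k), drop = FALSE])
  if (inherits(center, "center_conflict")) {
    return(structure(list(status = "case_conflict",
                          conflict_position = center$position,
                          haplotypes = NULL, center = NULL,
                          dh = NA_integer_, k = k, n = n, state = NULL),
                     class = "window_phase"))
  }
  st <- new_phase_state(gen, k)
  res <- ps_new_class(st, 2L * seq_len(k) - 1L, center)
  st <- res$st
  # affected complements; identical partial haplotypes share one class
  for (i in seq_len(k)) {
    h2 <- complement_pair(gen[, i], center)
    hit <- 0L
    for (qc in st$queue) {
      if (identical(st$values[[qc]], h2)) { hit <- qc; break }
    }
    if (hit > 0L) {
      st$members[[hit]] <- c(st$members[[hit]], 2L * i)
      st$class_of[2L * i] <- hit
    } else {
      res <- ps_new_class(st, 2L * i, h2)
      st <- res$st
      st$queue <- c(st$queue, res$id)
    }
  }

  repeat {
    while (length(st$queue) && length(st$P)) {
      cls <- st$queue[1L]
      st$queue <- st$queue[-1L]
      for (j in st$P) {
        if (st$solved[j]) next
        attempt <- ps_try_solve(st, cls, j)
        if (is.null(attempt)) next
        st2 <- ps_absorb_into_queue(attempt$st, attempt$new_class)
        st2$P <- setdiff(st2$P, j)
        st <- st2
      }
    }
    if (length(st$P) < 2L) break
    found <- FALSE
    Pv <- st$P
    for (a in seq_len(length(Pv) - 1L)) {
      for (b in (a + 1L):length(Pv)) {
        j1 <- Pv[a]; j2 <- Pv[b]
        sp <- infer_shared_pair(st$gen[, j1], st$gen[, j2])
        if (is.null(sp)) next
        res <- ps_new_class(st, c(2L * j1 - 1L, 2L * j2 - 1L), sp$shared)
        st <- res$st; c_sh <- res$id
        res <- ps_new_class(st, 2L * j1, sp$other1)
        st <- res$st; c_a <- res$id
        res <- ps_new_class(st, 2L * j2, sp$other2)
        st <- res$st; c_b <- res$id
        st$solved[c(j1, j2)] <- TRUE
        st$P <- setdiff(st$P, c(j1, j2))
        st <- ps_absorb_into_queue(st, c_sh)
        for (cid in c(c_a, c_b)) {
          if (st$alive[cid]) st <- ps_absorb_into_queue(st, cid)
        }
        found <- TRUE
        break
      }
      if (found) break
    }
    if (!found) break
  }

  st <- ps_finalize_unsolved(st)
  r <- ps_resolve(st)
  if (is.null(r)) {
    return(structure(list(status = "control_shares_center",
                          conflict_position = NA_integer_,
                          haplotypes = NULL, center = NULL,
                          dh = NA_integer_, k = k, n = n, state = st),
                     class = "window_phase"))
  }
  structure(list(status = "valid", conflict_position = NA_integer_,
                 haplotypes = r$haplotypes, center = r$center, dh = r$dh,
                 k = k, n = n, state = st),
            class = "window_phase")
}

#' @export
print.window_phase <- function(x, ...) {
  cat(sprintf("window_phase: status=%s, k=%d affected of n=%d\n",
              x$status, x$k, x$n))
  if (x$status == "valid") {
    cat(sprintf("  center: %s\n  distinct haplotypes: %d\n",
                seg_string(x$center), x$dh))
  } else if (x$status == "case_conflict") {
    cat(sprintf("  conflicting position (window-relative): %d\n",
                x$conflict_position))
  }
  invisible(x)
}
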