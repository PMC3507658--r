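# Independent reference implementations ("oracles") used by the property
# tests. These are deliberately naive: direct scans and exhaustive
# enumerations whose correctness is obvious by inspection.

# Random genotype instance: S x n matrix over {0,1,2}, first k columns
# affected. Within-set duplicate columns are resampled so the instance is
# accepted by phase_window().
rand_instance <- function(S, k, n_un) {
  if (3^S < max(k, n_un))
    stop("impossible shape: fewer possible columns than distinct individuals")
  repeat {
    g <- matrix(sample(0:2, S * (k + n_un), replace = TRUE), nrow = S)
    ka <- apply(g[, seq_len(k), drop = FALSE], 2, paste, collapse = "")
    ku <- apply(g[, k + seq_len(n_un), drop = FALSE], 2, paste, collapse = "")
    if (!anyDuplicated(ka) && !anyDuplicated(ku)) return(g)
  }
}

# Direct conflicting-position scan: an affected-set conflict exists iff some
# position carries both homozygous genotypes among the affected columns.
direct_case_conflict <- function(aff) {
  any(apply(aff, 1, function(r) any(r == 0L) && any(r == 1L)))
}

# Full solution check for a valid phase: haplotypes resolved to 0/1,
# Clark-consistency (C1/C2) with every genotype, every affected pair contains
# the center, no unaffected haplotype equals the center, and the reported
# distinct-haplotype count is right.
check_valid_phase <- function(ph, gen, k) {
  hap <- ph$haplotypes
  n <- ncol(gen)
  if (anyNA(hap)) return("unresolved haplotype value")
  if (!all(hap %in% c(0L, 1L))) return("non-binary haplotype value")
  if (anyNA(ph$center)) return("unresolved center value")
  for (i in seq_len(n)) {
    h1 <- hap[2L * i - 1L, ]
    h2 <- hap[2L * i, ]
    g <- gen[, i]
    hom <- g != 2L
    if (!all(h1[hom] == g[hom]) || !all(h2[hom] == g[hom]))
      return(sprintf("C1 violated for individual %d", i))
    if (!all(h1[!hom] + h2[!hom] == 1L))
      return(sprintf("C2 violated for individual %d", i))
  }
  for (i in seq_len(k)) {
    if (!identical(hap[2L * i - 1L, ], ph$center) &&
        !identical(hap[2L * i, ], ph$center))
      return(sprintf("affected individual %d does not carry the center", i))
  }
  for (i in seq.int(k + 1L, n, length.out = n - k)) {
    if (identical(hap[2L * i - 1L, ], ph$center) ||
        identical(hap[2L * i, ], ph$center))
      return(sprintf("unaffected individual %d carries the center", i))
  }
  if (ph$dh != nrow(unique(hap))) return("reported dh is wrong")
  NA_character_
}

# Exact minimum number of distinct haplotypes over all feasible phasings.
#
# Enumerates every candidate shared (center) haplotype over the L sites; a
# candidate fixes each affected pair completely, and each unaffected
# individual then ranges over its unordered phasings that avoid the center.
# Returns list(feasible, min_dh, space) where space is the number of
# configurations examined; callers cap `space` and regenerate oversized
# instances (enumeration beyond the cap is pointless desk-scale).
brute_min_dh <- function(gen, k, max_space = 2^14) {
  S <- nrow(gen)
  n <- ncol(gen)
  pow <- 2L^(seq_len(S) - 1L)
  # bit-pack each individual: hom mask/values and het mask
  hom_mask <- integer(n); hom_val <- integer(n); het_mask <- integer(n)
  for (i in seq_len(n)) {
    g <- gen[, i]
    hom_mask[i] <- sum(pow[g != 2L])
    hom_val[i] <- sum(pow[g == 1L])
    het_mask[i] <- sum(pow[g == 2L])
  }
  # unordered phasings per unaffected individual: h1 ranges over subsets of
  # the het mask with the lowest het bit fixed to 0; h2 = h1 xor het mask
  un <- seq.int(k + 1L, n, length.out = n - k)
  un_h1 <- lapply(un, function(i) {
    het <- which(bitwAnd(het_mask[i], pow) > 0L)
    if (!length(het)) return(hom_val[i])
    rest <- pow[het[-1L]]
    subs <- 0L
    for (b in rest) subs <- c(subs, subs + b)
    hom_val[i] + subs
  })
  best <- Inf
  feasible <- FALSE
  space <- 0L
  for (h in 0:(2L^S - 1L)) {
    # center must explain every affected genotype
    if (!all(bitwAnd(h, hom_mask[seq_len(k)]) == hom_val[seq_len(k)])) next
    aff_haps <- c(rbind(rep(h, k), bitwXor(h, het_mask[seq_len(k)])))
    opts <- lapply(seq_along(un), function(j) {
      h1 <- un_h1[[j]]
      h2 <- bitwXor(h1, het_mask[un[j]])
      cbind(h1, h2)[h1 != h & h2 != h, , drop = FALSE]
    })
    if (any(vapply(opts, nrow, integer(1L)) == 0L)) next
    feasible <- TRUE
    idx <- as.matrix(expand.grid(lapply(opts, function(o) seq_len(nrow(o)))))
    space <- space + max(1L, nrow(idx))
    if (space > max_space) return(list(feasible = NA, min_dh = NA,
                                       space = space))
    if (!length(un)) {
      best <- min(best, length(unique(aff_haps)))
    } else {
      for (r in seq_len(nrow(idx))) {
        haps <- c(aff_haps, unlist(lapply(seq_along(opts), function(j)
          opts[[j]][idx[r, j], ])))
        best <- min(best, length(unique(haps)))
      }
    }
  }
  list(feasible = feasible, min_dh = best, space = space)
}

# Exhaustive shared-region oracle for small truth sets: an interval [a,b]
# qualifies when some choice of one haplotype per affected individual agrees
# across all of them on [a,b] while every unaffected haplotype mismatches the
# shared sequence somewhere in [a,b]; shared regions are the qualifying
# intervals maximal under containment. Returns NULL when the carrier-choice
# interval around the mutation site never qualifies (the error case).
oracle_regions <- function(haps_aff, haps_un, carrier_choice, mut) {
  k <- length(haps_aff)
  S <- ncol(haps_aff[[1L]])
  normal <- if (length(haps_un)) do.call(rbind, haps_un) else
    matrix(integer(0), 0L, S)
  combos <- as.matrix(expand.grid(rep(list(1:2), k)))
  qualifies <- function(a, b, choice) {
    seqs <- do.call(rbind, lapply(seq_len(k), function(i)
      haps_aff[[i]][choice[i], a:b]))
    if (k > 1L && !all(seqs[-1L, , drop = FALSE] ==
                       rep(seqs[1L, ], each = k - 1L))) return(FALSE)
    if (nrow(normal)) {
      for (hh in seq_len(nrow(normal)))
        if (all(normal[hh, a:b] == seqs[1L, ])) return(FALSE)
    }
    TRUE
  }
  qual <- list()
  for (a in seq_len(S)) for (b in a:S) {
    if (any(apply(combos, 1L, function(ch) qualifies(a, b, ch))))
      qual[[length(qual) + 1L]] <- c(a, b)
  }
  if (!length(qual)) return(NULL)
  qm <- unique(do.call(rbind, qual))
  keep <- vapply(seq_len(nrow(qm)), function(i)
    !any(qm[, 1L] <= qm[i, 1L] & qm[, 2L] >= qm[i, 2L] &
           (qm[, 1L] < qm[i, 1L] | qm[, 2L] > qm[i, 2L])), logical(1L))
  shared <- qm[keep, , drop = FALSE]
  shared <- shared[order(shared[, 1L]), , drop = FALSE]
  # carrier interval: maximal qualifying interval under the carrier choice
  # that contains the mutation site
  cand <- NULL
  for (a in seq_len(mut)) for (b in mut:S) {
    if (qualifies(a, b, carrier_choice) &&
        (is.null(cand) || b - a > cand[2L] - cand[1L])) cand <- c(a, b)
  }
  if (is.null(cand)) return(NULL)
  sup <- shared[shared[, 1L] <= cand[1L] & shared[, 2L] >= cand[2L], ,
                drop = FALSE]
  true_region <- if (nrow(sup)) sup[which.max(sup[, 2L] - sup[, 1L]), ]
                 else cand
  list(true_region = as.integer(true_region),
       shared = data.frame(start = as.integer(shared[, 1L]),
                           end = as.integer(shared[, 2L])))
}

# Small random truth-like object for exercising true_and_shared_regions
# directly (no pedigree semantics needed: the function only reads haplotypes,
# status, carrier_strand and mutation_site).
rand_truth <- function(S, k, n_un, p_copy = 0.7) {
  ids <- as.character(seq_len(k + n_un))
  status <- stats::setNames(rep(c("affected", "unaffected"), c(k, n_un)), ids)
  carrier_strand <- stats::setNames(sample(1:2, k, replace = TRUE), ids[seq_len(k)])
  template <- sample(0:1, S, replace = TRUE)
  mut <- sample.int(S, 1L)
  haps <- lapply(seq_len(k + n_un), function(i) {
    h <- matrix(sample(0:1, 2L * S, replace = TRUE), nrow = 2L)
    # make sharing plausible: affected carrier strands copy a template over
    # an interval containing the mutation site, with random flanking noise
    if (i <= k) {
      a <- sample.int(mut, 1L)
      b <- sample(mut:S, 1L)
      h[carrier_strand[[i]], a:b] <- template[a:b]
    } else if (stats::runif(1) < p_copy) {
      a <- sample.int(S, 1L)
      b <- sample(a:S, 1L)
      h[sample(1:2, 1L), a:b] <- template[a:b]
    }
    h
  })
  names(haps) <- ids
  structure(list(haplotypes = haps, mutation_site = mut,
                 carrier_strand = carrier_strand, out_ids = ids,
                 status = status, genotypes = NULL,
                 true_region = NULL, shared_regions = NULL),
            class = "truth_set")
}
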