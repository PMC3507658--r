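# Region-level precision/recall of reported regions against simulated truth.
# All metrics count SNP sites. The primed variants replace the single true
# mutation region with the union of all shared mutation regions; since the
# true region is one of the shared regions, the primed precision can only be
# larger.

interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
}

# merge possibly-overlapping intervals (matrix/df with start, end) into a
# disjoint union
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    j <- nrow(out)
    if (iv$start[i] <= out$end[j] + 1L) {
      out$end[j] <- max(out$end[j], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Evaluate reported regions against the true mutation region
#'
#' `precision` is the number of SNPs of the reported regions lying inside the
#' true mutation region divided by the total number of reported SNPs;
#' `recall` divides the same numerator by the size of the true region.
#' `precision_shared`/`recall_shared` use the union of all shared mutation
#' regions in place of the true region.
#'
#' @param reported data frame of reported regions (columns `start`, `end`,
#'   sorted by descending score as produced by [detect_regions()]); must be
#'   pairwise disjoint
#' @param true_region integer `c(start, end)`
#' @param shared_regions data frame with columns `start`, `end`
#' @param top_k evaluate only the best `top_k` reported regions (ties broken
#'   by leftmost start; `Inf` = all)
#' @return list of class `eval_result` with `precision`, `recall`,
#'   `precision_shared`, `recall_shared`, `k_used`, `n_reported`,
#'   `empty_report` (TRUE when nothing was reported; metrics are then 0)
#' @export
evaluate_regions <- function(reported, true_region, shared_regions,
                             top_k = Inf) {
  stopifnot(length(true_region) == 2L, true_region[1L] <= true_region[2L])
  k_used <- min(top_k, nrow(reported))
  rep_k <- utils::head(reported, k_used)
  if (!nrow(rep_k)) {
    return(structure(list(precision = 0, recall = 0, precision_shared = 0,
                          recall_shared = 0, k_used = 0L, n_reported = 0L,
                          empty_report = TRUE),
                     class = "eval_result"))
  }
  if (nrow(rep_k) > 1L) {
    o <- rep_k[order(rep_k$start), , drop = FALSE]
    if (any(o$start[-1L] <= o$end[-nrow(o)]))
      stop("reported regions must be pairwise disjoint")
  }
  total_rep <- sum(region_length(rep_k$start, rep_k$end))
  cd <- sum(interval_overlap(rep_k$start, rep_k$end,
                             true_region[1L], true_region[2L]))
  shared_u <- merge_intervals(shared_regions[, c("start", "end")])
  cd_sh <- sum(vapply(seq_len(nrow(shared_u)), function(i)
    sum(interval_overlap(rep_k$start, rep_k$end,
                         shared_u$start[i], shared_u$end[i])), integer(1L)))
  structure(list(
    precision = cd / total_rep,
    recall = cd / region_length(true_region[1L], true_region[2L]),
    precision_shared = cd_sh / total_rep,
    recall_shared = cd_sh / sum(region_length(shared_u$start, shared_u$end)),
    k_used = as.integer(k_used), n_reported = nrow(rep_k),
    empty_report = FALSE), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result (top %d): precision %.2f%%, recall %.2f%%, precision' %.2f%%, recall' %.2f%%\n",
    x$k_used, 100 * x$precision, 100 * x$recall,
    100 * x$precision_shared, 100 * x$recall_shared))
  invisible(x)
}

#' Simulate, detect and evaluate over many replicates
#'
#' Runs `simulate -> detect -> evaluate` `n_reps` times with per-replicate
#' seeds derived deterministically from `seed`, and reports per-replicate
#' metrics plus means. Replicates whose simulation or detection fails are
#' recorded and excluded; a replicate that reports no region scores 0 in the
#' inclusive means and is dropped from the exclusive means.
#'
#' @param ped a [pedigree()]
#' @param n_reps number of replicates
#' @param sites number of SNP sites per replicate
#' @param seed master seed
#' @param L window length for detection
#' @param cfg a [sim_config()]
#' @param cm_per_site genetic-map density (see [uniform_genetic_map()])
#' @param top_k vector of report sizes to evaluate (default 1 and 3)
#' @return list of class `batch_eval`: `per_rep` (data frame: one row per
#'   replicate and top-k, with metrics, mutation-site hit flag and seed),
#'   `summary` (means per top-k, inclusive and exclusive of empty reports),
#'   `n_failed`
#' @export
batch_evaluate <- function(ped, n_reps, sites, seed, L = 500L,
                           cfg = sim_config(), cm_per_site = 0.001,
                           top_k = c(1L, 3L)) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  map <- uniform_genetic_map(sites, cm_per_site)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    res <- tryCatch({
      truth <- drop_pedigree(ped, map, cfg)
      det <- detect_regions(truth$genotypes, L)
      lapply(top_k, function(k) {
        ev <- evaluate_regions(det, truth$true_region, truth$shared_regions,
                               top_k = k)
        top <- utils::head(det, k)
        hit <- nrow(top) > 0L &&
          any(top$start <= truth$mutation_site &
                top$end >= truth$mutation_site)
        data.frame(rep = r, seed = rep_seeds[r], top_k = k,
                   precision = ev$precision, recall = ev$recall,
                   precision_shared = ev$precision_shared,
                   recall_shared = ev$recall_shared,
                   empty_report = ev$empty_report,
                   mutation_site_hit = hit)
      })
    }, error = function(e) {
      message(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      rows <- c(rows, res)
    }
  }
  per_rep <- do.call(rbind, rows)
  metr <- c("precision", "recall", "precision_shared", "recall_shared")
  summ <- do.call(rbind, lapply(sort(unique(per_rep$top_k)), function(k) {
    d <- per_rep[per_rep$top_k == k, , drop = FALSE]
    dn <- d[!d$empty_report, , drop = FALSE]
    data.frame(top_k = k,
               n = nrow(d),
               hit_rate = mean(d$mutation_site_hit),
               t(colMeans(d[metr])),
               t(stats::setNames(colMeans(dn[metr]),
                                 paste0(metr, "_nonempty"))))
  }))
  structure(list(per_rep = per_rep, summary = summ, n_failed = n_failed),
            class = "batch_eval")
}

#' @export
print.batch_eval <- function(x, ...) {
  cat(sprintf("batch_eval: %d replicate rows, %d failed\n",
              nrow(x$per_rep), x$n_failed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  top-%d: hit %.0f%% | precision %.2f%% recall %.2f%% precision' %.2f%% recall' %.2f%%\n",
      s$top_k[i], 100 * s$hit_rate[i], 100 * s$precision[i], 100 * s$recall[i],
      100 * s$precision_shared[i], 100 * s$recall_shared[i]))
  }
  invisible(x)
}
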