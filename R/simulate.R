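# Gene-dropping pedigree simulator with ground truth.
#
# Founder haplotypes are mosaics over a small ancestral pool (giving local
# LD); haplotypes descend through the pedigree with recombination under the
# chi-square interference model; transmissions from a mutation-carrier parent
# are conditioned so that affected children inherit the carrier strand and
# unaffected children do not. All randomness uses R's global RNG: call
# set.seed() before simulating for reproducibility.

#' Construct and validate a pedigree
#'
#' @param id individual identifiers (coerced to character)
#' @param father,mother parent ids; `"0"` marks a founder (both must be 0
#'   together)
#' @param sex `"M"`/`"F"` per individual
#' @param status `"affected"`/`"unaffected"` (or `"D"`/`"U"`)
#' @param in_output logical: does this individual's genotype enter the
#'   detection input?
#' @return data frame of class `pedigree`, topologically ordered (parents
#'   before children)
#' @details Validity under single-origin dominant transmission: exactly one
#'   founder is affected (the mutation carrier), every affected non-founder
#'   has exactly one affected parent, and the output set contains at least one
#'   affected and one unaffected individual.
#' @export
pedigree <- function(id, father, mother, sex, status, in_output) {
  status <- ifelse(status %in% c("D", "affected"), "affected",
            ifelse(status %in% c("U", "unaffected"), "unaffected", NA))
  if (anyNA(status)) stop("status must be D/U or affected/unaffected")
  ped <- data.frame(id = as.character(id), father = as.character(father),
                    mother = as.character(mother), sex = as.character(sex),
                    status = status, in_output = as.logical(in_output))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  founder <- ped$father == "0" & ped$mother == "0"
  if (any((ped$father == "0") != (ped$mother == "0")))
    stop("founders must have both parents set to 0")
  if (!all(ped$father[!founder] %in% ped$id) ||
      !all(ped$mother[!founder] %in% ped$id))
    stop("unknown parent id")
  # topological order by repeated sweeps (also detects cycles)
  placed <- character(0)
  order_idx <- integer(0)
  remaining <- seq_len(nrow(ped))
  while (length(remaining)) {
    ready <- remaining[
      (ped$father[remaining] == "0" | ped$father[remaining] %in% placed) &
      (ped$mother[remaining] == "0" | ped$mother[remaining] %in% placed)]
    if (!length(ready)) stop("pedigree contains a cycle")
    order_idx <- c(order_idx, ready)
    placed <- c(placed, ped$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ped <- ped[order_idx, , drop = FALSE]
  rownames(ped) <- NULL
  aff_founders <- sum(founder[order_idx] & ped$status == "affected")
  if (aff_founders != 1L)
    stop("exactly one founder must be affected (the mutation carrier)")
  for (r in which(ped$status == "affected" & ped$father != "0")) {
    pa <- ped$status[match(c(ped$father[r], ped$mother[r]), ped$id)]
    if (sum(pa == "affected") != 1L)
      stop(sprintf(
        "affected individual %s must have exactly one affected parent",
        ped$id[r]))
  }
  outs <- ped$status[ped$in_output]
  if (!any(outs == "affected") || !any(outs == "unaffected"))
    stop("output set needs at least one affected and one unaffected individual")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read / write a pedigree TSV
#'
#' Columns: `id`, `father`, `mother`, `sex`, `status` (D/U), `in_output`
#' (0/1). Founders have father and mother `0`.
#'
#' @param path file path
#' @return [pedigree()] for the reader; invisibly `path` for the writer
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("id", "father", "mother", "sex", "status", "in_output")
  if (!all(need %in% names(df)))
    stop("pedigree file needs columns: ", paste(need, collapse = ", "))
  pedigree(df$id, df$father, df$mother, df$sex, df$status,
           df$in_output %in% c("1", "TRUE"))
}

#' @rdname read_pedigree
#' @param ped a [pedigree()]
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$status <- ifelse(df$status == "affected", "D", "U")
  df$in_output <- as.integer(df$in_output)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Five-generation example pedigree
#'
#' A single founder couple whose mutation carrier's descendants run in an
#' affected chain down two branches; the bottom generation holds two sibships
#' of `n_children` each, of which `n_affected` in total are affected. Only the
#' bottom-generation children enter the output set, mirroring the study
#' design where genotypes are available for the latest generation only.
#'
#' @param n_affected total affected children in the bottom generation (1..
#'   `2 * n_children`; default 2, i.e. 2 affected out of 10)
#' @param n_children children per bottom sibship (default 5)
#' @return a [pedigree()]
#' @export
example_pedigree <- function(n_affected = 2L, n_children = 5L) {
  stopifnot(n_affected >= 1L, n_affected <= 2L * n_children)
  a1 <- ceiling(n_affected / 2)
  a2 <- n_affected - a1
  rows <- list(
    # G1 founders: 1 is the carrier
    c("1", "0", "0", "M", "D"), c("2", "0", "0", "F", "U"),
    # G2: two affected children + married-in founders
    c("3", "1", "2", "M", "D"), c("4", "0", "0", "F", "U"),
    c("5", "1", "2", "F", "D"), c("6", "0", "0", "M", "U"),
    # G3
    c("7", "3", "4", "M", "D"), c("8", "0", "0", "F", "U"),
    c("9", "6", "5", "F", "D"), c("10", "0", "0", "M", "U"),
    # G4
    c("11", "7", "8", "M", "D"), c("12", "0", "0", "F", "U"),
    c("13", "10", "9", "F", "D"), c("14", "0", "0", "M", "U")
  )
  kid <- 20L
  for (fam in 1:2) {
    f <- if (fam == 1L) c("11", "12") else c("14", "13")
    n_aff <- if (fam == 1L) a1 else a2
    for (j in seq_len(n_children)) {
      kid <- kid + 1L
      rows[[length(rows) + 1L]] <-
        c(as.character(kid), f[1L], f[2L],
          if (j %% 2L) "M" else "F",
          if (j <= n_aff) "D" else "U")
    }
  }
  m <- do.call(rbind, rows)
  pedigree(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L],
           in_output = as.integer(m[, 1L]) > 20L)
}

#' Simulation configuration
#'
#' @param m chi-square interference parameter (degrees of freedom divided by
#'   two); `m = 0` gives the interference-free Haldane model. Default 4.
#' @param pool_size number of ancestral haplotypes in the founder pool
#' @param switch_rate per-site probability that a founder mosaic switches to
#'   another pool haplotype (default 0.002: about one switch per 500 sites)
#' @param freq_range range of per-site allele-1 frequencies for the pool
#' @param mutation_site `"uniform"` (drawn uniformly over sites) or a fixed
#'   1-based SNP ordinal
#' @return list of class `sim_config`
#' @export
sim_config <- function(m = 4L, pool_size = 10L, switch_rate = 0.002,
                       freq_range = c(0.05, 0.95),
                       mutation_site = "uniform") {
  stopifnot(m >= 0L, pool_size >= 1L, switch_rate >= 0, switch_rate <= 1)
  structure(list(m = as.integer(m), pool_size = as.integer(pool_size),
                 switch_rate = switch_rate, freq_range = freq_range,
                 mutation_site = mutation_site),
            class = "sim_config")
}

#' Uniform genetic map
#'
#' @param S number of SNP sites
#' @param cm_per_site genetic distance between adjacent sites (default 0.001
#'   cM, i.e. 1 cM per 1,000 sites)
#' @return numeric vector of nondecreasing positions in centimorgans
#' @export
uniform_genetic_map <- function(S, cm_per_site = 0.001) {
  (seq_len(S) - 1L) * cm_per_site
}

#' Read a genetic map TSV (columns `snp_id`, `cM`)
#' @param path file path
#' @return numeric vector of cM positions
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("snp_id", "cM") %in% names(df)))
    stop("genetic map file needs columns snp_id, cM")
  pos <- as.numeric(df$cM)
  if (is.unsorted(pos)) stop("map positions must be nondecreasing")
  pos
}

#' Generate founder haplotypes with local LD
#'
#' Each haplotype is a mosaic over a pool of `pool_size` ancestral haplotypes
#' whose per-site allele frequencies are drawn from `freq_range`; mosaic
#' switch points occur independently per site at `switch_rate`, so nearby
#' sites tend to descend from the same pool haplotype (HapMap-like local LD).
#'
#' @param n_haps number of haplotypes to generate
#' @param S number of sites
#' @param cfg a [sim_config()]
#' @return `n_haps` x `S` integer 0/1 matrix
#' @export
generate_founders <- function(n_haps, S, cfg = sim_config()) {
  freq <- stats::runif(S, cfg$freq_range[1L], cfg$freq_range[2L])
  pool <- matrix(stats::rbinom(cfg$pool_size * S, 1L, rep(freq, each = cfg$pool_size)),
                 nrow = cfg$pool_size)
  out <- matrix(0L, n_haps, S)
  for (h in seq_len(n_haps)) {
    switches <- c(TRUE, stats::runif(S - 1L) < cfg$switch_rate)
    seg <- cumsum(switches)
    choice <- sample.int(cfg$pool_size, max(seg), replace = TRUE)
    out[h, ] <- pool[cbind(choice[seg], seq_len(S))]
  }
  out
}

#' Simulate crossover positions under the chi-square interference model
#'
#' Chiasmata on the four-strand bundle form a stationary renewal process in
#' which every `(m+1)`-th event of a Poisson process of rate `2(m+1)` per
#' Morgan is a chiasma (uniformly random initial phase gives stationarity);
#' each chiasma lands on the sampled gamete independently with probability
#' 1/2. The retained crossover rate is 1 per Morgan for every `m`; `m = 0`
#' recovers the interference-free Poisson (Haldane) model.
#'
#' @param map genetic map (cM positions, nondecreasing)
#' @param m interference parameter
#' @return sorted numeric vector of crossover positions in cM
#' @export
simulate_crossovers <- function(map, m = 4L) {
  T_mor <- (max(map) - min(map)) / 100
  if (T_mor <= 0) stop("total map length must be positive")
  n_ev <- stats::rpois(1L, 2 * (m + 1L) * T_mor)
  if (n_ev == 0L) return(numeric(0))
  ev <- sort(stats::runif(n_ev, 0, T_mor))
  phase <- sample.int(m + 1L, 1L) - 1L
  first <- phase + 1L
  if (first > n_ev) return(numeric(0))
  chi <- ev[seq.int(first, n_ev, by = m + 1L)]
  chi <- chi[stats::runif(length(chi)) < 0.5]
  min(map) + chi * 100
}

#' Build a gamete from a parent's two haplotypes
#'
#' Copies alternate parental strands, switching after each crossover.
#'
#' @param hap1,hap2 the parent's haplotypes (0/1 integer vectors)
#' @param crossovers crossover positions in cM
#' @param map genetic map (cM per site)
#' @param start_strand 1 or 2: strand copied before the first crossover
#' @return integer haplotype vector
#' @export
make_gamete <- function(hap1, hap2, crossovers, map, start_strand) {
  stopifnot(start_strand %in% c(1L, 2L), length(hap1) == length(map),
            length(hap2) == length(map))
  strand <- (start_strand - 1L + findInterval(map, sort(crossovers))) %% 2L
  ifelse(strand == 0L, hap1, hap2)
}

#' Gene-drop haplotypes through a pedigree
#'
#' Founders receive generated haplotypes (the carrier founder's first
#' haplotype carries the mutation); every transmission simulates crossovers
#' and copies alternating strands. For a transmission from a carrier parent
#' the starting strand is chosen so that the allele at the mutation site
#' descends from the carrier strand exactly when the child is affected — the
#' crossover pattern itself is untouched, only the strand labelling flips, so
#' the recombination law is preserved everywhere else and exactly one true
#' mutation region exists by construction.
#'
#' @param ped a [pedigree()]
#' @param map genetic map (cM per site); length gives the site count
#' @param cfg a [sim_config()]
#' @param founder_haps optional pre-generated founder haplotype matrix
#'   (`2 * n_founders` x S, rows paired per founder in pedigree order);
#'   generated with [generate_founders()] when `NULL`
#' @return list of class `truth_set`:
#'   * `haplotypes`: named list, per individual a 2 x S integer matrix;
#'   * `mutation_site`: 1-based SNP ordinal;
#'   * `carrier_strand`: named integer (1 or 2) per affected individual;
#'   * `genotypes`: [genotype_matrix()] of the output-set individuals;
#'   * `true_region`, `shared_regions`: filled by [true_and_shared_regions()].
#' @export
drop_pedigree <- function(ped, map, cfg = sim_config(), founder_haps = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  S <- length(map)
  if (S < 2L) stop("need at least two sites")
  founders <- ped$id[ped$father == "0"]
  if (is.null(founder_haps)) {
    founder_haps <- generate_founders(2L * length(founders), S, cfg)
  }
  stopifnot(nrow(founder_haps) == 2L * length(founders),
            ncol(founder_haps) == S)
  mut <- if (identical(cfg$mutation_site, "uniform"))
    sample.int(S, 1L) else as.integer(cfg$mutation_site)
  stopifnot(mut >= 1L, mut <= S)

  haps <- list()
  carrier_strand <- integer(0)
  for (f in seq_along(founders)) {
    haps[[founders[f]]] <- founder_haps[c(2L * f - 1L, 2L * f), , drop = FALSE]
  }
  carrier_id <- ped$id[ped$father == "0" & ped$status == "affected"]
  carrier_strand[carrier_id] <- 1L

  transmit <- function(parent_id, child_affected) {
    cx <- simulate_crossovers(map, cfg$m)
    if (parent_id %in% names(carrier_strand)) {
      cs <- carrier_strand[[parent_id]]
      parity <- sum(cx < map[mut]) %% 2
      want <- if (child_affected) cs else 3L - cs
      start <- if (parity == 0) want else 3L - want
    } else {
      start <- sample.int(2L, 1L)
    }
    ph <- haps[[parent_id]]
    make_gamete(ph[1L, ], ph[2L, ], cx, map, start)
  }

  for (r in which(ped$father != "0")) {
    id <- ped$id[r]
    affected <- ped$status[r] == "affected"
    pat <- transmit(ped$father[r], affected)
    mat <- transmit(ped$mother[r], affected)
    haps[[id]] <- rbind(pat, mat)
    if (affected) {
      from_father <- ped$status[match(ped$father[r], ped$id)] == "affected"
      carrier_strand[id] <- if (from_father) 1L else 2L
    }
  }

  out_ids <- ped$id[ped$in_output]
  codes <- vapply(out_ids, function(id) {
    h <- haps[[id]]
    ifelse(h[1L, ] == h[2L, ], h[1L, ], 2L)
  }, integer(S))
  rownames(codes) <- paste0("snp", seq_len(S))
  gm <- genotype_matrix(codes, ped$status[match(out_ids, ped$id)])

  truth <- structure(
    list(haplotypes = haps, mutation_site = mut,
         carrier_strand = carrier_strand,
         out_ids = out_ids,
         status = stats::setNames(ped$status[match(out_ids, ped$id)], out_ids),
         genotypes = gm, true_region = NULL, shared_regions = NULL),
    class = "truth_set")
  reg <- true_and_shared_regions(truth)
  truth$true_region <- reg$true_region
  truth$shared_regions <- reg$shared_regions
  truth
}

#' Shared and true mutation regions of a simulated truth set
#'
#' A shared mutation region is a maximal interval on which some choice of one
#' haplotype per affected output individual is identical across all of them
#' while no unaffected output individual's haplotype matches that sequence
#' over the whole interval. The true mutation region is the shared region
#' containing the mutation site (reached through the actual carrier strands).
#'
#' @param truth a `truth_set` from [drop_pedigree()] (the region fields may
#'   still be `NULL`)
#' @return list with `true_region` (integer `c(start, end)`) and
#'   `shared_regions` (data frame with columns `start`, `end`)
#' @export
true_and_shared_regions <- function(truth) {
  aff <- names(truth$status)[truth$status == "affected"]
  una <- names(truth$status)[truth$status == "unaffected"]
  k <- length(aff)
  S <- ncol(truth$haplotypes[[aff[1L]]])
  normal_haps <- do.call(rbind, lapply(una, function(id) truth$haplotypes[[id]]))

  combo_runs <- function(choice) {
    chosen <- do.call(rbind, lapply(seq_len(k), function(i)
      truth$haplotypes[[aff[i]]][choice[i], ]))
    agree <- rep(TRUE, S)
    if (k > 1L) {
      for (i in 2:k) agree <- agree & (chosen[i, ] == chosen[1L, ])
    }
    r <- rle(agree)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    if (!nrow(runs)) return(NULL)
    # keep runs over which every unaffected haplotype mismatches somewhere
    if (length(una)) {
      keep <- rep(TRUE, nrow(runs))
      for (h in seq_len(nrow(normal_haps))) {
        cs <- c(0L, cumsum(normal_haps[h, ] != chosen[1L, ]))
        hit <- cs[runs[, 2L] + 1L] - cs[runs[, 1L]]
        keep <- keep & (hit > 0L)
      }
      runs <- runs[keep, , drop = FALSE]
    }
    runs
  }

  combos <- as.matrix(expand.grid(rep(list(1:2), k)))
  all_runs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(ci)
    combo_runs(combos[ci, ])))
  if (is.null(all_runs) || !nrow(all_runs))
    stop("no shared mutation region exists")
  all_runs <- unique(all_runs)
  # maximal under containment
  contained <- vapply(seq_len(nrow(all_runs)), function(i) {
    any(all_runs[, 1L] <= all_runs[i, 1L] & all_runs[, 2L] >= all_runs[i, 2L] &
          (all_runs[, 1L] < all_runs[i, 1L] | all_runs[, 2L] > all_runs[i, 2L]))
  }, logical(1L))
  shared <- all_runs[!contained, , drop = FALSE]
  shared <- shared[order(shared[, 1L]), , drop = FALSE]

  carrier_choice <- truth$carrier_strand[aff]
  cr <- combo_runs(carrier_choice)
  mut <- truth$mutation_site
  in_run <- !is.null(cr) && nrow(cr) &&
    any(cr[, 1L] <= mut & cr[, 2L] >= mut)
  if (!in_run)
    stop("mutation site not inside any shared region (carrier haplotype matched by an unaffected individual)")
  run <- cr[cr[, 1L] <= mut & cr[, 2L] >= mut, , drop = FALSE][1L, ]
  sup <- shared[shared[, 1L] <= run[1L] & shared[, 2L] >= run[2L], ,
                drop = FALSE]
  true_region <- if (nrow(sup)) {
    sup[which.max(sup[, 2L] - sup[, 1L]), ]
  } else run
  list(true_region = as.integer(true_region),
       shared_regions = data.frame(start = as.integer(shared[, 1L]),
                                   end = as.integer(shared[, 2L])))
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "truth_set: %d individuals in output, mutation site %d, true region [%d,%d], %d shared region(s)\n",
    length(x$out_ids), x$mutation_site,
    x$true_region[1L], x$true_region[2L], nrow(x$shared_regions)))
  invisible(x)
}
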