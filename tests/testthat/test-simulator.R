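test_that("pedigree validation enforces single-origin dominant structure", {
  expect_s3_class(example_pedigree(), "pedigree")
  # two affected founders
  expect_error(pedigree(c("1", "2", "3"), c("0", "0", "1"),
                        c("0", "0", "2"), c("M", "F", "M"),
                        c("D", "D", "D"), c(FALSE, FALSE, TRUE)),
               "exactly one founder")
  # affected child of two unaffected parents
  expect_error(pedigree(c("1", "2", "3", "4"), c("0", "0", "0", "2"),
                        c("0", "0", "0", "3"), c("D", "M", "F", "M"),
                        c("D", "U", "U", "D"), c(FALSE, FALSE, FALSE, TRUE)),
               "affected parent")
  # cycle
  expect_error(pedigree(c("1", "2"), c("2", "1"), c("2", "1"),
                        c("M", "F"), c("D", "U"), c(TRUE, TRUE)),
               "cycle")
})

test_that("pedigree TSV round-trips", {
  ped <- example_pedigree()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, p)
  expect_equal(read_pedigree(p), ped)
})

test_that("founder mosaics carry local LD from a small ancestral pool", {
  set.seed(8)
  cfg <- sim_config(pool_size = 4L, switch_rate = 0.01)
  fh <- generate_founders(200L, 1200L, cfg)
  expect_true(all(fh %in% 0:1))
  # between-haplotype allele correlation decays with distance: adjacent sites
  # descend from the same pool haplotype far more often than distant ones
  ld <- function(d) mean(vapply(seq_len(ncol(fh) - d), function(j) {
    a <- fh[, j]; b <- fh[, j + d]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    abs(stats::cor(a, b))
  }, numeric(1L)), na.rm = TRUE)
  expect_gt(ld(1L), ld(500L) + 0.2)
})

test_that("crossover count is calibrated to the map length in Morgans", {
  set.seed(21)
  map <- uniform_genetic_map(1000, 0.25)  # 250 cM = 2.5 Morgans
  for (m in c(0L, 4L)) {
    n <- vapply(seq_len(4000), function(i)
      length(simulate_crossovers(map, m)), integer(1L))
    se <- stats::sd(n) / sqrt(length(n))
    expect_lt(abs(mean(n) - 2.5), 3 * se + 1e-9)
    expect_true(all(vapply(seq_len(50), function(i) {
      cx <- simulate_crossovers(map, m)
      !is.unsorted(cx) && all(cx >= 0) && all(cx <= 250)
    }, logical(1L))))
  }
})

test_that("interference reduces the variance of inter-crossover distances", {
  set.seed(22)
  map <- uniform_genetic_map(100, 1)  # ~1 Morgan
  gaps <- function(m) unlist(lapply(seq_len(8000), function(i)
    diff(simulate_crossovers(map, m)))) / 100
  expect_lt(stats::var(gaps(4L)), stats::var(gaps(0L)))
})

test_that("gametes copy alternating parental strands", {
  map <- uniform_genetic_map(10, 1)
  h1 <- rep(0L, 10)
  h2 <- rep(1L, 10)
  g <- make_gamete(h1, h2, c(2.5, 6.5), map, start_strand = 1L)
  expect_equal(g, c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(make_gamete(h1, h2, numeric(0), map, 2L), h2)
})

test_that("gene dropping produces a consistent truth set", {
  ped <- example_pedigree(n_affected = 3L)
  map <- uniform_genetic_map(3000)
  for (seed in c(4, 17, 123)) {
    set.seed(seed)
    truth <- drop_pedigree(ped, map)
    gm <- truth$genotypes
    # genotypes encode the haplotype pairs
    for (id in truth$out_ids) {
      h <- truth$haplotypes[[id]]
      expect_equal(unname(gm$codes[, id]),
                   ifelse(h[1L, ] == h[2L, ], h[1L, ], 2L))
    }
    # every affected output individual carries the founder's mutation allele
    # descent: at the mutation site the carrier strand is identical by
    # descent, hence identical in state, across all affected individuals
    aff <- names(truth$status)[truth$status == "affected"]
    carrier_alleles <- vapply(aff, function(id)
      truth$haplotypes[[id]][truth$carrier_strand[[id]], truth$mutation_site],
      integer(1L))
    expect_equal(length(unique(carrier_alleles)), 1L)
    # the true region contains the mutation site and is a shared region
    expect_true(truth$true_region[1L] <= truth$mutation_site)
    expect_true(truth$true_region[2L] >= truth$mutation_site)
    sh <- truth$shared_regions
    expect_true(any(sh$start == truth$true_region[1L] &
                      sh$end == truth$true_region[2L]))
    # shared regions are pairwise non-nested
    if (nrow(sh) > 1L) {
      for (i in seq_len(nrow(sh))) {
        expect_false(any(sh$start <= sh$start[i] & sh$end >= sh$end[i] &
                           (sh$start < sh$start[i] | sh$end > sh$end[i])))
      }
    }
  }
})

test_that("simulation is reproducible from the seed", {
  ped <- example_pedigree()
  map <- uniform_genetic_map(1000)
  set.seed(77)
  t1 <- drop_pedigree(ped, map)
  set.seed(77)
  t2 <- drop_pedigree(ped, map)
  expect_equal(t1$genotypes$codes, t2$genotypes$codes)
  expect_equal(t1$mutation_site, t2$mutation_site)
  expect_equal(t1$true_region, t2$true_region)
})

test_that("shared regions match the exhaustive interval oracle", {
  set.seed(303)
  n_checked <- 0L
  for (rep in seq_len(120)) {
    S <- sample(8:16, 1L)
    k <- sample(2:3, 1L)
    n_un <- sample(1:2, 1L)
    truth <- rand_truth(S, k, n_un)
    aff <- names(truth$status)[truth$status == "affected"]
    una <- names(truth$status)[truth$status == "unaffected"]
    orc <- oracle_regions(truth$haplotypes[aff], truth$haplotypes[una],
                          truth$carrier_strand[aff], truth$mutation_site)
    if (is.null(orc)) {
      expect_error(true_and_shared_regions(truth), "shared")
    } else {
      got <- true_and_shared_regions(truth)
      expect_equal(got$true_region, orc$true_region)
      expect_equal(got$shared_regions, orc$shared)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 20L)
})
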