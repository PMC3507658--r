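make_grid <- function(status, L = 10L) {
  n <- length(status)
  structure(list(grid = data.frame(start = seq(1L, by = L, length.out = n),
                                   end = seq(L, by = L, length.out = n),
                                   status = status),
                 L = L),
            class = "window_grid")
}

test_that("the chromosome is tiled into consecutive inclusive windows", {
  set.seed(5)
  ped <- example_pedigree()
  truth <- drop_pedigree(ped, uniform_genetic_map(1234))
  grid <- scan_windows(truth$genotypes, 100L)
  g <- grid$grid
  expect_equal(g$start, seq(1L, 1234L, by = 100L))
  expect_equal(g$end, c(seq(100L, 1200L, by = 100L), 1234L))
  expect_true(all(g$status %in%
    c("valid", "case_conflict", "control_shares_center")))
})

test_that("valid windows merge across center-sharing gaps only", {
  v <- "valid"; t1 <- "case_conflict"; t2 <- "control_shares_center"
  # gap of unavoidable-sharing windows within 2L merges
  expect_equal(merge_valid(make_grid(c(v, t2, t2, v))),
               data.frame(start = 1L, end = 40L))
  # an affected-conflict window in the gap blocks the merge
  expect_equal(merge_valid(make_grid(c(v, t2, t1, v))),
               data.frame(start = c(1L, 31L), end = c(10L, 40L)))
  # a gap longer than 2L sites blocks the merge even if all windows share
  expect_equal(merge_valid(make_grid(c(v, t2, t2, t2, v))),
               data.frame(start = c(1L, 41L), end = c(10L, 50L)))
  # merging chains left to right across several valid windows
  expect_equal(merge_valid(make_grid(c(v, t2, v, t2, v))),
               data.frame(start = 1L, end = 50L))
  expect_equal(merge_valid(make_grid(c(t1, t2, t1))),
               data.frame(start = integer(0), end = integer(0)))
})

ext_fixture <- function() {
  codes <- cbind(
    A1 = as_genotype_seg("222102222"),
    A2 = as_genotype_seg("222122222"),
    U  = as_genotype_seg("222210222"))
  genotype_matrix(codes, c(A1 = "affected", A2 = "affected",
                           U = "unaffected"))
}

test_that("all-heterozygous positions are annexed without limit", {
  gm <- ext_fixture()
  sp <- phase_span(gm, 4L, 6L)
  expect_equal(sp$phase$status, "valid")
  expect_equal(extend_region(4L, 6L, expand_haplotypes(sp), gm,
                             cols = sp$cols),
               c(1L, 9L))
})

test_that("extension stops at the first conflicting position on each side", {
  gm <- ext_fixture()
  gm$codes[3L, ] <- c(0L, 1L, 2L)  # affected disagree homozygously
  gm$codes[8L, ] <- c(1L, 0L, 2L)
  sp <- phase_span(gm, 4L, 6L)
  expect_equal(sp$phase$status, "valid")
  expect_equal(extend_region(4L, 6L, expand_haplotypes(sp), gm,
                             cols = sp$cols),
               c(4L, 7L))
})

test_that("refinement keeps the longest widening that still phases valid", {
  set.seed(31)
  ped <- example_pedigree()
  truth <- drop_pedigree(ped, uniform_genetic_map(2000))
  grid <- scan_windows(truth$genotypes, 200L)
  spans <- merge_valid(grid)
  for (r in seq_len(nrow(spans))) {
    ref <- refine_boundaries(spans$start[r], spans$end[r], truth$genotypes,
                             200L)
    expect_false(is.null(ref))  # the unwidened span itself phases valid
    expect_true(ref$b <= spans$start[r] && ref$e >= spans$end[r])
    expect_equal(ref$phase$phase$status, "valid")
    # bounds come from one of the three candidate widenings
    expect_true(ref$b %in% pmax(1L, spans$start[r] - c(100L, 40L, 0L)))
    expect_true(ref$e %in% pmin(2000L, spans$end[r] + c(100L, 40L, 0L)))
  }
})

test_that("the region score is (2n - DH) times the inclusive length", {
  expect_equal(score_region(6L, 8L, 11L, 20L), (12L - 8L) * 10L)
  expect_equal(score_region(3L, 6L, 5L, 5L), 0L)
  expect_error(score_region(3L, 7L, 1L, 2L), "2n")
  expect_error(score_region(3L, 0L, 1L, 2L))
})

test_that("detected regions are disjoint, scored and sorted", {
  set.seed(99)
  ped <- example_pedigree()
  truth <- drop_pedigree(ped, uniform_genetic_map(8000))
  det <- detect_regions(truth$genotypes, 400L)
  expect_true(nrow(det) >= 1L)
  expect_equal(det$length, det$end - det$start + 1L)
  expect_equal(det$score,
               score_region(n_individuals(truth$genotypes), det$dh,
                            det$start, det$end))
  expect_true(all(diff(det$score) <= 0))
  o <- det[order(det$start), ]
  if (nrow(o) > 1L) expect_true(all(o$start[-1L] > o$end[-nrow(o)]))
  # deterministic re-run
  expect_equal(detect_regions(truth$genotypes, 400L), det)
})

test_that("original-frame reporting needs a filtered matrix", {
  set.seed(13)
  ped <- example_pedigree()
  truth <- drop_pedigree(ped, uniform_genetic_map(1500))
  expect_error(detect_regions(truth$genotypes, 300L, report = "original"),
               "original index")
  gmiss <- truth$genotypes
  gmiss$codes[c(10L, 700L), 1L] <- NA
  f <- drop_missing_sites(gmiss)
  det <- detect_regions(f, 300L, report = "original")
  orig <- attr(f, "original_index")
  expect_true(all(det$start %in% orig & det$end %in% orig))
})
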