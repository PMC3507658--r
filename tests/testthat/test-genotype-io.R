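test_that("genotype_matrix validates codes, status and snp index", {
  codes <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), nrow = 3,
                  dimnames = list(NULL, c("a", "b")))
  gm <- genotype_matrix(codes, c(a = "affected", b = "unaffected"))
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(n_sites(gm), 3L)
  expect_equal(n_individuals(gm), 2L)

  expect_error(genotype_matrix(matrix(3L, 2, 2),
                               c("affected", "unaffected")), "code")
  expect_error(genotype_matrix(codes, c(a = "affected", b = "affected")),
               "unaffected")
  expect_error(genotype_matrix(codes, c(a = "unaffected", b = "unaffected")),
               "affected")
  expect_error(genotype_matrix(codes, c(a = "affected", b = "unaffected"),
                               snp_index = c(5L, 4L, 6L)),
               "increasing")
})

test_that("drop_missing_sites removes exactly the sites with missing calls", {
  codes <- matrix(c(0L, NA, 2L, 1L,
                    2L, 1L, NA, 0L), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  gm <- genotype_matrix(codes, c(a = "affected", b = "unaffected"),
                        allow_missing = TRUE)
  f <- drop_missing_sites(gm)
  expect_equal(n_sites(f), 2L)
  expect_false(anyNA(f$codes))
  expect_equal(attr(f, "original_index"), c(1L, 4L))

  all_na <- genotype_matrix(matrix(NA_integer_, 2, 2,
                                   dimnames = list(NULL, c("a", "b"))),
                            c(a = "affected", b = "unaffected"),
                            allow_missing = TRUE)
  expect_error(drop_missing_sites(all_na), "no usable sites")
})

test_that("genotype TSV round-trips byte-identically", {
  set.seed(11)
  codes <- matrix(sample(c(0:2, NA), 40, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), nrow = 10,
                  dimnames = list(NULL, c("i1", "i2", "i3", "i4")))
  gm <- genotype_matrix(codes, c(i1 = "affected", i2 = "affected",
                                 i3 = "unaffected", i4 = "unaffected"),
                        allow_missing = TRUE)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, p1)
  back <- read_genotype_tsv(p1)
  expect_equal(unname(back$codes), unname(gm$codes))
  expect_equal(back$status, gm$status)
  write_genotype_tsv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("genotype TSV reader reports offending line numbers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#STATUS\tD\tU", "snp_id\ta\tb", "s1\t0\t2", "s2\t0\t7"), p)
  expect_error(read_genotype_tsv(p), "line 4")
  writeLines(c("#STATUS\tD\tU", "snp_id\ta\tb", "s1\t0\t2", "s1\t1\t1"), p)
  expect_error(read_genotype_tsv(p), "duplicate")
})

test_that("VCF reader maps GT fields to 0/1/2/NA codes", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1/0",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t./.\t0/0",
    "1\t400\trs4\tT\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0"), p)
  expect_message(
    gm <- read_vcf_genotypes(p, c(s1 = "affected", s2 = "unaffected")),
    "multi-allelic")
  expect_equal(n_sites(gm), 3L)
  expect_equal(unname(gm$codes[, 1L]), c(0L, 2L, NA))
  expect_equal(unname(gm$codes[, 2L]), c(1L, 2L, 0L))
  expect_error(read_vcf_genotypes(p, c(nope = "affected", s2 = "unaffected")),
               "nope")
})

test_that("regions TSV round-trips", {
  det <- data.frame(start = c(10L, 50L), end = c(20L, 90L),
                    length = c(11L, 41L), dh = c(4L, 6L),
                    score = c(88L, 246L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_regions(det, p)
  expect_equal(read_regions(p), det)
})
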