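reg <- function(start, end) data.frame(start = start, end = end)

test_that("precision and recall count SNP overlap with the true region", {
  sh <- reg(101L, 200L)
  # exact hit
  ev <- evaluate_regions(reg(101L, 200L), c(101L, 200L), sh)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # disjoint report
  ev <- evaluate_regions(reg(300L, 400L), c(101L, 200L), sh)
  expect_equal(ev$precision, 0)
  expect_equal(ev$recall, 0)
  # contained truth
  ev <- evaluate_regions(reg(1L, 300L), c(101L, 200L), sh)
  expect_equal(ev$precision, 100 / 300)
  expect_equal(ev$recall, 1)
})

test_that("primed metrics use the union of shared regions", {
  true_r <- c(101L, 200L)
  sh <- reg(c(101L, 250L), c(200L, 349L))
  ev <- evaluate_regions(reg(c(101L, 250L), c(200L, 299L)), true_r, sh)
  expect_equal(ev$precision, 100 / 150)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision_shared, 1)
  expect_equal(ev$recall_shared, 150 / 200)
  # overlapping shared regions are merged before counting
  sh2 <- reg(c(101L, 150L), c(200L, 260L))
  ev2 <- evaluate_regions(reg(101L, 260L), true_r, sh2)
  expect_equal(ev2$precision_shared, 1)
  expect_equal(ev2$recall_shared, 1)
})

test_that("since the true region is shared, primed precision dominates", {
  set.seed(40)
  for (rep in seq_len(50)) {
    S <- 1000L
    a <- sort(sample.int(S, 2L))
    sh <- reg(a[1L], a[2L])
    extra <- sort(sample.int(S, 2L))
    sh <- rbind(sh, reg(extra[1L], extra[2L]))
    rp <- sort(sample.int(S, 4L))
    rep_df <- reg(c(rp[1L], rp[3L]), c(rp[2L] - 1L, rp[4L] - 1L))
    rep_df <- rep_df[rep_df$start <= rep_df$end, , drop = FALSE]
    if (!nrow(rep_df)) next
    if (nrow(rep_df) == 2L && rep_df$start[2L] <= rep_df$end[1L]) next
    ev <- evaluate_regions(rep_df, c(a[1L], a[2L]), sh)
    expect_gte(ev$precision_shared, ev$precision)
  }
})

test_that("top-k selection keeps the best-scored regions", {
  det <- data.frame(start = c(500L, 100L, 900L), end = c(599L, 150L, 999L))
  ev1 <- evaluate_regions(det, c(500L, 599L), reg(500L, 599L), top_k = 1L)
  expect_equal(ev1$recall, 1)
  ev_all <- evaluate_regions(det, c(500L, 599L), reg(500L, 599L))
  expect_equal(ev_all$recall, 1)
  expect_lt(ev_all$precision, ev1$precision)
  expect_equal(ev_all$k_used, 3L)
})

test_that("an empty report yields zero metrics with a flag", {
  ev <- evaluate_regions(reg(integer(0), integer(0)), c(1L, 10L),
                         reg(1L, 10L))
  expect_true(ev$empty_report)
  expect_equal(ev$precision, 0)
  expect_equal(ev$recall, 0)
})

test_that("overlapping reported regions are rejected", {
  expect_error(evaluate_regions(reg(c(1L, 50L), c(60L, 80L)), c(1L, 10L),
                                reg(1L, 10L)),
               "disjoint")
})

test_that("batch evaluation is deterministic and internally consistent", {
  ped <- example_pedigree()
  b1 <- batch_evaluate(ped, n_reps = 3L, sites = 1200L, seed = 5L, L = 300L)
  b2 <- batch_evaluate(ped, n_reps = 3L, sites = 1200L, seed = 5L, L = 300L)
  expect_equal(b1$per_rep, b2$per_rep)
  expect_equal(b1$summary, b2$summary)
  pr <- b1$per_rep
  expect_true(all(pr$recall[pr$top_k == 3L] >= pr$recall[pr$top_k == 1L]))
  expect_true(all(pr$precision_shared >= pr$precision - 1e-12))
  expect_true(all(vapply(pr[c("precision", "recall", "precision_shared",
                              "recall_shared")], function(x)
    all(x >= 0 & x <= 1), logical(1L))))
})
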