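test_that("binning is left-closed right-open with open-ended edge bins", {
  fd <- binResponses(c(27, 29, 30), rep("beta", 3), binWidth = 4,
                     rangeLo = 0, rangeHi = 52)
  get <- function(lo) fd$count[fd$bin_lo == lo & fd$label == "beta"]
  expect_equal(get(24), 1L)
  expect_equal(get(28), 2L)
  expect_equal(sum(fd$count), 3L)

  # a value on a bin edge belongs to the right-hand bin
  fd2 <- binResponses(28, "beta", 4, 0, 52)
  expect_equal(fd2$count[fd2$bin_lo == 28], 1L)

  # below-range values land in the low open-ended bin; totals conserved
  fd3 <- binResponses(c(-5, 10, 60), rep("alpha", 3), 4, 0, 52)
  expect_equal(fd3$count[is.infinite(fd3$bin_lo)], 1L)
  expect_equal(fd3$count[is.infinite(fd3$bin_hi)], 1L)
  expect_equal(sum(fd3$count), 3L)

  empty <- binResponses(numeric(0), character(0), 4, 0, 52)
  expect_equal(sum(empty$count), 0L)
  expect_error(binResponses(1, "a", 0, 0, 52), "binWidth")
  expect_error(binResponses(1, "a", 4, 52, 0), "rangeLo")
})

test_that("bin counts always sum to the per-label classified n", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(1:300, 1)
    x <- rnorm(n, sample(c(-10, 5, 27), 1), runif(1, 0.1, 30))
    lab <- sample(c("beta", "alpha"), n, replace = TRUE)
    fd <- binResponses(x, lab, 4, 0, 52)
    for (lb in unique(lab))
      expect_equal(sum(fd$count[fd$label == lb]), sum(lab == lb))
  }
})

test_that("per-type summaries use the sample-sd SEM", {
  s <- summarizeByType(rep(27, 5), rep("beta", 5))
  expect_equal(s$mean[s$label == "beta"], 27)
  expect_equal(s$sem[s$label == "beta"], 0)

  s2 <- summarizeByType(c(26, 27, 28), rep("beta", 3))
  expect_equal(s2$mean, 27)
  expect_equal(s2$sem, 1 / sqrt(3))

  # absent labels are absent, not zero
  s3 <- summarizeByType(c(1, 2), c("beta", "beta"))
  expect_false("alpha" %in% s3$label)
})

test_that("sampled beta means land within the sampling-distribution bound", {
  set.seed(123)
  x <- rnorm(183, 27, 12.2)
  s <- summarizeByType(x, rep("beta", 183))
  expect_lt(abs(s$mean - 27), 3 * 12.2 / sqrt(183))
})

test_that("FP and FN counting follows the stain-versus-response definitions", {
  mkResp <- function(stat, ids) data.frame(cell_id = ids, statistic = stat,
                                           qc = "ok")
  ids <- sprintf("c%03d", 1:215)
  lab <- c(rep("beta", 183), rep("alpha", 32))
  idt <- data.frame(cell_id = ids, label = lab)

  clean <- mkResp(c(rep(27, 183), rep(-5, 32)), ids)
  rep0 <- classifyFpFn(clean, idt, threshold = 4)
  expect_equal(fpRate(rep0), 0)
  expect_equal(fnRate(rep0), 0)

  oneFp <- mkResp(c(rep(27, 183), 10, rep(-5, 31)), ids)
  expect_equal(fpRate(classifyFpFn(oneFp, idt, 4)), 1 / 32)

  oneFn <- mkResp(c(2, rep(27, 182), rep(-5, 32)), ids)
  expect_equal(fnRate(classifyFpFn(oneFn, idt, 4)), 1 / 183)
})

test_that("raising the threshold never lowers FN or raises FP", {
  set.seed(7)
  ids <- sprintf("c%03d", 1:120)
  resp <- data.frame(cell_id = ids,
                     statistic = rnorm(120, 10, 15), qc = "ok")
  idt <- data.frame(cell_id = ids,
                    label = sample(c("beta", "alpha"), 120, replace = TRUE))
  prev <- classifyFpFn(resp, idt, threshold = -20)
  for (thr in seq(-15, 35, by = 5)) {
    cur <- classifyFpFn(resp, idt, threshold = thr)
    expect_lte(fpCount(cur), fpCount(prev))
    expect_gte(fnCount(cur), fnCount(prev))
    prev <- cur
  }
})

test_that("excluded labels are tallied, not silently dropped", {
  ids <- sprintf("c%d", 1:10)
  resp <- data.frame(cell_id = ids, statistic = rep(27, 10),
                     qc = c(rep("ok", 9), "failed_calibration"))
  idt <- data.frame(cell_id = ids,
                    label = c(rep("beta", 6), "alpha", "unclassified",
                              "ambiguous", "beta"))
  rep <- classifyFpFn(resp, idt, 4)
  ex <- excludedCounts(rep)
  expect_equal(unname(ex["unclassified"]), 1L)
  expect_equal(unname(ex["ambiguous"]), 1L)
  expect_equal(unname(ex["failed_calibration"]), 1L)
  expect_equal(typeSummary(rep)$n[typeSummary(rep)$label == "beta"], 6L)
})

test_that("exclusion percentage matches the printed-count arithmetic", {
  idt <- data.frame(cell_id = seq_len(224),
                    label = c(rep("beta", 183), rep("alpha", 29),
                              rep("unclassified", 12)))
  expect_equal(exclusionSummary(idt), 5)
  expect_equal(exclusionSummary(idt, digits = NULL), 100 * 12 / 224)
  expect_equal(exclusionSummary(data.frame(cell_id = 1:4,
                                           label = c("beta", "beta", "beta",
                                                     "unclassified"))), 25)
  idt0 <- data.frame(cell_id = 1:3, label = rep("beta", 3))
  expect_equal(exclusionSummary(idt0), 0)
  expect_error(exclusionSummary(idt0[0, ]), "empty")
})
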