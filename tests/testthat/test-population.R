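layoutDefault <- makeGridLayout()

test_that("exact-quota sampling reproduces the per-type counts", {
  spec <- populationSpec()
  cells <- samplePopulation(spec, layoutDefault, seed = 11)
  counts <- table(cells$type)
  expect_equal(unname(counts["beta"]), 183L, ignore_attr = TRUE)
  expect_equal(unname(counts["alpha"]), 32L, ignore_attr = TRUE)
  expect_equal(unname(counts["other"]), 12L, ignore_attr = TRUE)
  expect_equal(nrow(cells), 227L)
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- populationSpec(nCells = 100L, composition = c(beta = 1.0),
                         responseMean = c(beta = 27),
                         responseSd = c(beta = 12.2))
  a <- samplePopulation(spec, layoutDefault, seed = 5)
  b <- samplePopulation(spec, layoutDefault, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("invalid composition is rejected", {
  expect_error(populationSpec(composition = c(beta = 0.5, alpha = 0.2)),
               "sum to 1")
})

test_that("per-type response means obey the law of large numbers", {
  spec <- populationSpec(nCells = 10000L, nRegions = 500L,
                         minSpacingUm = 15, edgeMarginUm = 5)
  cells <- samplePopulation(spec, layoutDefault, seed = 42)
  for (ty in c("beta", "alpha", "other")) {
    x <- cells$response_param[cells$type == ty]
    tol <- 3 * spec@responseSd[[ty]] / sqrt(length(x))
    expect_lt(abs(mean(x) - spec@responseMean[[ty]]), tol)
  }
})

test_that("multinomial sampling matches the composition in expectation", {
  spec <- populationSpec(nCells = 227L, samplingMode = "multinomial",
                         nRegions = 10L)
  set.seed(99)
  pooled <- c(beta = 0, alpha = 0, other = 0)
  for (i in 1:200) {
    cells <- samplePopulation(spec, layoutDefault)
    tab <- table(cells$type)
    pooled[names(tab)] <- pooled[names(tab)] + tab
  }
  p <- stats::chisq.test(pooled[c("beta", "alpha", "other")],
                         p = spec@composition[c("beta", "alpha", "other")])$p.value
  expect_gt(p, 0.01)
})

test_that("cells respect the grid square, spacing and calibration invariants", {
  spec <- populationSpec()
  cells <- samplePopulation(spec, layoutDefault, seed = 3)
  expect_equal(locateSquare(layoutDefault, cells$x_um, cells$y_um),
               cells$square_id)
  expect_true(all(cells$plateau_kcn > cells$plateau_fccp))
  expect_true(all(cells$plateau_fccp > 0))
  for (sq in unique(cells$square_id)) {
    xy <- cbind(cells$x_um, cells$y_um)[cells$square_id == sq, , drop = FALSE]
    if (nrow(xy) > 1L)
      expect_gte(min(stats::dist(xy)), spec@minSpacingUm)
  }
})
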