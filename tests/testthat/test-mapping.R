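test_that("a known rigid shift between sessions is recovered", {
  set.seed(31)
  live <- cbind(runif(8, 10, 140), runif(8, 10, 140))
  stained <- sweep(live, 2, -c(5, -3))  # live + (5, -3)
  off <- estimateSquareOffset(live, stained)
  expect_equal(off, c(5, -3), tolerance = 1)

  expect_equal(estimateSquareOffset(live, live), c(0, 0))
  expect_equal(estimateSquareOffset(matrix(c(10, 20), 1),
                                    matrix(c(14, 17), 1)), c(4, -3))
  # empty side falls back to a zero offset
  expect_equal(estimateSquareOffset(live, live[0, , drop = FALSE]), c(0, 0))
})

test_that("zero jitter matches every cell to its own stain record", {
  layout <- makeGridLayout()
  spec <- populationSpec(jitterSdUm = 0)
  cells <- samplePopulation(spec, layout, seed = 41)
  stains <- simulateStaining(cells, spec, layout = layout, seed = 42)
  mt <- matchCells(cells, stains)
  expect_equal(stains$cell_id[match(mt$stain_id, stains$stain_id)],
               mt$cell_id)
  expect_equal(mt$distance_um, rep(0, nrow(cells)), tolerance = 1e-9)
})

test_that("a missing stain record leaves that cell unmatched, others intact", {
  layout <- makeGridLayout(150, 1, 1)
  cells <- makeCells(n = 3L, x = c(30, 75, 120), y = c(40, 90, 50))
  stains <- data.frame(stain_id = c("s1", "s3"),
                       x_um = cells$x_um[c(1, 3)], y_um = cells$y_um[c(1, 3)],
                       square_id = "1-1", insulin = c(900, 10),
                       glucagon = c(10, 900))
  id <- identityTable(cells, stains)
  expect_equal(id$label, c("beta", "unmatched", "alpha"))
  expect_true(is.na(id$stain_id[2]))
})

test_that("stain intensities map to identity labels", {
  expect_equal(assignIdentity(900, 10), "beta")
  expect_equal(assignIdentity(10, 900), "alpha")
  expect_equal(assignIdentity(10, 10), "unclassified")
  expect_equal(assignIdentity(900, 900), "ambiguous")
  expect_equal(assignIdentity(NA, NA), "unmatched")
  expect_equal(assignIdentity(c(900, 10), c(10, 10)),
               c("beta", "unclassified"))
  expect_error(assignIdentity(1, 1, insulinThreshold = 0), "> 0")
})

test_that("matching is one-to-one and equivariant under constant translation", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    live <- cbind(runif(n, 10, 140), runif(n, 10, 140))
    m <- sample(2:10, 1)
    stained <- cbind(runif(m, 10, 140), runif(m, 10, 140))
    cells <- makeCells(n, x = live[, 1], y = live[, 2])
    stains <- data.frame(stain_id = sprintf("s%d", seq_len(m)),
                         x_um = stained[, 1], y_um = stained[, 2],
                         square_id = "1-1", insulin = 900, glucagon = 10)
    mt <- matchCells(cells, stains, toleranceUm = 30)
    matched <- mt$stain_id[!is.na(mt$stain_id)]
    expect_equal(anyDuplicated(matched), 0L)
    expect_true(all(mt$distance_um[!is.na(mt$distance_um)] <= 30))

    shifted <- transform(stains, x_um = x_um + 10, y_um = y_um - 5)
    mt2 <- matchCells(cells, shifted, toleranceUm = 30)
    expect_equal(mt2$stain_id, mt$stain_id)
  }
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  set.seed(77)
  agree <- 0L; trials <- 200L
  for (i in seq_len(trials)) {
    n <- sample(2:10, 1)
    pts <- .placeSpread(n)
    jit <- pts + matrix(rnorm(2 * n, 0, 2), n, 2)
    cells <- makeCells(n, x = pts[, 1], y = pts[, 2])
    stains <- data.frame(stain_id = sprintf("s%d", seq_len(n)),
                         x_um = jit[, 1], y_um = jit[, 2],
                         square_id = "1-1", insulin = 900, glucagon = 10)
    mt <- matchCells(cells, stains, toleranceUm = 10)
    if (any(is.na(mt$stain_id))) next
    off <- c(mt$offset_x_um[1], mt$offset_y_um[1])
    cost <- sqrt(outer(pts[, 1] + off[1], jit[, 1], "-")^2 +
                 outer(pts[, 2] + off[2], jit[, 2], "-")^2)
    optCost <- optimalAssignmentCost(cost)
    greedyCost <- sum(mt$distance_um)
    if (abs(greedyCost - optCost) < 1e-9) agree <- agree + 1L
  }
  expect_gte(agree / trials, 0.99)
})
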