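test_that("steady state is the closed-interval window mean", {
  expect_equal(steadyState(c(80, 80, 80), c(35, 37, 39), c(35, 45)), 80)
  expect_equal(steadyState(c(10, 20, 30), c(36, 40, 44), c(35, 45)), 20)
  # boundary samples are included (closed interval)
  expect_equal(steadyState(c(1, 2, 9), c(35, 45, 50), c(35, 45)), 1.5)
  expect_error(steadyState(c(1, 2), c(10, 20), c(35, 45)), "no samples")
  expect_error(steadyState(1, 1, c(45, 35)), "start < end")
})

test_that("KCN and FCCP plateaus normalize to 100% and 0%", {
  # raw trace: flat 275 RFU, KCN plateau 500, FCCP plateau 50
  ts <- piecewiseTrace(list(c(0, 115, 275), c(115, 135, 500),
                            c(135, 155, 50)), channel = "nadph")
  norm <- normalizeTraces(ts)
  v <- traceSignal(norm)[1, ]
  tm <- traceTimes(norm)
  expect_equal(unname(v[tm >= 127 & tm <= 134]), rep(100, 4))
  expect_equal(unname(v[tm >= 147 & tm <= 154]), rep(0, 4))
  # intermediate value: midpoint of the anchors
  expect_equal(unname(v[tm < 115]), rep(50, sum(tm < 115)))
  expect_true(all(rowData(norm)$calibration_ok))
})

test_that("degenerate calibration flags the cell instead of scoring it", {
  ts <- piecewiseTrace(list(c(0, 115, 275), c(115, 135, 50),
                            c(135, 155, 500)), channel = "nadph")
  norm <- normalizeTraces(ts)
  expect_false(rowData(norm)$calibration_ok[1])
  expect_true(all(is.na(traceSignal(norm)[1, ])))
  resp <- responseMinChange(norm)
  expect_equal(resp$qc, "failed_calibration")
  expect_true(is.na(resp$statistic))
})

test_that("minimum change takes the smaller of the two glucose transitions", {
  # beta-composite-like: steady states 40 / 67 / 40 -> statistic 27
  ts <- piecewiseTrace(list(c(0, 15, 40), c(15, 65, 67), c(65, 155, 40)))
  r <- responseMinChange(ts)
  expect_equal(r$delta_up, 27)
  expect_equal(r$delta_down, 27)
  expect_equal(r$statistic, 27)

  # upward drift with zero response: up-step positive, statistic negative
  ts2 <- piecewiseTrace(list(c(0, 15, 40), c(15, 65, 45), c(65, 155, 50)))
  r2 <- responseMinChange(ts2)
  expect_equal(r2$delta_up, 5)
  expect_equal(r2$statistic, -5)

  # alpha-like small wobble
  ts3 <- piecewiseTrace(list(c(0, 15, 40), c(15, 65, 38), c(65, 155, 41)))
  expect_equal(responseMinChange(ts3)$statistic, -3)
})

test_that("calcium response is the raw steady-state ratio change", {
  ts <- piecewiseTrace(list(c(0, 15, 1.00), c(15, 65, 1.33), c(65, 125, 1.08)),
                       endMin = 125, channel = "calcium_ratio")
  expect_equal(calciumResponse(ts)$statistic, 0.33)
  flat <- piecewiseTrace(list(c(0, 125, 1.2)), endMin = 125,
                         channel = "calcium_ratio")
  expect_equal(calciumResponse(flat)$statistic, 0)
  alpha <- piecewiseTrace(list(c(0, 15, 1.20), c(15, 65, 1.25),
                               c(65, 125, 1.21)),
                          endMin = 125, channel = "calcium_ratio")
  expect_equal(calciumResponse(alpha)$statistic, 0.05)
})

test_that("the normalized statistic is invariant to affine gain/offset", {
  cells <- makeCells(n = 6L, response = c(30, 5, -5, 12, 27, 0),
                     noise = 5, drift = 0.05, tau = 3)
  ts <- simulateTraces(cells, seed = 77)
  base <- responseTable(ts)
  scaled <- TraceSet(3.7 * traceSignal(ts) + 120, traceTimes(ts),
                     channel = "nadph", cellData = rowData(ts))
  expect_equal(responseTable(scaled)$statistic, base$statistic,
               tolerance = 1e-9)
})

test_that("drift of either sign cannot push a null cell above zero", {
  for (drift in seq(-0.5, 0.5, by = 0.05)) {
    cells <- makeCells(response = 0, drift = drift)
    r <- responseTable(simulateTraces(cells))
    expect_lte(r$statistic, 1e-9)
    if (drift > 0.01) expect_gt(r$delta_up, 0)
  }
})

test_that("a larger true plateau strictly increases the statistic", {
  stats <- vapply(c(5, 10, 20, 27, 40), function(resp) {
    cells <- makeCells(response = resp, tau = 3)
    responseTable(simulateTraces(cells))$statistic
  }, 0)
  expect_true(all(diff(stats) > 0))
})
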