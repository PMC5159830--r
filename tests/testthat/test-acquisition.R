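test_that("scan schedule places each region at its cycle slot", {
  s <- buildScanSchedule("r1", acquisitionTimeS = 0.2, cyclePeriodS = 120,
                         nCycles = 3)
  expect_equal(s$time_s, c(0, 120, 240))

  s10 <- buildScanSchedule(sprintf("r%02d", 1:10), 0.2, 120, nCycles = 5)
  for (rid in unique(s10$region_id))
    expect_equal(diff(s10$time_s[s10$region_id == rid]), rep(120, 4))
  # regions within a cycle are offset by the acquisition slot
  expect_equal(s10$time_s[s10$cycle == 1], 0.2 * (0:9))
})

test_that("an overfull cycle is rejected with the required minimum period", {
  expect_error(buildScanSchedule(sprintf("r%03d", 1:601), 0.2, 120, 10),
               "minimum feasible cycle period is 120.2")
})

test_that("throughput arithmetic follows regions/s x 60 x cells/region", {
  expect_equal(maxThroughput(3, 20), 3600)
  expect_equal(maxThroughput(1, 1), 60)
  expect_equal(maxThroughput(3, 40), 7200)
  expect_error(maxThroughput(0, 10), "> 0")
})

test_that("ROI means reproduce frame intensities", {
  roi <- data.frame(cell_id = "c1", x_px = 10, y_px = 10, radius_px = 4)
  frames <- list(matrix(100, 20, 20), matrix(100, 20, 20))
  ts <- extractRoiTraces(frames, roi, c(0, 2))
  expect_equal(unname(traceSignal(ts)[1, ]), c(100, 100))

  frames2 <- list(matrix(10, 20, 20), matrix(20, 20, 20))
  ts2 <- extractRoiTraces(frames2, roi, c(0, 2))
  expect_equal(unname(traceSignal(ts2)[1, ]), c(10, 20))
})

test_that("bad ROIs and mismatched stacks are rejected", {
  roi <- data.frame(cell_id = "c1", x_px = 2, y_px = 10, radius_px = 4)
  expect_error(extractRoiTraces(list(matrix(0, 20, 20), matrix(0, 20, 20)),
                                roi, c(0, 2)), "outside the image")
  roiOk <- data.frame(cell_id = "c1", x_px = 10, y_px = 10, radius_px = 4)
  expect_error(extractRoiTraces(list(matrix(0, 20, 20)), roiOk, c(0, 2)),
               "does not match")
})

test_that("rendered regions round-trip through ROI extraction", {
  layout <- makeGridLayout(150, 2, 2)
  cells <- makeCells(n = 2L, x = c(40, 110), y = c(50, 100), square = "1-1")
  img <- renderRegionImage(cells, layout, "1-1", intensities = c(100, 180),
                           imageSizePx = 150L)
  rois <- regionRois(cells, layout, "1-1", imageSizePx = 150L)
  ts <- extractRoiTraces(list(img, img), rois, timestampsMin = c(0, 2))
  expect_equal(unname(traceSignal(ts)[, 1]), c(100, 180))
  # agreement with the brute-force pixel oracle
  for (i in 1:2)
    expect_equal(traceSignal(ts)[i, 1],
                 roiMeanBruteForce(img, rois$x_px[i], rois$y_px[i],
                                   rois$radius_px[i]))
})

test_that("empty and single-cell renders behave as specified", {
  layout <- makeGridLayout(150, 2, 2)
  empty <- renderRegionImage(makeCells(0L), layout, "1-1", imageSizePx = 64L)
  expect_true(all(empty == 0))
  one <- makeCells(1L, x = 75, y = 75, square = "1-1")
  img <- renderRegionImage(one, layout, "1-1", intensities = 100,
                           imageSizePx = 150L)
  roi <- regionRois(one, layout, "1-1", imageSizePx = 150L)
  ts <- extractRoiTraces(list(img, img), roi, c(0, 2))
  expect_equal(unname(traceSignal(ts)[1, 1]), 100)
  # a cell outside the named square is refused
  bad <- makeCells(1L, x = 200, y = 75, square = "1-2")
  expect_error(renderRegionImage(bad, layout, "1-1", imageSizePx = 64L),
               "square")
})

test_that("traces are invariant to joint image+mask translation and linear in gain", {
  layout <- makeGridLayout(150, 1, 1)
  cells <- makeCells(n = 2L, x = c(40, 100), y = c(60, 90), square = "1-1")
  img <- renderRegionImage(cells, layout, "1-1", intensities = c(50, 120),
                           imageSizePx = 150L)
  rois <- regionRois(cells, layout, "1-1", imageSizePx = 150L)
  base <- traceSignal(extractRoiTraces(list(img, img), rois, c(0, 2)))

  # translate by whole pixels: pad the image and shift the masks
  shift <- c(7, 4)  # x, y in px
  big <- matrix(0, 170, 170)
  big[shift[2] + seq_len(150), shift[1] + seq_len(150)] <- img
  roisT <- transform(rois, x_px = x_px + shift[1], y_px = y_px + shift[2])
  moved <- traceSignal(extractRoiTraces(list(big, big), roisT, c(0, 2)))
  expect_equal(unname(moved), unname(base))

  scaled <- traceSignal(extractRoiTraces(list(img * 3.5, img * 3.5), rois, c(0, 2)))
  expect_equal(unname(scaled), unname(base) * 3.5)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  img1 <- matrix(round(runif(400, 0, 65535)), 20, 20)
  img2 <- matrix(round(runif(400, 0, 65535)), 20, 20)
  f <- tempfile(fileext = ".tif")
  writeImageStack(list(img1, img2), f)
  back <- readImageStack(f)
  expect_length(back, 2L)
  expect_equal(round(back[[1]]), img1, ignore_attr = TRUE)
  expect_equal(round(back[[2]]), img2, ignore_attr = TRUE)
  unlink(f)
})
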