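# Hand-built fixtures used across test files.

# A cell table with fully controlled generator parameters (one grid square
# unless positions are supplied).
makeCells <- function(n = 1L, response = 27, baseline = 230, kcn = 500,
                      fccp = 50, drift = 0, noise = 0, tau = 0,
                      channel = "nadph", x = 75, y = 75, square = "1-1",
                      type = "beta") {
  S4Vectors::DataFrame(
    cell_id = sprintf("cell%04d", seq_len(n)),
    type = rep_len(type, n),
    x_um = rep_len(x, n), y_um = rep_len(y, n),
    square_id = rep_len(square, n),
    response_param = rep_len(response, n),
    baseline = rep_len(baseline, n),
    plateau_kcn = rep_len(kcn, n),
    plateau_fccp = rep_len(fccp, n),
    drift_slope = rep_len(drift, n),
    noise_sd = rep_len(noise, n),
    tau_min = rep_len(tau, n),
    channel = rep(channel, n))
}

# Piecewise-constant trace over the standard sampling grid: `levels` is a
# named list of c(start, end, value) triples (t in [start, end) takes value).
piecewiseTrace <- function(levels, endMin = 155, dt = 2,
                           channel = "nadph_pct", calibrationOk = TRUE) {
  times <- seq(0, endMin, by = dt)
  times <- times[times < endMin]
  v <- rep(NA_real_, length(times))
  for (lv in levels)
    v[times >= lv[1] & times < lv[2]] <- lv[3]
  stopifnot(!anyNA(v))
  cd <- S4Vectors::DataFrame(cell_id = "cellA")
  if (channel == "nadph_pct") cd$calibration_ok <- calibrationOk
  TraceSet(matrix(v, nrow = 1), times, channel = channel, cellData = cd)
}

# n well-spread points inside one 150-um square (dart throwing).
.placeSpread <- function(n, side = 150, margin = 10, minSpacing = 30) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  while (placed < n) {
    cand <- runif(2, margin, side - margin)
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2) >= minSpacing^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

# Independent pixel-level oracle for circular-ROI mean intensity:
# loops over every pixel and applies the centre-in rule directly.
roiMeanBruteForce <- function(img, xPx, yPx, radiusPx) {
  tot <- 0; k <- 0L
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((c - 0.5 - xPx)^2 + (r - 0.5 - yPx)^2 <= radiusPx^2) {
        tot <- tot + img[r, c]; k <- k + 1L
      }
    }
  }
  tot / k
}
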