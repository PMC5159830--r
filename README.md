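# gridPheno

Functional phenotyping of heterogeneous cell mixtures imaged live on a
gridded perifusion coverslip.

When a mixed population — e.g. dispersed pancreatic islets containing
insulin-secreting beta cells and glucagon-secreting alpha cells — is imaged
live under stepped-glucose perifusion and only afterwards immunostained for
identity, the two measurements live in different imaging sessions. A
photolithographed fiducial grid of uniquely labelled 150-µm squares on the
coverslip makes the mapping possible: the grid address of every cell
survives fixation, so each live-imaging ROI can be re-found in the stained
image and its functional response attributed to its immunochemical type,
without FACS purification. `gridPheno` implements the complete analysis
pipeline plus a seeded synthetic-data generator that emulates it end to end.

## The statistics at the core

**Per-cell calibration.** NAD(P)H autofluorescence is uncalibrated, so each
cell is normalized against its own extremes — the KCN plateau
(maximal NAD(P)H, defined as 100%) and the FCCP plateau (minimal, 0%):

    v  ↦  100 · (v − R_FCCP) / (R_KCN − R_FCCP)

**Drift-robust response.** With SS(w) the mean over a steady-state window
(35–45 min after each glucose transition; baseline from the initial
low-glucose segment), the response statistic is

    min( SS(high) − SS(base),  SS(high) − SS(post) )

the *minimum* change over the up- and down-transition. A monotone signal
drift inflates one term but deflates the other, so drift alone can never
create a false positive. Calcium (Fura ratio) responses are the plain
stimulated-minus-baseline ratio change.

**Classification report.** Per-type frequency distributions (4 %-unit bins
for NAD(P)H, 0.1-ratio bins for calcium, with open-ended edge bins),
per-type n/mean/SEM, and false-positive / false-negative rates at a
threshold (default 4%): a false positive is a glucagon-stained cell scoring
like a beta cell, a false negative an insulin-stained cell scoring like an
alpha cell.

## Worked example

Simulate the reference mixed population — 183 beta-like cells (response
distribution truncated to ≥ 8% of span) and 32 alpha-like cells (truncated
to ≤ 0%) in ten grid squares, with measurement noise, drift and
between-session centroid jitter — then run the full pipeline:

```r
library(gridPheno)

layout <- makeGridLayout()                      # 133 × 133 squares of 150 µm
spec <- populationSpec(nCells = 215L,
                       composition = c(beta = 183, alpha = 32) / 215,
                       responseLo = c(beta = 8, alpha = -Inf),
                       responseHi = c(beta = Inf, alpha = 0))
cfg <- defaultConfig()
cfg$n_cells <- 215L
cfg$composition <- list(beta = 183 / 215, alpha = 32 / 215)

set.seed(7)
cells  <- samplePopulation(spec, layout)        # ground truth + positions
ts     <- simulateTraces(cells)                 # RFU every 120 s, 0–155 min
stains <- simulateStaining(cells, spec, layout = layout)
res    <- analyzePopulation(cells, ts, stains, cfg)
res$report
```

```
ClassificationReport: 215 cells, threshold 4
  beta         n = 183  mean  27.886  SEM  0.835
  alpha        n =  32  mean  -9.490  SEM  1.333
  false positives: 0 (rate 0)   false negatives: 0 (rate 0)
  excluded: unclassified 0, ambiguous 0, unmatched 0, failed_calibration 0
```

Every cell was re-identified through its grid square, the recovered beta
mean (27.9 ± 0.8% of the KCN–FCCP span) matches the generator's 27%, the
alpha mean is negative as expected for glucose-insensitive cells, and with
the two response distributions on opposite sides of the 4% threshold the
pipeline commits zero false positives and zero false negatives.
`responseDistribution(res$report)` gives the binned frequency distribution
and `res$responses` the per-cell statistics with both transition components.

The same stages are scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/gridpheno.R simulate --out sim --seed 7
Rscript inst/cli/gridpheno.R analyze --traces sim/traces.csv \
    --stains sim/staining.csv --cells sim/cells.csv --out report
```

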