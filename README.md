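# follicleMech

Quantitative analysis of tissue mechanics and Myosin dynamics during
*Drosophila* border cell migration. During Stage 9 of oogenesis a cluster of
8–10 border cells migrates between the nurse cells of the follicle; the
mechanics of this substrate — and the activity and turnover of non-muscle
Myosin II on the cluster — determine whether migration is on time. This
package implements the measurement pipeline for that system, for anyone who
needs to turn AFM force curves, fixed confocal images, and time-lapse movies
of follicles into the cohort statistics such studies report:

- **AFM nanoindentation.** Approach force curves are converted to
  force–indentation data and fitted with the Sneddon cone (Hertzian) contact
  model, `F = (2/π)·tan(α)·E/(1−ν²)·δ²`, by zero-intercept least squares of
  `F` against `δ²` over two depth windows: 20–100 nm probes the basement
  membrane, 310–550 nm the underlying nurse cells. Defaults: spring constant
  0.12 N/m, half cone angle α = 20°, sample Poisson ratio ν = 0.5 (a
  reduced-modulus variant supports a finite tip modulus with ν_t = 0.25).
  A contact-point estimator (baseline threshold + local piecewise-quadratic
  refinement) and a parametric-bootstrap calibration of cohort means are
  included.
- **pMRLC quantification.** Line-profile peak ratios of phospho-MRLC to
  phalloidin across nurse-cell membranes (three lines per follicle,
  averaged, normalized batch-wise to the control mean), cluster/cytoplasm
  intensity ratios over a translated same-shape mask, and automated
  detection of Myosin puncta (median + k·MAD threshold, connected
  components, Feret-diameter lengths in µm).
- **Myosin dynamics.** Per-frame punctum detection, gapless greedy
  nearest-neighbour linking (a punctum's track ends the first frame it is
  absent), and lifetime statistics: lifetime = frames present × 30 s,
  censored tracks (still present in the final frame) excluded from means.
- **Migration index.** Border cell distance divided by the outer follicle
  cell front distance, both from the anterior pole; ≈1 is on-time, <1
  delayed, >1 accelerated. Plus cluster length (front − rear).
- **Statistics.** Welch/Student unpaired t-tests, one-way ANOVA with Tukey
  HSD, group summaries, and the figure-legend star convention.

Because the raw force curves and images behind such studies are typically
not deposited, the package ships a first-class synthetic-data module —
two-layer elastic indentation curves, two-channel follicle scenes, and
transient-puncta movies, each with exact ground truth — so every stage is
validated by parameter recovery.

## Worked example

```r
library(follicleMech)

## AFM: simulate a wild-type cohort (basement membrane 24.2 kPa over nurse
## cells at 10.1 kPa), then recover both moduli from the curves alone
coh <- simulateForceCurveCohort(50, twoLayerSample(eShallow = 24.2, eDeep = 10.1),
                                afmProbe(), acquisitionParams(), seed = 7)
res <- recoverStiffnessCohort(coh$curves, seed = 8)
cat(sprintf("basement membrane (20-100 nm): %.2f kPa\n", res$shallow))
cat(sprintf("nurse cells     (310-550 nm): %.2f kPa\n", res$deep))
#> basement membrane (20-100 nm): 25.00 kPa
#> nurse cells     (310-550 nm): 10.17 kPa

## Myosin dynamics: movies at the two mean lifetimes, tracked and compared
ctrl <- simulateTimelapse(timelapseParams(nFrames = 181, birthRate = 3,
                                          meanLifetime = 70.2, seed = 10))
null <- simulateTimelapse(timelapseParams(nFrames = 181, birthRate = 3,
                                          meanLifetime = 151.8, seed = 9))
lc <- trackPunctaLifetimes(ctrl$movie)
ln <- trackPunctaLifetimes(null$movie)
cat(sprintf("control:     %.1f s mean lifetime (%d uncensored tracks)\n",
            lc$mean_lifetime_s, lc$n_uncensored))
cat(sprintf("fascin-null: %.1f s mean lifetime (%d uncensored tracks)\n",
            ln$mean_lifetime_s, ln$n_uncensored))
unpairedTTest(lc$lifetimes_s, ln$lifetimes_s)
#> control:     69.8 s mean lifetime (509 uncensored tracks)
#> fascin-null: 139.2 s mean lifetime (547 uncensored tracks)
#> Welch t-test (unpaired, unequal variance): statistic = -11.37, df = 695.7, p = 1.303e-27 (****)

## Migration index
migrationIndex(list(border_cell_distance = 117, follicle_cell_distance = 150))
#> migration index 0.780 (delayed)
```

The recovered moduli land within a few percent of the set values (the
nurse-cell window is essentially exact; the shallow window carries a few
percent of seed noise, see the methods vignette), the two lifetime cohorts
are recovered near their generator means and separate decisively, and the
migration index is plain arithmetic on the distance records.

A command-line wrapper is installed at
`system.file("scripts", "folliclemech", package = "follicleMech")` with
subcommands `simulate-afm`, `fit-afm`, `simulate-image`, `quantify-pmrlc`,
`simulate-timelapse`, `track-puncta`, `migration-index`, and `compare`; every
stage writes tidy CSVs plus a `run_log.json` and is byte-reproducible under a
fixed seed.

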