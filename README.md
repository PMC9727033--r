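# irclusters

Single-molecule localization, spatial clustering and time-correlated
cluster-lifetime analysis for PALM imaging of membrane receptors, plus a
confocal puncta-quantification workflow — built for studies of dynamic
receptor clusters (e.g. the insulin receptor) at the plasma membrane, in
the cytoplasm and in the nucleus.

## What it does

Receptor clusters assemble and dissolve on timescales of seconds. The
tc-PALM measurement chain implemented here turns raw photoactivation
movies (2400 frames at 20 Hz, 256×256 px, 160 nm/px, EMCCD) into cluster
dynamics statistics:

1. **localize** — pixelwise GLR hypothesis test (threshold set by a
   per-pixel false-alarm probability), maximum-likelihood Gauss–Newton
   fitting of an integrated-Gaussian PSF model (Poisson likelihood,
   CRLB-based uncertainties), and a deflation loop that subtracts fitted
   spots and re-detects dimmer overlapping emitters.
2. **cluster** — DBSCAN on the localization map at length-scale 120 nm,
   N_min = 4 (self-inclusive counting, pinned deterministic tie-breaks),
   with subcellular region assignment (plasma membrane / cytoplasm /
   nucleus) from label masks.
3. **tc-PALM** — per-cluster burst extraction along the time axis
   (configurable dark-gap tolerance), burst lifetime = timespan from
   first to last detection, short/long classification at a strict 100 s
   cutoff, τ_avg ± SEM of short-lived bursts, long-lived fraction,
   detections per cluster, clusters per cell by region, unpaired t tests
   between conditions.
4. **puncta** — confocal puncta segmentation exactly as printed in the
   emulated protocol (median subtraction 10 px → Laplacian-of-Gaussian
   σ = 1 → threshold mean + 2·SD → 3×3 opening), c-in/c-out enrichment,
   secondary-channel quantification inside puncta,
   fusion/fission/deformation total-intensity conservation checks
   (Σ mean×area), region means, slice-to-whole-cell count extrapolation.
5. **simkit** — a synthetic-data generator with full ground truth:
   Poisson cluster births, two-population exponential lifetimes (short
   mean 6.8 s, 15% long-lived by default), molecular turnover with
   blinking tracks, EMCCD noise (gamma gain model), and planted puncta
   fields. Every pipeline stage is validated against it.

No raw imaging data from the motivating study is deposited, so the
simulator is the data source for all tests; validation is property-based
(brute-force DBSCAN oracle, numeric CRLB benchmarks, censoring-corrected
lifetime recovery, byte-identical determinism).

## Worked example

```r
library(irclusters)

gt    <- simulate_ground_truth(sim_config(), seed = 7)   # 67 planted clusters
locs  <- emit_localization_table(gt, sim_config(), seed = 7)
cl    <- dbscan_cluster(locs)                            # eps 120 nm, n_min 4
bp    <- burst_params(frame_rate = 20)                   # lifetimes need Hz
bursts <- extract_bursts_by_cluster(cl$locs, bp, n_frames = 2400L)
summarize_lifetimes(bursts, bp)
```

Output:

```
<lifetime_summary> 65 bursts; tau_avg(short) = 10.43 +/- 2.26 s; long-lived fraction = 0.031
```

65 of 67 planted clusters are recovered (3 of 54,505 localizations end as
DBSCAN noise). τ_avg here is *larger* than the configured 6.8 s
short-lifetime mean, and the long-lived fraction *smaller* than the
configured 0.15 — both are censoring effects of a 120 s movie: long-lived
clusters (mean 1000 s) are mostly observed as truncated spans below
100 s, which inflates the short-lived average and hides the long
population. The package's recovery benchmark therefore runs long
simulated acquisitions where censoring is mild; see the methods vignette
(`vignettes/tcpalm-methods.Rmd`) for the model and the reasoning.

Cluster-level output (first rows of `cl$clusters`):

```
  cluster_id centroid_x_nm centroid_y_nm n_detections r_gyration_nm
1          1      16790.84      4165.80          963          75.2
2          2      30869.76     31414.98         7050          73.0
3          3      21467.53     35509.27          461          72.2
```

The end-to-end pipeline with persisted, schema-versioned CSV outputs and a
checksum manifest:

```r
cfg <- pipeline_config(sim = sim_config(), seed = 7L)
run_pipeline(cfg, out_dir = "out/")   # identical config+seed => byte-identical outputs
```

A thin command-line wrapper lives at `inst/cli/irclusters.R`
(`Rscript irclusters.R run --config cfg.json --seed 7 --out out/`, plus
`sim`, `localize`, `cluster`, `tcpalm` subcommands).

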