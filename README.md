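# axoquant

Quantification machinery for rodent ocular-hypertension (microbead occlusion
glaucoma) experiments, for researchers who read out early axonopathy from
fluorescence microscopy rather than cell counts:

* **Anterograde transport mapping** — reconstructs a flattened retinotopic
  map of CTB tracer density over the superior colliculus from serial coronal
  sections and computes **percent intact transport**: the fraction of the
  map at or above 70% of the tissue's reference maximum,
  `100 · #{density ≥ 0.70} / #{valid cells}`.
* **Immunolabel quantification** — percent area of positive label in an ROI
  and per-animal **microbead:saline ratios** (ratio 1 = no pressure effect),
  aggregated images → animal → group (mean ± SEM).
* **NF-κB nuclear localization** — DAPI-gated nucleus segmentation
  (Otsu + watershed) and a per-nucleus score
  `nuclear mean / (nuclear + perinuclear-annulus mean)`.
* **Retinal morphometry** — layer thickness from boundary polylines and
  CTB+/DAPI+ RGC density in the ganglion cell layer.
* **Statistics** — Shapiro–Wilk-gated two-sided t tests with Mann–Whitney
  fallback, one-way ANOVA + Holm–Šidák pairwise comparisons, one-sided t
  tests against a unity ratio, IOP elevation summaries.
* **Synthetic data** — generators for every input modality with exact,
  recomputable ground truth (sector-shaped transport deficits, controllable
  label fractions, known nuclear partitions, layered retina phantoms, IOP
  time series with ~30% unilateral elevation), so the whole pipeline is
  testable without microscopy data.

## Worked example

Simulate a small three-group cohort (vehicle / low dose / high dose, one
microbead and one saline eye per animal) and run the full pipeline:

```r
library(axoquant)
m   <- simulate_cohort("cohort", n_per_group = 2, seed = 1)
res <- run_pipeline("cohort", run_config(seed = 1), "report")
aggregate(percent_intact ~ group + eye, res$transport, mean)
#>     group       eye percent_intact
#> 1   HE100 MICROBEAD       87.32955
#> 2    HE20 MICROBEAD       69.16396
#> 3 VEHICLE MICROBEAD       56.23377
#> 4   HE100    SALINE       87.68669
#> 5    HE20    SALINE       85.17045
#> 6 VEHICLE    SALINE       85.36526
```

Saline-eye maps stay near 85–90% intact while the vehicle-group microbead
eye falls to ~56% — the transport deficit the model induces — and the
high-dose group's microbead eye stays near its saline eye, the rescue
pattern the effect-size calibration encodes. The ratio table shows the same
logic for markers (vehicle BDNF microbead:saline ≈ 2.2, i.e. pressure-driven
up-regulation; treated groups near or below 1):

```r
res$ratios[res$ratios$marker == "BDNF", c("group", "mean_ratio", "sem")]
#>     group mean_ratio        sem
#> 1 VEHICLE  2.2294668 0.04818025
#> 2    HE20  0.6985729 0.02624281
#> 3   HE100  1.3470783 0.01457214
```

Single-map usage:

```r
out <- generate_sc_series(synthetic_spec(seed = 7), deficit_fraction = 0.4)
tr  <- transport_from_sections(out$sections, out$masks)
tr$percent_intact   # 59.85 — i.e. ~60% intact for a 40% sector deficit
```

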