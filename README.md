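# HiCdegron

Contact-map analytics for acute-depletion (degron) Hi-C experiments.

When a chromatin protein is rapidly degraded — an RNA polymerase, CTCF,
Cohesin — the question is *which scales of genome organization respond*:
megabase A/B compartments, topologically associating domains (TADs), focal
chromatin loops, promoter-anchored stripes, or the dense clusters of
polymerase binding sites ("hotspots"). HiCdegron implements the full
quantitative toolkit for answering that question from binned contact
matrices, together with a synthetic contact-map generator with known
ground truth, so every estimator can be validated by parameter recovery
before it touches real data.

## What it computes

Given per-chromosome contact matrices for an untreated and a treated
condition (read from HiC-Pro-style triplet text files or built from
4DN-style pairs), the pipeline:

* **matches sequencing depth** by multivariate-hypergeometric
  downsampling (totals conserved exactly);
* **balances** each matrix by iterative correction (ICE): cells are
  repeatedly divided by the product of their bins' marginals until the
  marginal coefficient of variation falls below tolerance, giving
  weights *w* with `balanced(i,j) = count(i,j) · w_i · w_j`;
* computes the **expected-by-distance profile** `e(d)` and the
  **observed/expected** transform `O/E(i,j) = x_ij / e(|i−j|)`, whose
  per-distance mean is 1 by construction;
* calls **A/B compartments** as the leading principal component of the
  O/E correlation map (sign-oriented by a GC-like track) and quantifies
  compartmentalization with **saddle plots**: bins are ranked into PC1
  quantiles and strength = (mean AA + mean BB corners) / (mean of the
  cross corners);
* computes the **insulation score**
  `log2(diamond sum / chromosome mean)` in a sliding window, boundary
  meta-profiles, 90×90 rescaled **meta-TAD pile-ups** (each domain window
  spans three domain lengths) and per-domain **intra-TAD O/E
  enrichment** (two-sided Wilcoxon between conditions);
* runs pair-anchored aggregates: **PE-SCAn** around all hotspot-summit
  pairs (500-kb windows, permuted-anchor background), **loop APA**
  (center pixel / bottom-left corner block), stratified
  **promoter-pair pile-ups** (intra-TAD 200 kb–2 Mb vs long-range
  2–10 Mb × expression tertiles × CTCF within ±5 kb) and **stripe decay
  curves** up to 200 kb from each target;
* classifies loops by ChIP occupancy of their anchors
  (both / single / none per factor, e.g. "Pol II at both anchors,
  no Cohesin, no CTCF"), stitches binding peaks into ROSE-style
  **hotspots** (12.5-kb gap, rank-signal tangent cutoff), and reports
  **percent change** per feature class,
  `100 · (mean_treated − mean_untreated) / mean_untreated`, with paired
  and two-sample standard errors and Student's-t / Wilcoxon tests, loop
  length trends (loess), transcription-ranked domain contrasts and
  change-vs-signal correlations.

The synthetic generator (`simulationConfig()` → `makeExperiment()`)
embeds a power-law distance decay, a mean-preserving compartment
checkerboard, domain blocks, 3×3 focal loops of three occupancy classes,
stripes, and clustered hotspots, then draws Poisson counts at a chosen
depth; every feature class carries a multiplicative perturbation factor
*f* applied in the treated condition, so the expected percent change of
that class is exactly `100 · (f − 1)`.

## Worked example

An in-silico depletion: hotspot-pair contacts scaled by 0.874 and
Pol II-only loops by 0.9, on two 20-Mb chromosomes at 25-kb bins with
2×10⁶ contacts per condition.

```r
library(HiCdegron)

cfg <- simulationConfig(seed = 42L,
                        factors = list(hotspot = 0.874,
                                       loop = c(pol2_only = 0.9)))
exp <- makeExperiment(cfg)
report <- runAnalyze(exp, defaultAnalysisParams(seed = 42L))

report$hotspots$change
#> Percent change: -14.02% (s.e. 2.04); t-test p = 1.0997e-07
#>   means: untreated 2.893 (n=132) -> treated 2.487 (n=132)
report$loopClasses$pol2_only
#> Percent change: -11.74% (s.e. 0.98); t-test p = 2.6657e-09
report$loopClasses$ctcf_cohesin
#> Percent change: -1.63% (s.e. 1.64); t-test p = 0.33511
```

The perturbed classes are detected (hotspot pairs −14%, Pol II-only
loops −12%, against injected −12.6% and −10%), while the untouched
readouts stay flat: saddle compartmentalization strength 1.63 → 1.62
(Wilcoxon p = 0.57), intra-TAD enrichment change −0.35% (p = 0.94),
CTCF/Cohesin loops −1.6% (p = 0.34). `runRecover(report, exp)` tabulates
recovered against injected changes per class:

```
              class injectedFactor expectedChangePct recoveredChangePct absErrorPct
  loop_ctcf_cohesin          1.000               0.0              -1.63        1.63
     loop_pol2_only          0.900             -10.0             -11.74        1.74
          loop_both          1.000               0.0              -3.08        3.08
            hotspot          0.874             -12.6             -14.02        1.42
             domain          1.000               0.0              -0.35        0.35
```

This is the dissociation the pipeline is built to measure: focal,
small-scale contacts respond to the perturbation while compartments and
domains do not.

## Vignette

`vignettes/contact-map-analytics.Rmd` documents the model and estimator
choices, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
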