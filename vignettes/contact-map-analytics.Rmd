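---
title: "Contact-map analytics for acute-depletion experiments: models, parameters and validation"
author: "HiCdegron authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-map analytics for acute-depletion experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

HiCdegron quantifies how chromatin architecture responds to the acute
depletion of a protein, from binned contact matrices of an untreated and
a treated condition. Its estimators span the scales of genome folding:
A/B compartments (saddle strength), domains (insulation, meta-domain
pile-ups, intra-domain enrichment), focal loops (APA, occupancy-class
percent changes), promoter-anchored stripes, and clustered binding
hotspots (PE-SCAn). A synthetic generator with known ground truth drives
validation: every estimator is tested by recovering the parameters it is
meant to measure.

# The data model

All objects share a `GenomeGrid`: chromosomes tiled left-to-right into
half-open `[start, end)` bins of fixed width (the last bin may be
short). Coordinates are 0-based half-open on disk (BED convention) and
1-based closed inside `GRanges`. Contact matrices are dense, symmetric,
per-chromosome (`ContactMatrix`), with `NA` marking masked bins — at the
scales this package targets (hundreds to a few thousand bins per
chromosome) dense storage is simpler and faster than sparse for
balancing, O/E and pile-ups, while the HiC-Pro-style triplet text file
remains the interchange format. Per-bin signals are `BinnedTrack`s in
which "no data" is `NA`, distinct from zero signal. Interval pairs
(loops, promoter pairs) are `LoopSet`s with canonically ordered anchors;
trans pairs are rejected.

# Normalization

**Depth matching.** Contact totals differ between libraries, and most
readouts are depth-sensitive, so both conditions are downsampled to the
smaller total before any comparison. Sampling is without replacement
across the multiset of contacts (multivariate hypergeometric), conserves
the target exactly, and is seed-reproducible.

**Balancing.** ICE iterative correction: bins with marginal below 2% of
the median nonzero marginal are masked (an optional MAD filter exists),
then every cell is divided by the product of its bins' mean-one
marginals until the marginal coefficient of variation drops below `tol`
(default 1e-7, maximum 400 iterations; non-convergence warns and flags
the result). Weights are returned so `balanced = count · w_i · w_j`.

**Expected and O/E.** `e(d)` is the mean balanced value over valid bin
pairs at bin distance `d`, per chromosome (cis decay differs between
chromosomes and all pile-ups are cis). Distances with no valid pair are
missing, not zero. `O/E = x / e(|i−j|)` has per-distance mean exactly 1.
The diagonal and `d = 1` are inflated by ligation artifacts in real
data; intra-domain enrichment therefore skips `d < 2` by default
(configurable), and pile-up windows are kept off the diagonal.

# Compartments

The eigenvector is the leading principal component of the Pearson
correlation map of the O/E matrix, per chromosome. Centering the
correlation columns before the eigendecomposition matters: the raw
correlation map carries a shared positive baseline whose eigenvector is
nearly constant, and on synthetic checkerboards the centered version
recovers bin labels at ≥ 99% sign agreement versus ~85–99% without
centering. Undefined O/E cells are imputed at their expectation (1)
so the dense BLAS path can be used. The sign is oriented against a
GC-content-like track (higher in A); chromosomes with a leading-variance
gap under 10% are flagged low-confidence.

The saddle ranks bins genome-wide into `n_quantiles` equal-occupancy
groups (default 5) and averages O/E over cis pairs at distance
≥ 10 bins (removing the decay-dominated near-diagonal); strength is the
mean of the two same-type extreme-quantile corners over the mean of the
two cross-type corners — single corner cells, not corner blocks, which
is stated here because it changes the numeric value.

In two-condition comparisons each condition is ranked by **its own**
eigenvector. Ranking the treated matrix by the untreated PC1 inflates
only the untreated corners (bins partly selected by their own noise),
producing a spurious ~0.3 strength asymmetry on otherwise identical
synthetic conditions; the symmetric design removes it.

# Domains and insulation

The insulation score of bin `b` is `log2` of the diamond sum
`{(i,j): b−w ≤ i < b < j ≤ b+w}` over the chromosome-mean diamond sum;
window default 10 bins (250 kb at 25-kb resolution — unstated in most
studies, so it is a declared choice here). Bins within `w` of an end are
masked. Boundary calling is prominence-based (flanking-maxima mean minus
the minimum, default threshold 0.5, leftmost plateau point on ties);
externally supplied boundary sets are equally supported and are the
normal mode for real data.

Meta-domain pile-ups extract, per domain, the O/E window spanning three
domain lengths (domain in the central third), rescale it to 90×90 by
exact area-weighted resampling (the global mean is preserved; missing
cells are excluded per pixel, a declared choice), and average per pixel.
Intra-domain enrichment is the per-domain mean O/E over inside pairs,
compared between conditions with a two-sided unpaired Wilcoxon test —
the unpaired test is deliberate: it asks whether the population of
domain enrichments shifted, and is insensitive to the sub-percent
systematic offsets that loop pixels inside domains would otherwise let
a paired test detect.

# Pair-anchored aggregates

**PE-SCAn** forms all cis pairs of point anchors (hotspot summits)
separated by at most 10 Mb and at least the window half-width (500 kb
default; the lower bound keeps the extracted square off the diagonal and
out of the mirrored triangle — a constraint beyond the usual
chromosome-end check), extracts the `(2w+1)²` submatrix around each pair
pixel and averages. The background repeats this with anchors placed
uniformly at random per chromosome (count-preserving, seed-controlled);
the ratio matrix and its center enrichment (center pixel over the
outermost one-pixel frame) are reported. Window extraction at matrix
level is equivalent to accumulating read pairs that map near both
anchors, which is how the procedure is usually described at read level.

**Loop APA** averages O/E windows at loop pixels (loops with anchor
separation ≤ 2 half-windows are skipped and counted); the summary is
the center pixel over the bottom-left 3×3 corner block (the
short-distance corner). Retained per-loop values are center 3×3 means —
a single pixel adds avoidable Poisson noise to downstream change
statistics without changing their expectation.

**Promoter pairs** are stratified by distance class (intra-TAD
200 kb–2 Mb; long-range 2–10 Mb), activity tertile (both promoters in
the same tertile; tertile sizes follow the remainder-to-higher-slices
rule, e.g. 4/3/3 for n = 10) and CTCF status (peak within ±5 kb of the
midpoint; mixed pairs are dropped from CTCF strata). Windows are 400-kb
squares. Promoters are caller-supplied intervals; the package does not
derive them from annotation.

**Stripes** are quantified at supplied targets (not discovered): the
decay curve is the mean O/E connecting the target bin to bins at
distance `d` on either side, for `d` up to 200 kb.

# Change statistics

Percent change is `100 · (mean_T − mean_U) / mean_U` over per-feature
values, defined only for a positive untreated mean and scale-invariant.
Two standard errors are always reported: the two-sample delta-method
s.e. (the uncertainty of the statistic when the two value sets are
treated as independent samples — the error bar that belongs to the
printed statistic in a two-condition figure) and, when features are
matched across conditions, the paired delta-method s.e.
`(100/m_U) · sd(t_i − (m_T/m_U)·u_i)/√n`, which removes between-feature
heterogeneity and is the right basis for detection tests in matched
in-silico designs. Tests follow the conventions of the readouts they
mirror: Student's t for loop sets, Wilcoxon for domain enrichments; both
are available everywhere.

Loop/hotspot change statistics run on matched-depth raw counts rather
than O/E: a multiplicative perturbation changes both by the same factor,
but counts keep the per-feature noise independent (O/E shares the
estimated `e(d)` across features). Loop occupancy classification uses
≥ 1 bp anchor–peak intersection, monotone in anchor padding. ROSE-style
stitching merges peaks with gaps ≤ 12.5 kb, ranks clusters by total
signal, scales rank and signal to [0, 1] and cuts where the curve is
farthest below the unit diagonal (the tangent-slope-1 point); ties
resolve toward fewer hotspots; summits are the strongest constituent
peak. The loess loop-length trend uses span 0.3, degree 1 (tricube), a
fixed evaluation grid, binned means as a smoothing-free fallback, and a
two-group summary at the 250-kb small/large threshold.

# The synthetic generator

`buildIntensity()` composes, per chromosome,
`μ(i,j) = max(|i−j|,1)^(−γ) · c · t · l · s · h`: a compartment
checkerboard `c` (amplitude α, renormalized per diagonal so it is
*exactly* mean-preserving — O/E corners stay symmetric around 1), domain
blocks `t = β`, 3×3 loop kernels `l = λ·f` (single pixels would vanish
under downsampling), stripe bands `s = σ·f` across each target's extent,
and hotspot-pair kernels `h = κ·f` for summit pairs within 10 Mb.
Overlaps combine multiplicatively. The treated condition multiplies each
feature class by its factor `f`, so the expected class change is exactly
`100·(f−1)`. Counts are independent Poisson draws scaled to the target
depth (negative-binomial overdispersion available), bit-reproducible
under a seed.

Defaults, fixed once: γ = 1.0, α = 0.15, β = 1.6, λ = 2.5, σ = 1.5,
κ = 1.4; two 20-Mb chromosomes at 25-kb bins with 2×10⁶ contacts per
condition (the scale at which the package's own validation suite runs —
roughly the per-chromosome information density of a deeply sequenced
experiment after restriction to a region of interest); 12 hotspots per
chromosome in one cluster spanning ~7 Mb with 2–4 constituent peaks each
(gene-dense-region density; clustering keeps pair separations in the
0.6–7 Mb range where 2×10⁶ contacts still put several counts per pixel,
a power consideration settled before the validation thresholds were
run); 12 CTCF/Cohesin corner loops (300–600 kb), 12 Pol II-only small
loops (175–250 kb, inside transcribed domains), 6 dual-occupancy loops,
~25–30 domains of 300–900 kb per chromosome, 6 stripes (200-kb extent),
36 promoters per chromosome with log-normal activities and Bernoulli(½)
CTCF flags. The nascent-transcription-like track is elevated over
transcribed domains and spikes at promoters proportionally to activity;
the orientation track is a noisy GC-like proxy higher in A bins.

What the generator does **not** emulate: restriction-fragment geometry
and ligation artifacts (the pair-level filters are tested on constructed
fixtures instead), genomic coverage bias beyond what ICE removes,
overdispersion beyond Poisson by default, trans contacts, nested domain
hierarchies, polymer-physics correlations between neighboring pixels,
and real mESC biology. Passing recovery tests therefore demonstrates the
estimators' correctness and calibration under the stated statistical
model — not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

Text writers emit `%.17g` so read/write round trips are bit-exact.
Downsampling uses cumulative-sum inversion of a uniform draw without
replacement. ICE requires at least one unmasked bin and warns instead of
failing on non-convergence. Expected profiles return `NA` (never 0) for
empty distances; O/E cells with undefined or zero expected are missing.
`rescaleSubmatrix` weights fractional overlaps by area and preserves the
global mean exactly when no cell is missing. Empty feature sets
propagate as empty results, never errors. Boundary ties report the
leftmost plateau point; tertile and group remainders go to the
higher-ranked slices; domain ranking breaks score ties by coordinate,
stably. The hotspot tangent cutoff keeps ties below the line (fewer
hotspots). Derived seeds stay below 2³¹.

# Validation problem sizes

The test suite validates exact oracle equivalence (brute-force diamond
sums, area-weighted rescaling by common-subdivision, window extraction,
saddle enumeration) on random matrices up to 50×50; normalization
invariants at study scale; null calibration and the
loop-versus-large-scale dissociation over 20 simulation seeds at the
2×20 Mb / 2×10⁶-contact scale; effect recovery (hotspot factor 0.874,
Pol II-loop factor 0.9) averaged over 6 seeds, where the single-seed
sampling s.d. of the hotspot change is ~2–3 percentage points and the
6-seed mean ~1; and monotonicity of saddle strength in α and APA
enrichment in λ. These sizes were chosen so each property is measured
with comfortable statistical margin.

# Known limitations

Dense per-chromosome storage bounds practical resolution (a 2,000-bin
chromosome is instant; a 25,000-bin one is not the target). Balancing is
ICE only (no KR), cis only. Compartment calling returns one eigenvector
(no A1/A2 sub-compartments, no trans-based strength). Boundary calling
is prominence-based, not arrowhead; loop calling, peak calling and read
alignment are out of scope — the package starts from binned matrices and
caller-supplied features. The in-silico degron contrast assumes
multiplicative, class-wise perturbations; graded or position-dependent
effects can be emulated only by editing the truth catalog directly.
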