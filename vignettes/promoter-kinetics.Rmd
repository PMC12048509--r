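---
title: "From single-molecule promoter footprints to Pol II kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-molecule promoter footprints to Pol II kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfkinetics)
```

## The measurement and the model

Single-molecule footprinting (SMF) methylates accessible cytosines with an
exogenous enzyme before bisulfite sequencing. Each aligned read is therefore
a snapshot of one DNA molecule in one cell: methylated positions were
accessible, unmethylated positions were protected by a bound protein or a
nucleosome. At a promoter, the protection pattern around the TSS identifies
what occupied the molecule at the instant of labelling.

`smfkinetics` treats these snapshots as draws from the stationary
distribution of a three-state stochastic promoter:

* **nucleosome** — the promoter is occluded;
* **open** — accessible DNA, possibly PIC-bound, but without Pol II;
* **Pol II** — a polymerase footprint at the pausing site.

Transitions are nucleosome binding/unbinding (`kc`, `ko`) and Pol II
initiation/turnover (`ki`, `kt`), all in min⁻¹. The master equation is
linear; `steady_state()` returns its unique stationary distribution
(`p_open = 1/(1 + kc/ko + ki/kt)` and detailed-balance multiples thereof),
`propagate()` returns the exact time-dependent solution through the matrix
exponential of the 3×3 generator (no ODE stepping, so the `t = 0` identity
and the ergodic limit hold to machine precision), and
`gillespie_simulate()` provides an exact stochastic realisation used as an
independent cross-check of the algebra.

The key observable is the *relative Pol II occupancy*
`q = P_PolII/(P_open + P_PolII)`, the fraction of nucleosome-free molecules
carrying a Pol II footprint. At stationarity detailed balance gives
`ki * P_open = kt * P_PolII`, hence `q = 1/(1 + kt/ki)`: occupancy depends
on the rates only through their ratio. Measuring `q` (from the classifier)
and `kt` (from an initiation-block time course) therefore determines
`ki = kt * q/(1 - q)` (`infer_initiation_rate()`). Two modelling
consequences matter in practice:

* `q` alone can never separate fast-loading/fast-losing promoters from
  slow/slow ones — the turnover experiment is not optional;
* `kt` is an *effective* rate pooling entry into productive elongation with
  premature termination; the package makes no attempt to split them, since
  the decay of promoter-proximal signal cannot distinguish the two fates.

## The four-bin classifier

Reads are reduced to a 4-bit accessibility vector over four bins on the
TSS-relative axis (closed intervals, TSS base = 0, upstream negative;
minus-strand genes use the mirrored axis). The mouse preset is upstream
`[-58,-43]`, TATA `[-36,-22]`, Pol II `[28,47]`, downstream `[54,69]`; the
flanking bins separate the compact PIC/Pol II footprints from broad
continuous nucleosome protection. Other species shift these footprints
(e.g. the +1 nucleosome sits ~20 bp closer to the TSS in *Drosophila*), so
`bin_layout()` accepts arbitrary coordinates; only the mouse preset ships.

Per read, the mean methylation in each bin is rounded to 0/1. A mean of
exactly 0.5 rounds **up** (accessible) — an arbitrary but fixed and tested
tie-break. Reads lacking an informative cytosine in any bin are rejected
rather than imputed. The 16 possible vectors are partitioned into six
states; `default_state_mapping()` documents the default (fully accessible
`1111` = unbound; TATA-bin protection `1011` = PIC; Pol II-bin protection
`1101` = PolII; both `1001` = PIC+PolII; contiguous protected runs touching
an edge bin = nucleosome; the five remaining patterns = unassigned). The
mapping is deliberately an *input* (a 16-row TSV), not hard-wired: the
biochemical reading of the intermediate patterns is a judgement call, and an
analysis should be able to state and vary it.

Frequencies are computed per replicate for promoters with at least
`min_reads` classified molecules (20 by default; targeted amplicon designs
with thousands of reads per locus conventionally use 100), then averaged
across replicates unweighted — replicates are independent experiments, not
pools. Pol II binding is reported as `f(PolII) + f(PIC+PolII)` and PIC
binding as `f(PIC) + f(PIC+PolII)`.

When mapping the six observed states onto the three model states,
`unassigned` molecules are excluded from the nucleosome-free denominator of
`q` by default: they are not interpretable as open or Pol II-bound, and
counting them as "free" would dilute `q` by an amount that depends only on
classifier failure modes. `occupancy_from_states(include_unassigned =
TRUE)` provides the alternative convention, since the choice is not settled
by the data.

## Turnover from initiation-block time courses

After a chemical initiation block, promoter-proximal polymerase decays as
`mu(t) = A * exp(-kt * t)`. The package expects per-promoter counts at
{0, 2.5, 5, 10, 20} min with per-sample spike-in totals. Normalisation
divides by the spike-in total (times the mean total, purely cosmetic), then
averages replicates per timepoint; timepoints reduced to a single replicate
by QC pass through unchanged. Fold changes are taken against `t = 0`;
promoters with a zero baseline have no defined fold change and are dropped
*before* clustering (the alternative — dropping after — would let
all-zero rows distort the centroids).

`fit_decay()` maximises the Poisson-type log-likelihood
`sum(y_t log mu_t - mu_t)`. Because spike-in-normalised counts are not
integers, this is a quasi-likelihood; for integer counts it coincides with
the full Poisson MLE (the `y!` term is parameter-free). Numerics worth
stating:

* Given `kt`, the amplitude has the closed form
  `A = sum(y)/sum(exp(-kt t))`, so the fit is a one-dimensional root-find of
  the profile score, which is strictly decreasing in `kt` — no multi-start
  optimisation, no convergence tuning (root bracketing expands the upper
  limit geometrically and aborts with a diagnostic if the score never turns
  negative, which happens only when all counts sit at `t = 0`).
* The score at `kt = 0` is `sum(y) * mean(t) - sum(y t)`, so non-decaying
  data are detected analytically: the fit returns `kt = 0`, `half_life =
  Inf` and a boundary flag instead of a spurious interior optimum.
* The 95% Wald interval comes from the numerical observed information in
  `(log A, log kt)` (the log parameterisation keeps both parameters
  positive), delta-method-mapped back to the `kt` scale and truncated at 0.
  The paper-style design (5 timepoints, amplitude ≈ 5000) gives empirical
  coverage within a point or two of nominal; the level is a package default,
  not an empirical constant.
* `half_life = log(2)/kt` exactly.

Promoters are grouped by k-means (k = 4 by default) on the linear
fold-change vectors over the post-treatment timepoints, squared-Euclidean,
25 restarts under a fixed seed to stabilise Lloyd's algorithm. Cluster
labels are renumbered by increasing centroid decay rate so "cluster 1" is
reproducibly the slowest. Per-cluster rates are fitted to the *summed*
normalised counts of the member promoters — summing preserves the Poisson
character of the aggregate, whereas averaging would shrink the variance
inconsistently with the noise model; `fit_cluster_decay(per_gene = TRUE)`
fits members individually instead. Downstream, each promoter inherits its
cluster's `kt` (a per-gene override is a one-line join on the `kt` table
passed to `initiation_rate_table()`).

The pausing index is the ratio of counts at the TSS `[-150,150]` to the gene
body `[+300,+600]`; genes shorter than 600 bp (no body window) and genes
with a zero body count (non-finite ratio) are excluded with explicit
reasons rather than silently coerced.

## Annotation conventions

TSSs are refined to the strongest same-strand CAGE peak within 50 bp;
original positions are retained when no peak qualifies, and exact
`(chrom, pos, strand)` duplicates are then removed keeping the first record
in input order. CAGE score ties break by distance to the original TSS, then
by the most 5' position on the gene strand — deterministic and
minimal-displacement; neither tie-break is dictated by the data, so both are
stated here and tested. TATA-boxes are called by scanning for `TATAWAWR`
starting in `[-37,-18]`; the call provably ignores sequence outside
`[-37,-11]`. Window counting shifts each position downstream along its own
read strand (75 bp for fragment-size correction in ChIP-style data, 0 for
base-resolution assays), supports same/opposite/both strand selection
(nascent-transcription protocols sequence the strand opposite the gene),
and treats bedGraph input as 0-based half-open per the standard. Composite
profiles average across promoters, smooth with a centred 20-bp running mean
truncated at the edges, and optionally standardise to a Z-score; a constant
profile raises an error rather than dividing by zero.

## What the synthetic data does and does not emulate

The generators produce exactly the statistical structure the estimators
assume: molecules drawn i.i.d. from known state frequencies with
symmetric per-call flip noise `epsilon` (flanking cytosines accessible except
under a nucleosome, so composite profiles have the qualitative promoter
shape), and Poisson counts with exponentially decaying means scaled by
per-sample spike-in factors. Defaults mirror the study design: bins from the
mouse layout, timepoints {0, 2.5, 5, 10, 20} min, two replicates, amplitude
5000, 10,000–20,000 molecules per promoter in validation scenarios; where a
scenario needed a choice the design left open, it is made once here — e.g.
Dirichlet(5) state frequencies for recovery tests keep every state's
expected count well above the chi-square calibration floor, and random rate
sets for the stochastic-vs-analytic comparison are drawn Uniform(1, 2)
min⁻¹ so order-1 rates dominate Monte-Carlo error at 10⁵ simulated minutes.

Passing these tests shows the estimators are correct *under their own
assumptions*. Real data violate them in ways the generator deliberately does
not model: bisulfite conversion failure is asymmetric (not a symmetric
flip), cytosine density varies across promoters (some bins are chronically
uninformative), molecules are not independent across replicates prepared
from the same culture, counts are overdispersed relative to Poisson after
alignment and deduplication, and promoters need not be at steady state
during the labelling window. Estimates on real data inherit none of the
guarantees quantified here beyond consistency of the algebra.

## Validation problem sizes

The shipped checks run the classifier-recovery suite at 100 promoters ×
10,000 molecules, the decay calibration at 500 Monte-Carlo replicates of the
5-point design, Gillespie comparisons at 10⁵ simulated minutes × 10 rate
sets, and the end-to-end rate recovery at 20,000 molecules — sizes chosen so
Monte-Carlo error sits well inside each assertion's tolerance while the full
suite completes in a few minutes on one core.

## Known limitations

* The 16→6 mapping default encodes one biochemical reading of the ambiguous
  patterns; conclusions about the rare states (PIC+PolII in particular) are
  sensitive to it.
* `kt` conflates termination and elongation; `ki` is conditional on the
  measured `kt` and inherits its cluster-level granularity unless per-gene
  fits are used.
* The steady-state inversion is undefined at `q = 1` and degenerate at
  `q = 0`; both surface as typed errors/`Inf`, and promoters there need
  direct kinetic measurements instead.
* Only the mouse bin layout ships as a preset; applying the classifier to
  another species requires supplying coordinates appropriate to its
  footprint geometry.
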