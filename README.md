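# smfkinetics

Single-molecule footprinting (SMF) marks accessible DNA with an exogenous
methyltransferase before bisulfite sequencing, so each sequenced molecule
carries a protein-occupancy footprint: unmethylated cytosines were protected,
methylated ones were accessible. At promoters this resolves, molecule by
molecule, whether the DNA was wrapped in a nucleosome, open, bound by the
pre-initiation complex (PIC), or engaged by RNA polymerase II at the pausing
site — quantities that bulk assays (ChIP-seq, PRO-seq) can only report as
enrichments over a cell population.

`smfkinetics` is an R package for analysts working with such data. It
implements the quantitative machinery that links these single-molecule
promoter states to Pol II kinetics:

- **Promoter-state classifier.** Each read is summarised by its mean
  methylation in four bins around the TSS (upstream `[-58,-43]`, TATA
  `[-36,-22]`, Pol II `[28,47]`, downstream `[54,69]`; mouse preset), rounded
  to a 4-bit accessibility vector. The 2⁴ = 16 patterns are partitioned into
  six states — Pol II, PIC + Pol II, PIC, unbound, nucleosome, unassigned —
  and per-promoter state frequencies are computed per replicate (≥ 20 sorted
  reads) and averaged.
- **Three-state kinetic model.** A stochastic promoter cycling between
  nucleosome-occluded, open, and Pol II-bound states with rates *k*c, *k*o
  (nucleosome binding/unbinding) and *k*i, *k*t (initiation/turnover). At
  steady state, detailed balance gives *k*i·P_open = *k*t·P_PolII, hence the
  relative Pol II occupancy

  q = P_PolII / (P_open + P_PolII) = 1 / (1 + *k*t/*k*i)

  so occupancy measures the ratio of loading to loss. The package provides
  the closed-form steady state, the exact time-dependent solution of the
  master equation, a Gillespie simulator, and the inversion
  *k*i = *k*t·q/(1−q) that predicts initiation rates from occupancy and
  turnover.
- **Turnover estimation.** After chemically blocking initiation (e.g.
  triptolide), promoter-proximal Pol II decays at rate *k*t. From
  spike-in-normalised nascent-transcription counts at {0, 2.5, 5, 10, 20}
  min, the package computes fold changes, clusters promoters (k-means,
  k = 4), and fits A·e^(−*k*t·t) per cluster by Poisson maximum likelihood
  with Hessian-based Wald confidence intervals and half-lives
  τ½ = ln 2 / *k*t. Pausing indices (TSS `[-150,150]` over gene body
  `[300,600]`, genes < 600 bp excluded) are included.
- **Annotation utilities.** TSS refinement to the strongest same-strand CAGE
  peak within 50 bp, TATA-box detection (TATAWAWR in `[-37,-18]`),
  strand-aware shifted window counting, activity ranking, and composite
  profiles (20-bp smoothing, optional Z-score).
- **Synthetic data with ground truth.** Generators for single-molecule reads
  drawn from known state frequencies (with per-call flip noise) and for
  spike-in-scaled Poisson decay time courses, so every stage — and the full
  occupancy → turnover → initiation-rate chain — can be validated against
  known rates.

## Worked example

Simulate three promoters with known kinetics, classify their molecules,
estimate occupancy and turnover, and recover the initiation rates:

```r
library(smfkinetics)

rates <- list(kinetic_rates(1, 1, ki = 0.05, kt = 0.2),
              kinetic_rates(1, 1, ki = 0.30, kt = 0.2),
              kinetic_rates(2, 0.5, ki = 0.02, kt = 0.6))
sim <- simulate_end_to_end(rates, n_reads = 5000, A = 4000, seed = 42,
                           tss_ids = c("promA", "promB", "promC"))

cl     <- classify_molecules(sim$reads)
states <- average_replicates(state_frequencies(cl, min_reads = 20))
occ    <- occupancy_from_states(states)

ntc  <- spikein_normalize(sim$tc)
fits <- lapply(rownames(ntc$norm), function(g)
  fit_decay(ntc$norm[g, ], ntc$timepoints))
kt_tab <- data.frame(tss_id = rownames(ntc$norm),
                     kt = vapply(fits, `[[`, numeric(1), "kt_hat"))
initiation_rate_table(occ, kt_tab)
#>   tss_id      q    kt      r     ki interval_min
#> 1  promA 0.2111 0.201  3.736 0.0538        18.58
#> 2  promB 0.6048 0.196  0.653 0.3004         3.33
#> 3  promC 0.0293 0.592 33.100 0.0179        55.95
```

`q` is the fraction of nucleosome-free molecules carrying a Pol II footprint,
`kt` the fitted turnover rate (min⁻¹) after the initiation block, `r = kt/ki`
the rate ratio, `ki` the inferred initiation rate, and `interval_min = 1/ki`
the mean time between initiation events. The generating truth was
ki = (0.05, 0.30, 0.02) min⁻¹, kt = (0.2, 0.2, 0.6) min⁻¹, q = (0.20, 0.60,
0.032): the pipeline recovers all three within sampling error.

For file-based runs, `run_pipeline()` takes a YAML/list config and writes
`states.tsv`, `clusters.tsv`, `fits.tsv`, `rates.tsv` and a run log.

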