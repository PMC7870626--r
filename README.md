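# aopke — quantitative key-event analysis for mitochondrial neurotoxicants

`aopke` is an R package plus analysis workflow for adverse-outcome-pathway
(AOP) guided in vitro neurotoxicity screening of mitochondrial
respiratory-chain (MRC) inhibitors. The AOP chains MRC complex inhibition
(KE1) → mitochondrial dysfunction (KE2) → disturbed proteostasis (KE3) →
neurite degeneration (KE4, the in vitro proxy of the adverse outcome).
The package turns the raw outputs of such a screen — per-well
concentration–response readouts and targeted-sequencing count matrices —
into potencies, transcriptomic points of departure and concordance
classifications, and ships a synthetic-data module so every stage can be
validated against planted ground truth.

## What it computes

**Potency estimation.** Constrained four-parameter Hill fits with the
asymptotes fixed at 100/0 % of control,
`f(c) = 100 / (1 + (c/EC50)^h)`; effective concentrations solved
analytically, `ECx = EC50 * (x/(100-x))^(1/h)`; benchmark concentrations
(BMC10) with case-resampling bootstrap percentile intervals. Flat curves
(no 25 % effect in the tested range) are reported as explicit no-hits,
never as potencies.

**Differential expression.** Prefilter (sample total ≥ 0.2 million, gene
mean ≥ 1.5), median-of-ratios normalization, and a simplified per-gene NB
Wald test (`z = (ln μt − ln μc) / sqrt(vt + vc)`, `v = (1/n)(1/μ + α)`)
with trend-moderated method-of-moments dispersions and Benjamini–Hochberg
control. DEGs by the > 1.5-fold (0.59 log2) + FDR < 0.05 rule (an
FDR-only variant is also exposed).

**Transcriptomic point of departure.** Per-concentration DEG counts are
normalized to a positive-control count `N_pos` (capped at 100 %) and
fitted for EC10(DEG); the degree of gene-expression homeostasis,
`DGH = max(0, 100 − n_DEG)`, feeds the BMC machinery for BMC10(DEG). A
two-concentration overlap gene signature (anchor and 4× lower), its
FDR-masked cross-condition regulation matrix, and a PCA overview on the
100 most variable genes complete the stage.

**Classification.** Specificity of neurotoxicity from the
`EC25(viability)/EC25(neurite)` ratio (> 4 = specific, censored bounds
when viability is unaffected); a fixed 50 µM virtual screen with the
≥ 25 % effect hit rule; and the synoptic KE4/KEx sensitivity-ratio matrix
with categories > 3 / > 10 / > 100 (inverse < 1/3).

**Respirometry.** Per-well mitochondrial inhibition from OCR traces,
`100 * (baseline − post) / (baseline − nm)` after subtracting the
non-mitochondrial rate `nm`, with a mean ± 2 SD negative-control noise
band.

## Worked example

```r
library(aopke)

# a complex-I inhibitor with known truth
sp <- compound_spec("demo", "cI", ec50 = 1e-6, hill = 1.5, max_test_conc = 1e-4)
ds <- generate_dose_response(sp, "NA", noise_sd = 5, seed = 2)
fit <- fit_hill(ds)
fit
#> <hill_fit> demo/NA EC50 = 1.128e-06 M, h = 1.57, RSS = 415
effective_concentration(fit, 25)
#> <ec_estimate> EC25 = 5.606e-07 M (pEC 6.251)
benchmark_concentration(ds, 10, n_bootstrap = 500, seed = 3)
#> <bmc_result> BMC10 = 2.786e-07 M [2.475e-07, 3.085e-07], 500 bootstraps (0.0% failed)

# transcriptomic PoD worked values
deg_response(325, 325)   # positive-control normalization -> 100 (%)
dgh(150)                 # DGH floor                      -> 0
```

The full workflow lives in `analysis/01_simulate.R` …
`analysis/06_respirometry.R`; each stage is a thin driver over the
package functions, prints what it found and writes its tables under
`results/`. Running them in order on the shipped seed reproduces, among
others:

```
Fitted 70/70 curves (0 flat/no-hit)
EC50 recovery on KE curves: median |log10 error| = 0.014 (n = 56)
EC10(DEG) = 1.42e-07 M; truth 10% crossing = 7.08e-08 M (2.00-fold)
BMC10(DGH) = 1.58e-07 M
50 uM screen: 13/14 compounds fully concordant with KE4
KE ratio categories: 42/42 cells match the planted truth
Noise band from 12 vehicle wells: [-9.9, 7.1]%
```

i.e. potencies are recovered to a median of 0.014 log10 units (about
3 % on the concentration scale), the transcriptomic point
of departure lands within the method's characteristic ≤ 3-fold window of
the planted truth, and the ratio-based KE concordance layer reassigns
every planted category correctly.

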