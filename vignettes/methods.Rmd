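---
title: "Methods: quantitative key-event analysis for mitochondrial neurotoxicants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative key-event analysis for mitochondrial neurotoxicants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopke)
```

# Scope

`aopke` implements the quantitative layer of an adverse-outcome-pathway
(AOP) guided in vitro screen for mitochondrial respiratory-chain (MRC)
inhibitors. The AOP runs from MRC complex inhibition (KE1) through
mitochondrial dysfunction (KE2) and disturbed proteostasis (KE3) to
neurite degeneration (KE4), the in vitro proxy of the adverse outcome.
The package covers five analysis stages — concentration–response potency
estimation, negative-binomial differential expression on targeted count
matrices, transcriptomic points of departure, ratio-based classification
(specificity of neurotoxicity; KE sensitivity concordance), and
respirometry inhibition arithmetic — plus a synthetic-data module that
generates every input with known ground truth. Wet-lab processing, image
analysis and read alignment are out of scope: the pipeline starts from
per-well summary readouts and count matrices.

# Concentration–response model

All assay endpoints are expressed in percent of vehicle control, and the
curve model is the four-parameter Hill function with the upper and lower
asymptotes fixed at 100 and 0%:

$$f(c) = \frac{100}{1 + (c/\mathrm{EC}_{50})^h}.$$

Only the midpoint $\mathrm{EC}_{50}$ and the Hill coefficient $h$ are
free. Fixing the asymptotes makes the fit robust to stimulation
artifacts (responses above 100%, as seen with metabolic-reduction dyes);
such points are retained, never clipped.

Numerical choices, none of which the data model dictates, are:

* the optimisation runs in $(\log_{10}\mathrm{EC}_{50}, \log h)$ space
  with box constraints — $\mathrm{EC}_{50}$ within
  $[\min c/100,\ \max c \cdot 100]$, $h \in [0.2, 10]$ — using
  `L-BFGS-B` with an analytic gradient;
* three starts at the geometric quartiles of the tested range; best
  residual sum of squares wins, ties resolved toward the smaller $h$;
* a dataset in which no tested concentration reaches 25% effect is a
  *flat curve*: the fit is marked non-converged and no potency is
  reported, matching screening practice of not deriving an EC from an
  inactive curve. For the increasing DEG-response curve the same screen
  is applied at the 10% level.

Effective concentrations are solved analytically,
$\mathrm{EC}_x = \mathrm{EC}_{50}\,(x/(100-x))^{1/h}$, which holds for
both curve directions; a bisection oracle in the test suite confirms the
closed form to $10^{-9}$ relative tolerance. Estimates outside the
tested range are flagged `extrapolated`. Concentrations are molar
throughout; the $-\log_{10}$ (pEC) convention appears only in reporting
columns.

## Benchmark concentrations

`benchmark_concentration()` reports the $\mathrm{EC}_x$ at the benchmark
response (default 10%) with a case-resampling bootstrap interval:
replicates are resampled with replacement *within* each concentration,
the model refitted per resample (warm-started from the full-data
optimum), and the 2.5/97.5 percentiles of the resampled benchmark
concentrations taken. The point estimate is seed-free. A known
limitation: with triplicate data, percentile intervals of this kind are
narrower than their nominal level — the within-concentration resample
underestimates sampling variance by roughly the classical $(n-1)/n$
factor — and the coverage simulation in the test suite quantifies the
shortfall for the nominal 95% interval. Users needing calibrated
intervals at $n = 3$ should treat them as optimistic.

# Differential expression

The count stage follows the standard targeted-sequencing workflow:

1. **Prefilter.** Samples with a total count below 0.2 million are
   removed, then genes with a mean count below 1.5 over the surviving
   samples.
2. **Normalization.** Median-of-ratios size factors: reference genes are
   those with strictly positive counts everywhere; a sample's factor is
   the median ratio of its counts to the gene-wise geometric means.
   Factors are not rescaled further (a unit test cross-checks them
   against an independent reference implementation).
3. **Test.** A deliberately simplified per-gene NB Wald test of each
   treated condition against the vehicle controls, written from scratch:
   group means of normalized counts with a pseudocount of 0.5 (finite
   log fold changes with zeros), and
   $z = (\ln\mu_t - \ln\mu_c)/\sqrt{v_t + v_c}$ with
   $v = \tfrac1n(1/\mu + \alpha)$, the delta-method variance of a log NB
   mean ($\mathrm{Var} = \mu + \alpha\mu^2$). P values are two-sided
   normal, adjusted by Benjamini–Hochberg within the contrast (the FDR
   family is all genes surviving the prefilter for that condition).
   There is no fold-change shrinkage, outlier filtering or independent
   filtering: the downstream statistic consumes only per-condition DEG
   *counts*, which need calibrated testing rather than optimally ranked
   effect sizes.

## Dispersion moderation

The per-gene dispersion is the design decision that matters most at
$n = 3$. Three variants were evaluated against the package's own
calibration property (the fraction of raw $p < 0.05$ on null simulations
must sit in $[0.035, 0.065]$) and its power property (recall of planted
DE genes monotone in effect size, $\ge 80\%$ for well-expressed genes
with $|\log_2 \mathrm{FC}| \ge 1$):

* *Pooling.* Moment estimates $(s^2 - \bar x)/\bar x^2$ are computed per
  group and pooled by degrees of freedom. Pooling the raw counts of both
  groups around a grand mean instead lets a true expression difference
  masquerade as overdispersion and collapses power (recall 0.4–0.6 in
  pilots).
* *Trend.* A log-linear mean–dispersion trend is fitted to *binned
  arithmetic means* of the moment estimates. Gene-wise regression on the
  log scale, restricted to positive estimates, is biased low (≈ 0.038 at
  a true $\alpha = 0.05$) because the floored and negative estimates are
  dropped; bin averaging keeps them in.
* *Moderation.* Each gene's estimate (floored at $10^{-8}$) is shrunk
  50/50 toward the trend on the arithmetic scale. Log-scale (geometric)
  averaging drags floored genes toward zero dispersion and over-rejects.

With these choices the null level measures ≈ 0.043–0.058 across
simulation seeds — mildly conservative of the nominal 0.05, as expected
from the normal (rather than $t$) reference at four pooled degrees of
freedom combined with the pseudocount.

**DEG rule.** Two first-class rules: `fdr_and_fc` (default) calls a gene
at $|\log_2 \mathrm{FC}| > 0.59$ (1.5-fold) *and* FDR $< 0.05$;
`fdr_only` uses FDR $\le 0.05$ alone. The combined rule is the default
because the concentration–response DEG analysis downstream is defined
with the fold-change cut.

# Transcriptomic points of departure

Per-concentration DEG counts are converted into two complementary
summary statistics:

* **Normalized DEG response**: $\min(n_{\mathrm{DEG}}/N_{\mathrm{pos}},
  1) \cdot 100$, anchored to a positive-control DEG count
  $N_{\mathrm{pos}}$ (a strong reference inhibitor at its EC10 of
  viability; 325 in the motivating screen). $N_{\mathrm{pos}}$ is a
  required explicit input — the package hard-codes no value. The
  increasing Hill form is fitted to response versus concentration and
  solved at 10% for $\mathrm{EC}_{10}(\mathrm{DEG})$; 10% means 10% of
  the positive-control count, not of the DGH drop.
* **Degree of gene-expression homeostasis**:
  $\mathrm{DGH} = \max(0,\ 100 - n_{\mathrm{DEG}})$. The decreasing DGH
  series is run through the benchmark-concentration machinery at a 10%
  benchmark response, yielding $\mathrm{BMC}_{10}(\mathrm{DEG})$.

The two definitions are numerically different (10% of
$N_{\mathrm{pos}}$ versus a DGH drop of 10 DEGs) and both are exposed;
neither is privileged, and the analysis scripts report both.

The **overlap signature** intersects the DEG sets of an anchor
concentration (the highest non-cytotoxic level) and a 4× lower one —
genes regulated at the definitely non-cytotoxic level are unlikely to be
unspecific cell-death indicators. The dilution step is configurable; 4×
is the default because it matches the anchor's position in a 4-fold
concentration series. The signature's cross-condition **regulation
matrix** carries log2 fold changes, masks cells with FDR $> 0.1$ (shown
white in heatmaps), and distinguishes *absent* (gene missing from a
condition's table) from *masked*. The **PCA overview** ranks genes by
the variance of $\log_2(\text{normalized count} + 1)$ — the log scale is
chosen because "most variable genes" on the raw scale merely ranks by
expression — and decomposes the per-gene-centred top 100.

# Classification layers

* **Specificity of neurotoxicity**:
  $R = \mathrm{EC}_{25}(V)/\mathrm{EC}_{25}(\mathrm{NA})$ on the linear
  molar scale. $R > 4$: specific; $R \le 4$: unspecific (the published
  rule is a strict inequality, so exactly 4 is unspecific); viability
  unaffected in the tested range: the censored bound
  $c_{\max}/\mathrm{EC}_{25}(\mathrm{NA})$, called *potentially
  specific* when $\ge 2$; otherwise not determinable.
* **Virtual 50 µM screen**: effect $= 100 - f(50\,\mu M)$ from the
  fitted curve (interpolating the fit rather than snapping to the
  nearest tested concentration, since grids differ between compounds);
  hit at effect $\ge 25\%$. For flat curves the mean observed responses
  are interpolated in log concentration.
* **KE sensitivity ratios**:
  $\mathrm{EC}_{25}(\mathrm{KE4})/\mathrm{EC}_{25}(\mathrm{KEx})$ with
  categories strong ($> 100$), marked ($> 10$), moderate ($> 3$),
  neutral ($[1/3, 3]$), inverse ($< 1/3$); boundaries resolve to the
  lower category because all rules are strict. Undefined ECs give
  `n.a.`, with an optional censored lower-bound ratio computed from the
  maximum tested concentration.

# Respirometry

Per-well inhibition uses three anchor measurements of the OCR trace: the
baseline (last measurement before treatment), the first measurement
after treatment, and the non-mitochondrial OCR `nm` (mean of the
measurements after the rotenone + antimycin A injection, which abolishes
mitochondrial respiration):

$$\mathrm{inhibition} = 100 \cdot
  \frac{(\mathrm{baseline} - nm) - (\mathrm{post} - nm)}
       {\mathrm{baseline} - nm}.$$

The statistic is a ratio, hence invariant to per-well normalization
(dividing the trace by its OCR at equilibration end), which is applied
to reduce well-to-well variability. The first post-treatment measurement
is used, not an average of several. The negative-control noise band is
mean ± 2 SD of vehicle-well inhibitions — a methodological stand-in
declared as such, since noise-band conventions differ between
laboratories — and compound means inside the band are flagged
insignificant. Wells aggregate as mean ± SEM.

# Synthetic data

The generator defines the study conditions everything is tested under:

* **Responses.** Hill curves with fixed asymptotes plus Gaussian noise
  on the percent scale (default SD 5 percentage points, triplicates),
  truncated to $[-10, 110]$ to admit the slight overshoot of
  metabolic-reduction readouts. Concentration grids are log-spaced
  serial dilutions (half-log default), as in screening practice.
* **Counts.** $\mathrm{NB}(\mu = s_j\, b_g\, 2^{\mathrm{lfc}_g(c)},
  \alpha)$ for a 3000-gene targeted panel, five concentrations in a
  4-fold series, triplicates plus vehicle controls. Baseline means
  $b_g$ are log-normal (meanlog 4, sdlog 1.5), spanning the dynamic
  range of a targeted panel with zeros arising naturally; size factors
  $s_j$ are log-normal (meanlog 0, sdlog 0.1), a realistic library-depth
  spread; dispersion defaults to $\alpha = 0.05$. Planted DE genes
  follow a saturating Hill dose curve in $\log_2$ fold change with
  random sign; per-gene midpoints can be spread log-uniformly so the
  planted DEG-count curve rises smoothly.
* **KE panel.** Upstream KE potencies are the KE4 potency divided by
  MoA-class multipliers. Defaults put KE1 two-plus orders of magnitude
  more sensitive than KE4 for cI/cIII inhibitors (300× / 200×), KE2 in
  between (30×), KE3 at parity, and the weak cII class at 30/5/1. The
  multipliers deliberately sit at least 1.5-fold away from the ratio
  category boundaries so every planted cell has an unambiguous truth
  category. The Hill coefficient is shared across a compound's KEs,
  making the planted EC50 multiplier equal the truth EC25 ratio exactly.
* **Reproducibility.** One global seed expands into named sub-stream
  seeds (responses, baseline, size factors, counts, signs), so adding a
  stream never perturbs existing fixtures; identical seeds give
  bit-identical outputs.

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real data: gene–gene correlation,
batch/differentiation effects, probe-level biases, compound-specific
transcriptional programs, biokinetics (nominal concentration equals
exposure), and curve shapes outside the fixed-asymptote Hill family.

# Problem sizes

The bundled analysis scripts and tests run at deliberately modest sizes
chosen to exercise every code path while keeping a full run in minutes:
a 14-compound panel with 3 replicates, one 3000-gene count simulation,
500-resample bootstraps, 100–200 dataset recovery simulations, and
three 2000-gene null simulations for the calibration check. All sizes
are parameters; nothing in the implementation assumes them.
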