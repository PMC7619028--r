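---
title: "Methods: predicting resistance evolution from single-generation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting resistance evolution from single-generation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resevo)
```

## The system and the model

`resevo` models the spread of a pesticide-resistance allele through a selfing
laboratory population in which only two genotypes segregate: a homozygous
resistant type R and a homozygous susceptible type S. Self-fertilisation
means no heterozygotes arise, generations are made discrete by synchronising
eggs at each passage, and the census size is reset to a constant $N$ every
generation. Under these assumptions the full multinomial Wright–Fisher
offspring draw collapses to a single binomial draw on the resistant count,
which is how `wf_step()` implements it.

The workflow has four stages.

**1. Dose–survival curves.** Survival of each genotype across a compound
dilution series is summarised by an inverse sigmoid on the log2
concentration axis,

$$\hat y = \frac{1}{1 + e^{a(x - b)}}, \qquad x = \log_2(\text{concentration}),$$

with slope $a > 0$ and midpoint $b$; the EC50 is $2^b$. Plate counts are
first normalised to the mean adult count of the no-compound control wells
(`normalize_survival()`; values above 1 are retained, not clamped, because
the control mean is itself a noisy denominator). `fit_dose_response()`
minimises the total squared error of $\hat y$ against the per-concentration
mean survival.

**2. Genotype fitness.** Fitness under a condition is the product
$w = m \cdot v$ of relative baseline fecundity $m$ (mean eggs per worm,
normalised so the susceptible strain has $m_S = 1$) and survival $v$ at the
condition's concentration, read off the fitted sigmoid
(`condition_fitness()`). At concentration 0 survival is exactly 1 by the
control-normalisation convention — $\log_2 0$ is undefined and the control
has no compound mortality by construction. Relative fitness is
$w_R / w_S = 1 + s$, defining the selection coefficient $s$.

**3. Forward simulation.** `wf_simulate()` iterates
$f_{t+1} = k/N$, $k \sim \mathrm{Binomial}\!\left(N,\; \frac{f_t w_R}{f_t
w_R + (1 - f_t) w_S}\right)$, from the seeded frequency $f_0$.
Frequencies are stored as exact counts over $N$; 0 and 1 are absorbing, and
simulation runs to the final generation even after absorption so all
trajectories have equal length.

**4. Inference from trajectories.** In an infinite population the frequency
follows the closed form

$$f_t = \frac{1}{1 + (1+s)^{-t}\,\frac{1-f_0}{f_0}},$$

whose log10 odds are exactly linear in $t$ with slope $g = \log_{10}(1+s)$
and intercept $-\log_{10}\frac{1-f_0}{f_0}$. `estimate_selection()` fits
that line by ordinary least squares and reports $s = 10^g - 1$, the relative
fitness $1 + s$, and the implied $f_0$. `compare_relative_fitness()` then
tabulates trajectory-derived ("in-vivo") estimates against the direct
("in-silico") ratio $w_R / w_S$ per condition.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| $N$ | 7500 | individuals/generation | eggs re-plated at each passage in the emulated design |
| $f_0$ | 0.05 or 0.50 | frequency | seeded resistant fraction; 0.50 compensates a strong resistance cost |
| replicates | 100 simulated / 6 observed lines | — | ensemble of stochastic predictions vs replicate experimental lines |
| eggs per well | 100 | count | plate-assay seeding density |
| wells per dose | 4 | count | assay replication |
| worms per fecundity assay | 12 | count | per-strain sample for the fecundity mean |
| `n_counted` | 200 | individuals | worms scored per frequency measurement |
| `control_viability` | 0.9 | proportion | eggs reaching adulthood without compound |
| NB `dispersion` | 30 | size parameter | overdispersion of per-worm egg counts |

## Numerical choices

- **Least-squares fitting.** `stats::nls` (`"port"`, bounded to $a > 0$ so
  the curve is an inverse sigmoid), convergence tolerance `1e-8`, starting
  from $a_0 = 1$ and $b_0$ at the log2 of the tested dose whose mean
  survival is closest to 0.5 — a near-midpoint start avoids the flat tails
  where the gradient vanishes. When port reports false convergence on noisy
  counts, the identical SSE objective is minimised by `optim` (L-BFGS-B,
  same bounds and start). A fitted slope at the lower bound
  ($a \le 10^{-4}$) means the dose dependence is unidentifiable and raises
  an error; a fit never silently returns a degenerate curve. Fitting uses
  per-concentration replicate means by default (`per_well = TRUE` fits raw
  wells), mirroring how such assays are summarised and plotted.
- **Boundary frequencies in the regression.** An observed 0 or 1 has no
  finite log-odds. The default excludes those points *and* every generation
  after the first absorbing observation (later values only restate the
  absorption); `continuity_correction = TRUE` instead replaces 0 with
  $1/(2n)$ and 1 with $1 - 1/(2n)$ using the per-generation count total
  $n$. Lines with fewer than two usable points are reported as
  not-estimable, never dropped silently.
- **Per-replicate vs pooled estimation.** Each replicate line is fitted
  separately and summarised as mean ± SD across lines by default — the
  spread across lines is itself informative; `pooled = TRUE` fits one
  regression per condition instead. Generation 0, the seeded mixture whose
  frequency is known by construction, enters the regression at its nominal
  value.
- **RNG discipline.** Replicates run on independent L'Ecuyer-CMRG
  substreams spawned from one master seed, so enlarging an ensemble never
  perturbs the replicates already drawn; every generator restores the
  caller's RNG kind and state on exit.

## What the synthetic study emulates

`gen_full_study()` packages a five-condition design: a spirotetramat arm
(susceptible EC50 24.4, resistant 93.3 assay units — a 3.82-fold shift;
resistant fecundity advantage $m_R = 1.2$; resistance seeded at 5%;
conditions control / 20 / 24 units; 7 generations) and an ivermectin arm
(susceptible EC50 1.07, resistant 50.1 units; resistant fecundity cost
$m_R = 0.5$; seeded at 50%; conditions control / 1.4 units; 4 generations),
each with $N = 7500$ and 6 replicate observed lines.

Quantities the underlying experiments do not pin down were fixed once as
realistic study conditions and are flagged in the bundle's manifest as
assumptions: the sigmoid slopes ($a = 3$ throughout except the ivermectin
susceptible curve, $a = 5.7$, chosen so susceptible survival at the
selection doses is about 52% at 24 spirotetramat units — moderate
selection — and about 10% at 1.4 ivermectin units — strong selection);
the fecundity means (230.4/192 and 100/200 eggs per worm, giving the
ratios above); 200 individuals scored per frequency measurement (a
realistic plate-count scale at which counting noise is secondary to drift
at $N = 7500$); control viability 0.9 (cancelled by normalisation in
expectation); and negative-binomial egg counts with size 30.

Noise enters exactly where the assays are stochastic: binomial maturation
counts per well, negative-binomial per-worm fecundity, binomial Wright–
Fisher reproduction, and binomial observation of each generation's
frequency from `n_counted` scored individuals. The generator does **not**
emulate plate spatial effects, bleaching losses, temperature effects, male
outcrossing, de novo mutation, or fluctuating viable population size — so
passing recovery tests show the pipeline is correct and well calibrated
under its own assumptions, not that those assumptions hold for any given
laboratory dataset. In real data, for example, extra-binomial variance
between replicate lines (the motivation for the package's
`variance_sweep()`) would widen the spread of per-line estimates without
necessarily biasing their mean.

## Design decisions that were genuinely open

- **Genotype labels.** Fitness is expressed for explicit R and S genotypes
  with relative fitness $w_R / w_S$, avoiding AA/aa homozygote notation
  whose assignment to resistant vs susceptible is ambiguous in parts of the
  source literature. No computation changes.
- **Survival "interpolation".** Survival at a condition's dose is evaluated
  from the fitted sigmoid, not piecewise-linearly between tested doses: the
  curve is fitted explicitly and downstream code consumes single survival
  values, so the parametric curve is the natural interpolant.
- **Fitting means, not wells.** The default fits per-concentration means;
  per-well fitting is exposed but off. With equal well counts per dose the
  least-squares estimates are very close; means match how the assays are
  reported.
- **Observation count.** How many worms were scored per generation in the
  emulated experiments is unknown; 200 is the package default and is
  recorded as an assumption in the manifest.

## Problem sizes used in the test suite

Monte-Carlo checks in the package's tests use ensembles chosen to make the
statistical tolerances meaningful at desk scale: 10,000 replicates for the
one-generation drift law and the variance sweep (variance estimable to
~1.4% relative SE), 50,000 draws for the small-$N$ exact-enumeration
goodness of fit ($\alpha = 0.001$), 200 simulated plate assays for EC50
recovery at assay noise, and 20 synthetic study seeds × 6 lines × 5
conditions for the end-to-end relative-fitness recovery loop (within 10% of
truth on the mean). The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

- Two homozygous genotypes under selfing only: no dominance, outcrossing,
  mutation, migration, age structure, or density dependence.
- The logit-linear estimator assumes constant $s$ across generations and
  ignores drift-induced autocorrelation; it is exact on deterministic
  trajectories and unbiased at large $N$, but a likelihood-based
  Wright–Fisher estimator would be more efficient for small populations or
  heavily drifted lines.
- The 2-parameter inverse sigmoid has fixed asymptotes at 0 and 1; assays
  with partial maximal kill or hormesis would need a richer dose-response
  family, deliberately out of scope.
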