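---
title: "Modeling MSC passage culture and its probabilistic design space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MSC passage culture and its probabilistic design space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscpassage)
```

## The problem

Mesenchymal stem cells (MSCs) for cell therapy are expanded by repeated
passage: cells are seeded in flasks, grown for a few days, enzymatically
harvested and reseeded at the original density, doubling the culture
surface as the population grows. Two design variables govern the campaign:
the number of passages $N_p$ and the harvesting time $t_h$ (days per
cultivation). Choosing them is a compromise between three quality
indicators evaluated after the final passage:

* the **senescence level** $P_{sene} = \mu_{N_p+1} / \mu|_{cPDL=0}$, the
  growth rate the lot would still show relative to its naive rate —
  replicative senescence degrades proliferative (and therapeutic) capacity
  as doublings accumulate;
* the **confluency level** $P_{conf} = X_{h,N_p} / X_m$ — harvesting too
  close to confluence is a quality risk;
* the **total harvested cells**
  $N_{cell} = n_{flask,N_p} \cdot S \cdot X_{h,N_p}$ — the lot must cover
  the clinical dose.

`mscpassage` implements the growth model, its calibration from passage
experiments, Monte-Carlo uncertainty propagation, and the resulting
probabilistic design space.

## The model

**Senescence clock.** The cumulative population doubling level
$cPDL_i = \sum_{j \le i} \log_2(X_{h,j}/X_s)$ counts realized doublings.
The specific growth rate of the next cultivation declines sigmoidally in
it:

$$\mu(cPDL) = \frac{\mu_m}{1 + \exp\{K_{sr}(cPDL - K_{50})\}}$$

with maximum rate $\mu_m$ (h$^{-1}$), half-decline location $K_{50}$
(doublings) and senescence rate $K_{sr}$ (per doubling, the negative slope
of the normalised sigmoid at $K_{50}$).

**Single cultivation.** Within one cultivation $\mu$ is constant and the
culture grows exponentially until contact inhibition:
$X_h = \min\{X_s e^{\mu \, \cdot \, 24(t_h - 1)},\; X_m\}$.

*Why $24(t_h-1)$ hours and not $24\,t_h$:* cells spend the first day after
seeding attaching; experimental growth rates are defined on the window
from 24 h to harvest (density at harvest over density at day 1). Fitted
rates therefore describe growth over $24(t_h-1)$ hours, and using the full
clock time instead is inconsistent with the calibration: it would predict
senescence at Day-3 harvests of the umbilical-cord source and make the
minimum harvesting time for the cell-count specification 2.5 d, neither of
which the calibrated sources show. With the attachment day excluded, the
model reproduces the published behaviour of both sources (no senescence at
Day 3 for UC through 15 passages; minimum A3 harvesting times of 3.5 d for
BM and 3.0 d for UC). Consequently every $t_h$ must exceed 1 day.

**Flask expansion.** All harvested cells are reseeded at $X_s$, so
$n_{flask,i+1} = \min\{\lfloor n_{flask,i} X_{h,i}/X_s \rfloor,
n_{flask}^{max}\}$. Flasks are identical and synchronized (one shared
density per passage); the floor is applied to the double-precision product
without epsilon nudging, since realistic density ratios sit far from
integer boundaries.

**cPDL bookkeeping.** cPDL is held constant within a cultivation and
updated at passage from the *realized* (possibly capped) harvest density —
exactly what an experimentalist computing cPDL from cell counts would
record. A harvest below seeding density is a domain error, not a silent
clamp: it can only arise from a negative growth rate, which the stochastic
layer prevents by flooring.

## Parameters

| symbol | meaning | unit | BM | UC |
|---|---|---|---|---|
| $\mu_m$ | maximum specific growth rate | h$^{-1}$ | 2.80e-2 | 3.30e-2 |
| $K_{sr}$ | senescence rate | – | 0.120 | 0.332 |
| $K_{50}$ | cPDL at half-maximal rate | – | 29.2 | 49.3 |
| $\bar{SD}$ (`sd_e`) | growth-rate noise SD | h$^{-1}$ | 1.80e-3 | 1.99e-3 |
| $X_s$ | seeding density | cells cm$^{-2}$ | 5.0e3 | 5.0e3 |
| $X_m$ | maximum cell density | cells cm$^{-2}$ | 6.41e4 | 6.41e4 |
| $S$ | flask area | cm$^2$ | 1720 | 1720 |
| flasks | initial → maximum | – | 1 → 10 | 1 → 10 |

The two bundled configurations (`inst/extdata/bm.yaml`, `uc.yaml`) encode
a bone-marrow and an umbilical-cord source: BM senesces early
($K_{50}=29.2$) but slowly, UC late ($K_{50}=49.3$) but steeply. The
shared maximum density $6.41\times 10^4$ is the largest measured value for
these cultures; it is a configurable field (`X_m`), and per-source values
can be supplied when available — the feasible-set counts are sensitive to
it through the confluency specification.

## Estimation and validation

`fit_passage_model()` fits $(\mu_m, K_{sr}, K_{50})$ to pooled
(cPDL, $\mu^{exp}$) points by bounded Levenberg–Marquardt least squares
(via **minpack.lm**) with a multi-start scheme ($\mu_m$ spanning
$[\max \mu^{exp}, 2\max \mu^{exp}]$, $K_{50}$ across the observed cPDL
range, $K_{sr} \in [0.01, 1]$); the best converged start is kept, so the
returned residual never exceeds the residual at any start. Flat data
trigger a warning because $K_{sr}$ is then unidentifiable.

`cross_validate()` rotates over the replicate samples: each fold fits on
all but one sample and validates the *full chained model* (growth →
harvest → cPDL → next rate) against the held-out sample, comparing
predicted and observed rates at the same passage numbers by NRMSE (RMSE
over the held-out range, in %; the normalisation uses each fold's
experimental data only). The reported parameter set is the plain
arithmetic mean of the per-fold estimates — not a refit on pooled data —
and the noise SD is calibrated by `pooled_sd()`: the mean over passages of
the per-passage sample SD of $\mu^{exp}$ across replicates (which for
triplicates underestimates the generating SD by the usual $c_4 \approx
0.886$ factor; the calibration deliberately mirrors the experimental
procedure rather than correcting it).

## Stochastic simulation

Growth-rate variability is one additive Gaussian perturbation
$e \sim N(0, \bar{SD})$ per cultivation, iid across passages and
iterations (no autocorrelation), plus one extra draw for the post-harvest
rate entering $P_{sene}$ — which is why $P_{sene}$ can exceed 1 in
stochastic runs, while the denominator $\mu|_{cPDL=0}$ stays the
noise-free constant. Noise is applied to the first cultivation too (with
$e=0$ that choice is unobservable). Negative perturbed rates are floored
at zero — the model has no decay phase — and floor events are counted per
ensemble (`n_floored`); at the calibrated SDs the floor is essentially
inactive before deep senescence.

Each (N_p, t_h) grid cell draws from its own substream seed, a
deterministic function of the master seed and the cell coordinates
(`substream_seed()`), so any cell can be recomputed in isolation, in any
order, bit-identically. Ensembles are vectorised over iterations: the full
165-cell grid at $M=10^4$ runs in a few seconds.

## Design space

A lot passes the joint specification $A$ when $P_{sene} \ge 0.8$
(inclusive), $P_{conf} < 0.9$ (strict) and $N_{cell} \ge 3.5\times 10^8$
(inclusive). For every grid cell the probability
$h(N_p, t_h) = \frac{100}{M}\sum_i I(y_i \in A)$ is estimated on the
Monte-Carlo ensemble, and the design space is the set of cells with
$h \ge \pi$ (default $\pi = 90\%$). The per-QI maps ($A_1$, $A_2$, $A_3$)
are evaluated on the *same* ensembles as the joint map — one simulation
pass, four indicator evaluations — so the joint probability never exceeds
a marginal, exactly. Cells with $h$ within one binomial standard error of
$\pi$ are flagged `borderline`: their membership can flip between seeds at
finite $M$, which is why published counts are only meaningful to about
±1 cell.

**Sensitivity to $X_m$.** `sensitivity_delta_h()` re-runs every cell with
$X_m \sim N(6.41\times 10^4, 5\%)$ drawn once per iteration and held
constant across that iteration's passages (lot-level variability; the
growth-rate noise already covers per-passage variation). Both runs share
each cell's noise substream — common random numbers — so the reported
$\Delta h = h_2 - h$ isolates the $X_m$ effect from Monte-Carlo noise.
Non-positive density draws (practically impossible at 5%) are redrawn and
counted.

## The synthetic-experiment generator

`generate_experiment()` emulates the calibration experiments: by default
three independent samples, 15 passages each at $t_h = 4$ d, recording per
passage the cPDL an experimentalist would compute from harvest counts
(0 before the first passage) and the noisy growth rate as $\mu^{exp}$.
Process and measurement noise are deliberately conflated in the single
additive term, matching how the noise SD is calibrated from real
replicates. The generator does **not** emulate donor-level offsets
(replicates are iid around one parameter set), imaging/counting error
structure, lag phases, or the early-passage growth-rate *increase* seen in
some real sources — so parameter-recovery tests demonstrate internal
consistency of the pipeline, not robustness to those real-data features.

## Numerical choices and problem sizes

* Tolerances: the LM fitter runs with library defaults (≈1e-8 relative);
  noise-free recovery tests assert 1e-6 relative agreement.
* The grid stores $t_h$ as exact multiples of 0.25 d; map joins match on
  these values directly.
* Deterministic equivalence between the vectorised ensemble engine and the
  scalar reference loop is exact (identical arithmetic), and tested
  bit-for-bit at $sd_e = 0$.
* Test-suite problem sizes: full 165-cell maps at $M = 10^4$ for the
  headline feasibility counts and sensitivity, $M = 2000$ for per-QI map
  features, $M \le 8000$ for convergence properties, and 20 seeded
  triplicate experiments for parameter recovery — the whole suite runs in
  well under a minute on one core.

## Known limitations

* cPDL (and hence $\mu$) updates only at passage; the within-cultivation
  increase in cPDL is ignored, which slightly flatters $P_{sene}$ at long
  $t_h$.
* The shared default $X_m$ makes the confluency specification equally
  tight for both sources; feasible-set counts shift by several cells when
  a source-specific $X_m$ is configured.
* No nutrient or metabolite dynamics (medium is assumed replenished by
  passage or scheduled change over the 2.5–5 d window), no per-cell
  heterogeneity, no discard fraction at reseeding.

## A worked run

```{r, eval = FALSE}
bm <- load_config(system.file("extdata", "bm.yaml", package = "mscpassage"))
ds <- determine_design_space(bm$params, bm$config)
ds
sens <- sensitivity_delta_h(bm$params, bm$config)
sens
```
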