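---
title: "Modeling subcellular mRNA kinetics from metabolic labeling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling subcellular mRNA kinetics from metabolic labeling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slamkin)
```

## The model and its assumptions

`slamkin` models each transcript's life cycle as a linear first-order
cascade through subcellular pools: nuclear pre-mRNA is processed to
mature nuclear mRNA (rate $k_1$), exported ($k_2$) or — optionally —
degraded in the nucleus ($\gamma_2$), then degraded in the cytosol
($\gamma_3$; 3-step model, cytosol-localized transcripts) or
transported to the membrane compartment without cytosolic decay ($k_3$)
and degraded there ($\gamma_4$; 4-step model, membrane-localized and
undefined transcripts). The assumptions this buys and their cost:

* **First-order kinetics, steady state.** Every transition is a
  single-exponential waiting time and total expression is stationary
  over the labeling window. Under stationarity, dividing each pool by
  its steady state gives a *rescaled* system for the share of new mRNA
  $\tilde u_i(t)$ that depends only on the total exit rates
  $r = (k_1,\; k_2 + \gamma_2,\; r_3,\; \gamma_4)$ — the production
  rate drops out and is not identifiable, by design.
* **Closed-form solutions.** The rescaled cascade's solution is the CDF
  of a sum of independent exponentials (hypoexponential): stage $i$
  labels as
  $\tilde u_i(t) = 1 - \sum_{j \le i} \big[\prod_{m \ne j}
  \tfrac{r_m}{r_m - r_j}\big] e^{-r_j t}$.
  This is what the fitter evaluates; it is certified in the test suite
  against high-accuracy numerical integration of the ODE system (max
  absolute error below $10^{-8}$ over random draws including
  near-degenerate rate pairs).
* **Elongation delays.** Poly(A)-selected, full-length sequencing sees
  5'-distal sequence only after the polymerase has reached the 3' end,
  so each exon's curve is evaluated at
  $\tilde t = \max(0,\, t - d/v - \delta)$ with $d$ the exon's mean
  distance to the 3' end (kb), $v$ the fitted elongation rate (kb/min)
  and $\delta = 5$ min a global delay for labeling onset. The pooled
  intronic region is fitted from the pre-mRNA stage at the heuristic
  pseudo-distance $0.1 \times$ gene length. Intron-less genes (and
  genes with usable data in only one region) drop the pre-mRNA stage;
  $k_1$ and $v$ are then not fitted and $\tilde t = t - \delta$.
* **No cell-division dilution.** Division times of the cell system are
  an order of magnitude longer than the fitted half-lives; a dilution
  term is deliberately omitted.

## Parameters that matter

| parameter | meaning | units | default / bounds |
|---|---|---|---|
| $k_1, k_2, \gamma_3, k_3, \gamma_4$ | transition rates | 1/min | fitted in $[0.001, 2]$ |
| $\gamma_2$ | nuclear decay | 1/min | 0, or fitted in $[10^{-6}, 2]$ |
| $v$ | elongation rate | kb/min | fitted in $[0.1, 10]$ |
| $\delta$ | labeling-onset delay | min | 5, fixed |
| SE floor | weight stabilization | share units | 0.06 |
| `n_starts` | random multistarts | — | 200 |
| `n_best_pool` | selection pool | — | 10 |
| ratio band | constraint half-width | SE units | 5 |

Half-lives reported downstream are $\ln 2 / \text{rate}$; nuclear
retention uses the total nuclear exit rate $k_2 + \gamma_2$.

## The fitting procedure

Each gene is fitted independently by weighted least squares on the
share-of-new-mRNA scale. Weights are inverse *mixed* standard errors:
half the point's replicate SE, half the mean SE of its compartment,
floored at 0.06 — a variance-stabilization step that keeps
near-duplicate replicates from dominating the objective.

Measured steady-state expression ratios constrain the parameter space.
TPM values are within-fraction relative units, so they are first placed
on an absolute scale with the relative compartment abundance factors
(below); the resulting membrane/cytosol ratio then bounds $k_3/\gamma_4$
to $\pm 5$ SE, and the nuclear/cytosol ratio bounds the corresponding
rate ratio. Constraints are implemented by *reparameterization*: the
bounded ratio is itself a free variable and the dependent rate is
derived from it, which keeps the optimizer box-constrained and smooth
rather than adding penalty terms.

Optimization runs `n_starts = 200` times from log-uniform random starts
(Levenberg-Marquardt in $\log_{10}$ parameter space). Out of the ten
lowest-$\chi^2$ solutions, the fit whose parameters are farthest from
the boundaries is selected; the metric is the maximized minimum
$\log_{10}$ distance of any kinetic rate (and $v$) to its nearer bound.
The bounded ratio variables are excluded from this metric: their
$\pm 5$ SE band is a data constraint, not a prior bound, so sitting
near its edge is not evidence of a degenerate fit. Ties resolve by
$\chi^2$, making the selection invariant to start order.

Standard errors are the square roots of the diagonal of the inverse
Hessian at the optimum, with the covariance scaled by the reduced
$\chi^2$ (the convention of standard least-squares error reporting);
derived rates get delta-method propagation. Per-gene random-start
streams are seeded from the master seed plus a stable hash of the gene
id, so removing a gene from a cohort changes no other gene's fit.

**Quality control** applies three exclusion rules: (a) reduced
$\chi^2 > 4$; (b) relative standard deviation of any parameter across
the ten-best pool $> 0.05$; (c) the nuclear or cytosolic
(cytosol-localized), or nuclear or membrane (membrane-localized and
undefined) rate at the maximum allowed boundary (within $10^{-6}$
relative). An elongation rate at either of its bounds raises a separate
flag and excludes the gene only from elongation-rate analyses.

**Nuclear decay** is off by default ($\gamma_2 = 0$). Both the null and
the extended model are fitted within the gene's model class, and the
extended model is kept only if $\mathrm{BIC}_{null} -
\mathrm{BIC}_{ext} > 10$ *and* $\mathrm{SE}(\gamma_2) < \gamma_2$, and
the extended fit passes QC. With weights acting as known Gaussian
errors, $\chi^2$ is $-2\log L$ up to a constant that cancels in
differences, so $\mathrm{BIC} = \chi^2 + p \ln n$.

## Relative compartment abundances

The whole-cell expression vector is modeled as
$a\,\mathrm{TPM}_{nuc} + b\,\mathrm{TPM}_{cyto} + c\,\mathrm{TPM}_{mem}
= \mathrm{TPM}_{whole}$ across highly expressed genes
($\mathrm{TPM}_{whole} > 50$) with $a + b + c = 1$ enforced by
$c = 1 - a - b$. All four TPM vectors carry measurement error, so the
fit is errors-in-variables: each gene's residual is divided by
$\sqrt{a^2 s_n^2 + b^2 s_c^2 + c^2 s_m^2 + s_w^2}$, the standard
deviation the linear combination inherits from all axes. For known
error variances this normalized-residual formulation attains the same
minimum as orthogonal-distance regression on this linear model; with
all SEs zero it reduces to ordinary least squares. The ratio SEs used
in the constraints propagate the TPM standard errors to first order;
the abundance factors themselves are treated as fixed in that
propagation, since the cohort-level factor uncertainty (relative errors
of ~2%) is negligible against per-gene TPM noise — a documented
approximation.

## Conversion rates and new-to-total ratios

The share of new mRNA is estimated upstream of the kinetic fit from T>C
mismatch counts. The sequencing-error rate $p_e$ comes from the control
orientation (A>G on the primary read) as the pooled mismatch rate. The
conversion rate $p_{conv}$ is fitted by EM on the two-component binomial
mixture $P(k\,|\,n) = (1-\pi)\,B(k; n, p_e) + \pi\,B(k; n, p_{conv})$
with $p_e$ held fixed — a two-step scheme rather than joint estimation,
because the control orientation identifies $p_e$ cleanly. EM starts at
$p_{conv} = 10\,p_e$ and $\pi = 0.5$ and stops when the log-likelihood
(which is nondecreasing by construction, and asserted to be so in the
tests) changes by less than $10^{-8}$; for realistic tables the
likelihood basin is unimodal, so a single start suffices. Ratios are
then `((T>C/T) - p_e) / (p_conv - p_e)` (background-corrected default)
or the plain `(T>C/T) / p_conv`, clipped to $[0, 1]$ since sampling
noise can push raw ratios slightly outside; zero interrogated Ts yields
a missing value, never 0.

## What the synthetic-data generator emulates — and what it does not

`simulate_cohort()` reproduces the statistical structure the analysis
assumes: 7 labeling times (15–180 min) with 2–4 replicates, three
fractions plus whole cell, relative abundances normalized from
(0.39, 0.15, 0.45), Gaussian replicate noise on the share scale around
the 0.06 SE floor (truncated to $[0,1]$), lognormal expression spanning
the TPM filters, gene structures from below 12 kb to beyond 30 kb with
1–20 exons, ~20% membrane-localized and ~5% undefined transcripts, and
a ~6% subpopulation with nonzero nuclear decay (drawn at 1–5 times the
export rate, matching the observation that decaying transcripts turn
over their nuclear pool faster than they export it). Ground-truth rates
are log-uniform within half-life ranges bracketing the observed
medians (processing ~22 min, nuclear retention ~78 min, cytosolic
~10 min, membrane ~21 min). Membrane-localized genes draw
$k_3/\gamma_4 \in [10, 60]$ and undefined genes $[4.6, 8.9]$, so their
membrane enrichment falls on the correct side of the 1.5/3.0
classification cutoffs by construction.

Deliberately *not* simulated: read-level alignment artifacts, SNPs,
fraction cross-contamination beyond a constant membrane background for
cytosolic genes, cell-cycle dilution, and (by default) the slow
increase of conversion efficiency over labeling time — a documented
caveat of elongation-rate estimates; a linear ramp is available via
`conversion_ramp` for sensitivity checks. Passing recovery tests on
these data therefore demonstrates the estimator's correctness under the
model's own assumptions, not robustness to every artifact of real
libraries.

## Numerical choices

* **Near-equal rates.** The partial-fraction solution degrades when two
  exit rates nearly coincide. The public evaluator switches to the
  matrix exponential of the bidiagonal subgenerator (the exact
  confluent limit) when any pair is closer than $10^{-6}$ relative;
  inside the optimizer, where smoothness matters more than the last
  digit, rates closer than $10^{-7}$ are nudged apart by $3 \times
  10^{-7}$ relative — an error orders of magnitude below the data
  noise.
* **Degenerate constraint bands.** A ratio SE of 0 widens the band to
  $\pm 10^{-6}$ relative; a nonpositive lower bound is clipped to a
  small positive floor with a warning.
* **Exponential-decay fits** (derived half-lives) use the same
  least-squares backend, single start from a log-linear moment
  estimate, rate bounded in $[10^{-5}, 10]$ per min.
* **Problem sizes.** The validation suite uses cohorts of 200 genes for
  rate recovery and 150 genes for the nuclear-decay false-positive
  rate, 2,725 genes × 20 replicate simulations for abundance-factor
  recovery, and $10^5$ reads for conversion-rate recovery — sizes at
  which the Monte-Carlo error of each check is well below its
  acceptance margin.

## Open design points, resolved

* **Nuclear constraint species.** Whether the nuclear TPM constraint
  covers pre- plus mature mRNA or mature only is not determined by the
  data alone; poly(A) selection captures both species, so the default
  (`nuclear_constraint_mode = "total_nuclear"`) uses
  $(x_1 + x_2)/x_3$, with `"mature_only"` available. For intron-less
  genes the two coincide.
* **Ratio estimation framework.** New-to-total ratios are computed by
  scaled division rather than a posterior mean; the background-
  corrected mode is the default for synthetic data where $p_e$ is
  known exactly.
* **Inhibition-derived fits** use a plain exponential with no plateau
  term; transcripts with residual transcription would need one, and
  show up as `poor_fit` flags instead.

## Known limitations

Cytosolic residence of membrane-localized transcripts is short and
mainly pinned by the steady-state ratio constraint, so its point
estimates carry wider errors than the other rates — visible in the
recovery tests as a heavier error tail for $k_3$. Elongation rates for
short genes are weakly identified at a 15 min first time point;
boundary-flagged $v$ estimates should be excluded from elongation
analyses (the pipeline tracks this flag separately). BIC-based decay
detection is conservative by construction: at $\Delta\mathrm{BIC} > 10$
plus the SE rule, false positives among true-null genes are held below
1%, at the cost of limited power for weak nuclear decay.
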