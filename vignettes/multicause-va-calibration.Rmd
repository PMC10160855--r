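---
title: "Multi-cause verbal autopsy calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cause verbal autopsy calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacalibrate)
```

## The problem

Computer-coded verbal autopsy (CCVA) algorithms such as InSilicoVA and EAVA
turn interview data about a death into a cause-of-death prediction. Summing
those predictions over a surveillance population gives the *raw*
cause-specific mortality fraction (CSMF) vector $q$ — but CCVA predictions
are systematically wrong in ways that depend on the true cause, so $q$ is a
biased estimate of the true CSMF $p$. Where a reference standard exists for
a subset of deaths — here, expert panel determinations supported by
minimally invasive tissue sampling (MITS) — the error structure can be
estimated and removed.

Both sides of the comparison are *multi-cause*. A probabilistic CCVA
algorithm emits a full score vector $y$ over causes rather than a single
label, and MITS panels record both an underlying and an immediate cause.
This package implements the multi-cause calibration pipeline end to end:
encoding, misclassification estimation, generalized-Bayes calibration,
ensembling over algorithms, and WAIC model comparison.

## Model

**Encoding.** For each reference death the MITS assignment is a composition
$x$ with $x_c = 1$ if cause $c$ is both underlying and immediate, $0.5$ for
each of two distinct causes, and $0$ otherwise ([encode_mits()]). A record
missing its immediate cause is treated as single-cause — the only reading
consistent with the $\{1, 0.5, 0\}$ scheme.

**Misclassification.** For algorithm $a$, the matrix $M^{(a)}$ has entries
$M_{ij}$ = the average score assigned to cause $j$ among deaths with
reference cause $i$. A two-cause death is interpreted as a 50/50 mixture of
its two causes, so the expected VA composition of a death with encoding $x$
is $M'x$: estimating $M$ is the compositional regression $y = M'x$.
`fit_multicause_M()` minimises the Kullback–Leibler cross-entropy
$$L(M) = -\sum_k \sum_j y_{kj} \log\,(M'x_k)_j$$
over row-stochastic matrices (pseudo-maximum likelihood). When every $x$ is
one-hot the minimiser is the per-class mean of $y$, and for one-hot $y$ it
is the classical confusion-proportion matrix, so the single-cause definition
is an exact special case.

**Balance equation and calibration.** By the law of total probability the
raw and true CSMFs are linked by $q = M'p$. With $M$ and $q$ known exactly,
$p$ follows from a linear solve (`solve_fixed_M()`). Both are estimates, so
inference uses a generalized posterior
$$\pi(p, \{M^{(a)}\}) \propto
  \exp\!\big[-\textstyle\sum_a w_a L_a(p, M^{(a)})\big]\,\pi_0(p)\,
  \prod \pi_0(M^{(a)}),$$
where $L_a$ sums the paired-data term $-\sum_i y_i^{(a)}\!\cdot\!\log
M^{(a)\prime} x_i$ and the survey term $-\sum_k y_k^{(a)}\!\cdot\!\log
M^{(a)\prime} p$. For one-hot data each term is a multinomial
log-likelihood, so the generalized posterior is the ordinary Bayesian
posterior in the single-cause limit. Summing losses over algorithms with
equal weights is the ensemble calibration; `gb_config(loss_weights=)`
exposes the weighted variant.

## Sampler and numerical choices

- **Kernel.** Random-walk Metropolis within Gibbs: one block for $p$ and one
  per row of each $M^{(a)}$, all on additive-log-ratio (ALR) coordinates.
  No gradients are needed, every retained draw is renormalized onto the
  simplex at machine precision, and the ALR Jacobian combines with a
  Dirichlet$(\alpha)$ prior into the exponent $\alpha_j$ on each coordinate.
- **Adaptation.** Proposal scales adapt in batches of 50 iterations during
  burn-in only, multiplying by $\exp(\text{rate} - 0.25)$ toward roughly 25%
  acceptance, clamped to $[10^{-3}, 10]$.
- **Initialisation.** $M$ blocks start at the pseudo-ML fit; $p$ starts at
  the (algorithm-averaged) raw survey CSMF, floored at $10^{-4}$. Both are
  deterministic, so a fixed seed gives identical draws; chain $c$ uses
  `seed + c`.
- **Priors.** Flat Dirichlet(1) on $p$ and on each $M$ row. Nothing in the
  method prescribes informative priors, and the flat choice keeps the
  generalized posterior proportional to $\exp(-\text{loss})$ alone.
- **Floors.** Fitted and predicted compositions are floored at
  $\varepsilon = 10^{-10}$ before logs, then renormalized. This matters for
  structurally zero columns — an algorithm that *never* identifies a cause
  (as happens for congenital malformation with probabilistic CCVA output)
  must not generate $-\infty$ loss.
- **Ties.** The plurality rule breaks ties to the lowest cause index:
  deterministic and stable under the fixed cause order (the order of the
  packaged tables, which every matrix and vector in the package shares).
- **Misclassification fit.** Multiplicative EM-style updates with tolerance
  $10^{-8}$ on the loss decrease and at most 10,000 iterations; the update
  is monotone, so non-convergence is flagged rather than fatal.
- **Learning rate.** The loss enters the exponent unscaled (rate 1);
  `gb_config(learning_rate=)` exists for research use only.
- **Diagnostics.** Split-$\hat R$ and an FFT/initial-positive-sequence ESS
  per CSMF component; $\hat R > 1.05$ warns but does not fail, since short
  exploratory chains are legitimate.

**Uncalibrated model.** With $M$ fixed at the identity the survey loss is
$-\sum_k y_k\cdot\log p$, so the generalized posterior is conjugate:
Dirichlet$(\alpha + \sum_k y_k)$ — aggregate scores act as pseudo-counts.
`uncalibrated_posterior()` draws from this closed form directly; the MCMC
path with `fix_m` is kept and tested against it.

**WAIC.** The pointwise log predictive density is taken to be the *negative
of* each record's loss contribution (the loss is already a negative-log
quantity; a literal $-\log(\text{loss})$ would be dimensionally incoherent).
The pointwise unit is one death record, the finest partition available.
The uncalibrated comparison is evaluated on the same observations as the
calibrated fit: survey records through the drawn $q$, and paired records
through the identity matrix — the no-misclassification model's only reading
of them. This combined evaluation is what makes the comparison informative:
on survey records alone both models can match the survey margin equally
well, and the misfit of the identity model shows up in the paired term.

## Preprocessing rules

Grouping of fine causes into the analysis vocabulary (7 child causes, 5
neonate causes) is applied before everything else, by summation within
groups — the only mass-preserving choice. The complete fine-cause map is
site- and study-specific, so it is user-supplied configuration on
`cause_list()`. Survey records with an inconclusive (typically EAVA) result
are imputed with the mean conclusive composition, *after* grouping; paired
inconclusive records get the row of the single-cause misclassification
matrix (conclusive records only, one-hot underlying-cause encoding) indexed
by their underlying cause, in a single pass with no iteration. Site
exclusion (e.g. the 274 South Africa neonates) precedes estimation.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the child-stratum study conditions: 426
paired and 1,841 survey deaths, distinct calibration and survey CSMFs
(the method assumes transportable misclassification rates, not
transportable CSMFs), an underlying-to-immediate kernel with 70% diagonal
mass, one Dirichlet-output algorithm and one 0.75/0.25 two-spike rank
algorithm with an 18% inconclusive rate (the reported loss of data to
inconclusive EAVA results is roughly 15–20%). Where the studies report no
value we fixed one realistic choice: Dirichlet concentration 8 for the
probabilistic algorithm (individual-level score dispersion is never
reported; 8 gives visibly noisy but informative scores), and
cause-independent inconclusiveness.

Two honest caveats. First, the two-draw rank mechanism ("first cause from
the $M$ row, second from the renormalized remainder") is *not*
mean-preserving: its population average-score matrix is the induced matrix
returned by `rank_effective_M()`, not $M$ itself. Consistency checks for
rank output target that induced matrix; downstream calibration is
unaffected because the regression estimates $E[y \mid x]$, whatever
generated it. Second, the generator draws a single latent cause per death
from $x$ and conditionally independent VA output per algorithm; real VA
algorithms share the questionnaire and are correlated, real
inconclusiveness is cause-dependent, and real MITS panels are imperfect.
Passing recovery tests therefore demonstrate internal consistency of the
method under its own assumptions, not field validity.

## Problem sizes used in the checks

The recovery study runs 100 replicates at $C = 3$, 500 paired and 2,000
survey deaths, diagonal 0.7 misclassification, one chain of 1,500
iterations (750 burn-in) per replicate — large enough that the posterior
mean's Monte-Carlo average error per cause sits well under 0.05 and
interval coverage is measurable, small enough to run on one CPU in about a
minute. Coverage is summarised as per-cause coverage averaged over causes;
requiring *joint* coverage of all three 95% intervals would test a ~86%
event against an 85% bound and be uninformative. The WAIC comparison uses
400 paired / 1,200 survey deaths with diagonal 0.55 misclassification.
Larger runs only sharpen the same comparisons.

## Limitations

- Up to two reference causes per death are representable; longer causal
  chains are truncated by the $\{1, 0.5, 0\}$ encoding itself.
- Calibration acts on the population CSMF only; no individual death is
  reassigned a cause.
- A cause absent from the paired data has no estimable misclassification
  row, and the package treats it as an error rather than silently assuming
  a uniform row.
- Near-singular fitted $M$ (similar rows) inflates posterior uncertainty in
  $p$ honestly but sharply; wide intervals in that regime are a feature of
  the method, not of the implementation.
- The published headline calibrated CSMFs cannot be reproduced from the
  packaged summary tables alone: they require the individual-level paired
  VA–MITS records, which are not public. The packaged fixtures support the
  table arithmetic and the degraded fixtures-only pipeline mode; all
  statistical guarantees are exercised on synthetic data.
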