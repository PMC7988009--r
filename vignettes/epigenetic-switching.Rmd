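---
title: "Heritable epigenetic switching of digital NF-κB responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritable epigenetic switching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episwitch)
```

# The scientific setting

In epithelial monolayers, stimulation of TLR2 by bacterial lipopeptides
activates NF-κB in an all-or-nothing fashion: a capped minority of cells
respond fully, the rest not at all. Responder status is stable over multiple
cell generations, responders cluster spatially because lineages expand in
place, and the underlying licence is carried by the methylation state of the
TLR2 promoter, which is itself bimodal at the single-read level ("en bloc"
methylated or unmethylated). `episwitch` implements the statistical models
for each of these observations. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

# The switching model on lineage trees

## Model

Each cell carries a hidden binary state $s \in \{N, R\}$. At division both
daughters inherit the mother's state, then each independently switches with
per-generation probability $p_{on}$ ($N \to R$) or $p_{off}$ ($R \to N$).
This is a two-state Markov chain down every root-to-leaf path of the
division tree; the transition matrix, stationary fraction
$f_{ss} = p_{on}/(p_{on}+p_{off})$, and relaxation
$f(g) = f_{ss} + (f_0-f_{ss})\lambda^g$ with $\lambda = 1-p_{on}-p_{off}$
follow in closed form (`transition_matrix()`, `stationary_fraction()`,
`predict_fraction_decay()`; the closed form is verified against
generation-by-generation matrix iteration in the tests).

*Switch placement.* The per-generation switch could be drawn once per mother
or once per daughter; we draw one Bernoulli per daughter per division, the
simplest generative reading of "probability of switch per generation", and
the same convention the likelihood assumes. Under this convention sister
cells are conditionally independent given the mother.

## Likelihood and fitting

Phenotypes are observed only on cells present at the end of the experiment;
cells that died or migrated out of the field of view are *censored*. The
marginal likelihood of the observed leaf states is computed by the standard
post-order pruning recursion over the two hidden states. Censored leaves get
partial likelihood 1 in both states: they are marginalized out while their
position preserves the topology (dropping them together with their siblings
would discard real division events). Partial likelihoods are renormalized at
every level with the log-scale accumulated per tree, so deep forests cannot
underflow.

`fit_switching()` maximizes the summed log-likelihood on the logit scale
(probabilities bounded to $[10^{-8}, 1-10^{-8}]$ *during optimization
only*), with Nelder–Mead multi-start: a parsimony-informed start (directional
Fitch change counts over directional edge exposures) plus a fixed grid, six
starts by default, convergence tolerance $10^{-10}$ in relative
log-likelihood, followed by a polishing run. Estimates within $10^{-6}$ of 0
or 1 are flagged `boundary`, not silently clipped.

The founder-state distribution is a modelling choice exposed as
`root_dist`: `"free"` (default; the initial responder fraction is a third
fitted parameter), `"stationary"` (tied to $f_{ss}$, appropriate when the
population is known to be at steady state), or `"fixed"`. A free root is the
safe default for real tracking data, where the culture's history is unknown.

## Confidence intervals

Profile likelihood is the default: for each rate, the other parameters are
re-optimized (warm-started) on a grid of fixed values, and the 95% bound is
where the profile drops by $\chi^2_{1,0.95}/2 = 1.92$; the crossing is
bracketed by doubling steps and then bisected on the logit scale (tolerance
$10^{-3}$ in logit units, i.e. $\sim 10^{-5}$ near $p = 0.01$). Bisection
reuses the established bracket rather than re-evaluating its endpoints,
because the warm-started inner optimization can jitter a marginal endpoint.
A percentile bootstrap over lineages (default 1000 resamples) is available
as `ci = "bootstrap"`; CIs are per-parameter, not joint.

We chose maximum likelihood with profile CIs because it is the exact,
assumption-minimal treatment of censored tree data; a bootstrap is provided
since tree-level resampling is the natural alternative when lineages are
heterogeneous.

## Parsimony and relatedness

`fitch_parsimony()` is two-state Fitch small parsimony: censored leaves
enter with state set $\{N, R\}$ and never force a change. The count equals
the exhaustive minimum (verified by brute force over all hidden labelings in
the tests). Ties at the root are reported as `"N/R"` (non-responder listed
first) and resolved to N for propagation, so output is deterministic.
`relatedness_concordance()` classifies observed leaf pairs by divisions from
the focal cell to the most recent common ancestor (1 = sister, 2 = cousin,
≥3 = extended) and reports $P(\text{relative } R \mid \text{cell } R)$;
responder–responder pairs count once in each direction, matching the
conditional definition.

## Study-scale precision of the rate estimates

At the scale of one 60-h tracking experiment — 58 lineages spanning up to
five generations, ~273 divisions, which the generator reproduces with
`division_prob = 0.642` and `death_prob = 0.05` per generation (chosen so
the expected division count is 273/58 ≈ 4.7 per lineage) — the acceptance
suite measures a median 95% profile-CI half-width for $p_{on}$ of ~0.010,
with coverage of the true rate between 90% and 99% over 100 replicates.
That is, calibrated 95% intervals at this information content are about
twice as wide as ±0.005 (and ~0.010/1.96 ≈ 0.005 is the corresponding
standard error). This is a genuine property of the data size, not of the
optimizer; analyses quoting tighter intervals at this scale are implicitly
reporting ~1 SE.

# Trace featurization and responder calling

Traces are nuclear/cytoplasmic p65 median-intensity ratios and a
destabilized-reporter intensity on 5-min frames. Conventions, in order of
application:

* **QC** (`qc_filter()`): cells whose initial total p65 (first frame,
  nuclear + cytoplasmic) falls outside the inclusive [25th, 99th] population
  percentile are rejected. Percentiles use the inverse-ECDF definition
  (`quantile` type 1) so the cut lands exactly on order statistics; a single
  cell is kept with a warning.
* **Baseline**: median ratio before stimulus addition.
* **Peaks**: local maxima with topographic prominence ≥ 10% of baseline by
  default. The detector is deliberately simple — plateau maxima and
  first/last samples are not peak candidates — because the pulse shapes of
  interest rise and fall well within a trace.
* **AUC steady**: trapezoid integral of $\max(\text{ratio} -
  \text{baseline}, 0)$ from the *first trough after the first peak* to the
  trace end. Starting at the trough (the end of the initial decline) makes
  the statistic ~0 for a clean single pulse and proportional to plateau
  height × duration for sustained activity; it is invariant to adding a
  constant to the whole trace.
* **Responder calls** (`classify_responders()`): a cell responds when its
  score (max post-stimulus ratio) *strictly* exceeds the media-control
  maximum; a control quantile (default 0.99) is available when controls are
  contaminated. Strict exceedance makes the boundary case a non-responder.
  Fractions get Wilson score intervals (no continuity correction).
* **Bimodality**: Sarle's coefficient $(s^2+1)/k$ with population moments on
  log scores (ratio histograms are displayed on a log axis); > 5/9 flags
  bimodality.
* **Dose regressions**: features are regressed on $\log_{10}$ concentration
  (doses span decades); constant features yield `NA` correlations, never 0.
* **Count comparison** (`compare_count_distributions()`): two count samples
  (e.g. per-cell mRNA spots) are binned into 10 shared equal-width bins on
  the pooled range (rightmost bin closed); bins whose smaller expected cell
  is < 5 merge into their right neighbour (last bin merges left); Pearson
  χ² with df = bins − 1. With well-populated groups all 10 bins survive and
  df = 9.

# Spatial clustering of responders

The statistic is the median, over responder cells, of each responder's
median Euclidean distance to its $k = 5$ nearest other responders. Ties at
the $k$-th distance are all included in the median, so the statistic is
deterministic; exactly duplicated coordinates are jittered by < 0.01 µm with
a seeded RNG. The null hypothesis scatters the *labels* uniformly over the
observed positions (count preserved), which keeps the monolayer geometry —
cell density gradients cannot masquerade as clustering. Re-drawing positions
uniformly would confound label clustering with density structure, so label
permutation is the default and only built-in null. The test is one-sided
toward clustering (small distances) with the add-one p-value
$(1 + \#\{\text{null} \le \text{obs}\})/(1 + n_{perm})$, which cannot reach
0 and is exact under exchangeability.

# Per-read promoter methylation

`read_methyl_calls()` parses nanopolish-style call tables: a call is M when
LLR > 1.5, U when LLR < −1.5, and missing otherwise; rows covering a group
of CpGs (the caller cannot resolve CpGs within 10 bp) assign one call to
every CpG in the group, with group positions recovered from the CG offsets
of the sequence context. Genomic starts are 0-based; TSS-relative
coordinates are $p - \text{tss}$ on the + strand and $\text{tss} - p$ on the
− strand, so upstream is negative. The analysis window −110..−60 is
inclusive at both ends. Duplicate read/site entries keep the most confident
call.

Per-read U counts over the window require ≥ 80% of in-window sites covered
(truncated reads otherwise bias counts downward); `classify_enbloc()`
tolerates 1 discordant site by default. The two-component binomial mixture
is fitted by EM — tolerance $10^{-8}$ on the log-likelihood, ≤ 500
iterations, 10 restarts (one quantile-informed, nine random, all seeded) —
with components ordered by increasing U probability; the fit is `bimodal`
when both weights ≥ 0.05 and the component probabilities differ by ≥ 0.5.
The EM log-likelihood is non-decreasing and the mixture always fits at least
as well as a single binomial (asserted in the tests). Bisulfite-derived
matrices enter through the same matrix format; only the nanopolish-style
parser is provided.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure each analysis assumes,
with defaults anchored to the biology:

* `simulate_lineages()` / `gen_monolayer_field()`: heritable switching at
  (0.01, 0.055) per generation, stationary initial fraction 0.154, optional
  censoring; daughters placed at the mother ± isotropic Gaussian displacement
  (20 µm, about one cell diameter) in a 1000-µm field, 12 h per simulated
  generation for day-scale growth.
* `gen_trace_set()`: responders show a 10-min rise to a pulse that decays
  with a 25-min time constant (pulsatile) or a slowly damped oscillation
  (period 90 min); non-responders are flat; frame-to-frame noise SD 0.03 on
  a baseline ratio of 1 (SD 0.05 across cells). The reporter is a leaky
  integrator of supra-threshold activity (production 12 units/frame above
  baseline + 0.5, decay 4%/frame ≈ 85-min half-life), mimicking a
  destabilized PEST reporter; exact constants are free parameters since no
  reporter kinetics are uniquely identified by the data the package
  consumes.
* `gen_methyl_reads()`: 8 CpGs in −110..−60; per-read latent state U with
  the mixture weight; per-site call error 5%, optional missingness and
  10-bp grouped calls.
* `gen_dose_response()`: Hill response probability capped at
  $f_{max} = f_{ss}$ by default.

What the generators do *not* emulate: segmentation/tracking errors,
intensity bleaching and drift, cell-cycle-length heterogeneity (generations
are synchronous), mechanical crowding (displacements are free Gaussians),
read-level sequence context effects, and any coupling between methylation
state and trace dynamics within a single simulated cell. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to real-data artifacts.

# Problem sizes and runtime choices

The test and acceptance workloads use sizes chosen to make sampling error
small relative to the asserted tolerances while keeping a laptop-scale run:
20 replicate fits of 500 five-generation lineages for rate recovery, 100
study-scale replicates for CI calibration, 500 label-shuffled fields
(199 permutations each) for test size and 100 lineage-grown fields for
power, 100 seeds × 500 reads for mixture recovery, and 100 seeds × 400
cells for end-to-end responder-fraction coverage.

# Known limitations

* The switching model has no continuous-time component: switching is tied to
  division, and generation times are implicit. Converting generations to
  days uses a configurable constant (default 24 h).
* Likelihood and parsimony assume binary division; higher-order fission or
  cell fusion are rejected by the tree validator.
* The spatial test conditions on the observed positions; it has no model of
  density, so it cannot attribute clustering to lineage vs. niche effects —
  it only measures label clustering.
* The methylation mixture treats sites as exchangeable within a read;
  position-specific methylation rates within the window are not modelled.
* Per-parameter profile CIs do not account for the (mild) correlation
  between $p_{on}$ and $p_{off}$ estimates.
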