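---
title: "Subtype and stage inference for progressive regional atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference for progressive regional atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustainr)
```

## The problem

Cross-sectional morphometry of people with a chronic brain disorder — here,
regional cortical thickness and subcortical volumes in epilepsy — mixes
individuals at very different points of their disease course and,
plausibly, on different courses altogether. Subtype and Stage Inference
(SuStaIn) resolves both axes at once: it infers a small number of
*progression subtypes*, each an ordered sequence of regional atrophy
events, and places every individual at a *stage* along each subtype's
sequence, all from a single scan per person.

`sustainr` implements the z-score flavour of this model end to end:
control-referenced adjustment and z-scoring of 40 regional measures
(28 cortical-thickness and 12 subcortical-volume regions of interest),
the piecewise-linear z-score event model, greedy multi-start sequence
optimization with EM over subtype mixtures, Metropolis MCMC for ordering
uncertainty, cross-validated selection of the number of subtypes,
per-subject subtyping/staging, and the clinical association statistics
used to interpret the result. A synthetic-cohort generator with full
ground-truth provenance makes every stage testable without patient data.

## The model

Let $x_{ij}$ be the sign-flipped z-score of region $i$ in subject $j$
(positive = more atrophy; see below). Each region carries a set of
*events*: crossings of the fixed thresholds $z \in \{1, 2, 3\}$, the
boundaries of the mild ($1\le z<2$), moderate ($2\le z<3$) and severe
($z\ge 3$) bands used to render results. With $R$ regions there are
$E = 3R$ events; a subtype is a permutation $S$ of all $E$ events in which
each region crosses its thresholds in increasing order.

Region $i$'s expected trajectory over discrete stages $t = 0..E$ is the
piecewise-linear interpolation through
$(0, 0), (\mathrm{pos}(z_{i,1}), z_{i,1}), \ldots, (E, z_{\max})$, where
$\mathrm{pos}(e)$ is the event's position in $S$ and $z_{\max} = 5$ is the
terminal plateau. Measurement noise is Gaussian with shared SD
$\sigma = 1$ (the natural unit of control-referenced z-scores), so a
subject at stage $k$ has likelihood
$L_j(k) = \prod_i \mathcal{N}(x_{ij};\, g_i(k), \sigma)$. Stages carry a
uniform prior; a dataset with subtypes $S_c$ in proportions $f_c$ has

$$\log \mathcal{L} = \sum_j \log \sum_c f_c\, \frac{1}{E+1} \sum_{k=0}^{E} L_j(k \mid S_c).$$

All likelihood sums are computed in log space.

### Z-scoring against controls

Each raw measure is adjusted in the control group with a conjugate
Bayesian linear regression on total intracranial volume, sex, age and
age² (vague Normal–inverse-gamma prior, precision $10^{-6} I$, so the
posterior mean is ridge-regularized least squares), separately per
scanner stratum; subjects are z-scored with their own stratum's residual
mean and SD, and the z-score is multiplied by $-1$ exactly once so that
atrophy (thinner cortex, smaller volume) is positive. Fitting controls
therefore come out with per-region mean 0 and SD 1 by construction, which
the acceptance suite audits at $10^{-6}$.

Two free choices here were genuinely open and are pinned as follows:
age is centred at the stratum control mean before squaring (conditioning
only; predictions are unchanged), and TIV enters the model for all
regions, thickness included (it can be disabled with
`run_config(include_tiv = FALSE)`). Where the source methods describe
both a per-ROI residualization for age/sex and a combined four-predictor
Bayesian model, the more specific combined model is implemented.

For lateralized focal disease, `regroup_ipsi_contra()` relabels
left/right columns as ipsilateral/contralateral relative to the seizure
focus, keeping only subjects with a proven left or right focus.

### Fitting

`fit_sustain()` grows the model hierarchically. $C=1$ is multi-start
greedy coordinate ascent (default 25 starts): from a uniformly random
valid ordering, each event is repeatedly relocated to its best feasible
position until no single move improves the log-likelihood. For $C>1$,
each existing cluster is split by random bipartition (several tries, each
refined with a short EM), the best split is refined by full EM
alternating responsibility-weighted fraction updates with per-cluster
weighted sequence re-optimization, until the improvement falls below
$10^{-6}$ or 100 rounds. Two guards interrupt plain EM, both re-seeding a
cluster's sequence from the worst-fit subjects: an empty cluster, and a
cluster whose sequence has collapsed onto another's. The latter matters:
with one mixed cluster, both halves of a random bipartition usually
optimize to the majority ordering, a symmetric fixed point that plain EM
cannot leave. Because the best state seen is returned, re-seeding never
worsens the reported fit, and EM ascent is otherwise monotone (tested at
$10^{-9}$).

`mcmc_sample()` quantifies ordering uncertainty with a Metropolis chain
(production default $10^6$ iterations, 10% burn-in, no thinning): each
iteration relocates one uniformly chosen event of one uniformly chosen
subtype to a uniformly chosen valid position, then jointly perturbs the
fractions with a Dirichlet proposal centred at the current value
(concentration $100 f + 1$); both moves accept with
$\min(1, e^{\Delta \log \mathcal{L}})$ under flat priors. The relocation
proposal is not exactly symmetric (feasible-position counts can differ
between states); the plain Metropolis rule is retained deliberately as the
pinned algorithm — on every grid small enough to enumerate, the chain's
mode matches the exhaustive argmax, which is what the model uses it for.
Positional-variance diagrams (PVDs) — the fraction of retained samples
placing each event at each position — are accumulated over all retained
samples. Fraction sampling can be frozen with
`run_config(sample_fractions = FALSE)`.

### Choosing the number of subtypes

`crossval()` runs seeded k-fold cross-validation (production default 10
folds, up to 4 subtypes) and scores each $C$ by held-out deviance,
$\mathrm{CIC}(C) = -2\sum_{\text{folds}} \log\mathcal{L}_{\text{test}}$.
The cited information criterion has no published formula; held-out
deviance is the minimal faithful reading and is fully testable. The
smaller $C$ is preferred whenever its CIC lies within 6 of the minimum
(the conventional "strong evidence" deviance margin; configurable).
Fold-to-reference stability is summarized by `cv_similarity()`: fold
subtypes are matched to the reference by the permutation maximizing total
PVD overlap, and a matched pair's similarity is the mean over events of
the summed element-wise minimum of their position distributions — 1 for
identical orderings, 0 for disjoint ones. The source quantity is defined
only by its [0, 1] range; this overlap metric is pinned here.

### Subtyping and staging individuals

`subject_posteriors()` gives each subject membership probabilities
$p(c \mid x_j) \propto f_c e^{\ell_j(S_c)}$ and the *weighted stage*
$w_j = \sum_c p(c \mid x_j) \sum_k k\, p(k \mid x_j, c)$. A subject is
assigned to a subtype only when its maximum membership strictly exceeds
the cut-off (default $>0.5$); a subject whose posterior stage mass sits
at baseline ($w_j < 0.5$) is flagged stage-zero and left unassigned.
An exact 0.5/0.5 tie is unclassified by the strict inequality.

## The synthetic world

`simulate_cohort()` draws patients from exactly the generative model the
fitter assumes: $K$ valid sequences (uniform over valid orderings unless
supplied), subtype fractions, integer stages (uniform on $0..E$ by
default; a point mass and a beta option model cohorts enriched for early
or late disease), and Gaussian noise $\sigma_{\mathrm{gen}}$ around the
trajectory. Raw units are produced by inverting a known control model at
plausible scales (thickness ~2–4 mm, subcortical volumes ~10³–10⁴ mm³;
config constants, not claims), so the full adjust→fit path is exercised;
controls are drawn at $z^* \sim \mathcal{N}(0,1)$, defining the reference
distribution. `simulate_clinical()` encodes the associations the
analysis stage should re-detect: duration rises with true stage
(slope 1, SD 5 years — Table-1-scale durations), prior-year convulsions
follow a designated-subtype log-odds shift (defaults $b_0 = -0.7$,
$b_1 = 2$, i.e. roughly 33% vs 83% rates), seizure frequency is a
proportional-odds ordinal shifted by subtype, and ASM count is Poisson in
frequency. Every dataset ships its `synthetic_truth` and regenerates
bit-identically from (config, seed).

What the generator does *not* emulate — and hence what a green test does
not establish — includes: site/scanner effects beyond a label, non-
Gaussian or spatially correlated measurement error, regional differences
in noise, longitudinal dynamics, attrition, and any realistic dependence
between demographics and disease. Recovery results on synthetic cohorts
bound what the pipeline can do when its assumptions hold; they say
nothing about violations.

## Numerical and design notes

- **Plateau anchor**: if a region's last threshold event sits at position
  $E$, the $(E, z_{\max})$ anchor would duplicate the abscissa; the
  threshold anchor is kept and the plateau anchor dropped.
- **$z_{\max} = 5$**: never printed in the source; chosen above the
  severest (">3") band, configurable, and echoed in logs.
- **Ties**: assignment ties above the cut-off resolve to the lowest
  subtype index; exact equality at the cut-off is unclassified.
- **Determinism**: one seeded R RNG threads through start points, splits,
  folds and the MCMC chain (the C++ core draws from R's RNG), so any
  stage re-run under an identical (config, seed) is byte-identical.
- **Configuration files**: a minimal flat `key = value` TOML subset is
  parsed natively (strings, numbers, booleans, numeric arrays, comments);
  no TOML dependency exists in the supported R stack.
- **Memory**: PVDs are accumulated inside the chain, so
  `store_samples = FALSE` runs million-iteration chains in O(E²) memory.
- **Missing data**: incomplete ROI rows are dropped (with a logged count)
  before fitting — never imputed; missing clinical values propagate as
  missing into the association stage.

### A note on similarity under unidentifiable data

The PVD-overlap similarity rewards *agreement of position
distributions*, not confidence. On data with no staging information
(e.g. every subject at baseline) the chain accepts nearly every move and
each fold's PVD smears toward the uniform distribution — the correct
flat-landscape behaviour, verified by a property test. Two near-uniform
PVDs overlap almost completely, so cross-fold "similarity" on
unidentifiable data is *high* at mixing-length chains, and higher the
longer the chain. Similarity should therefore be read jointly with the
PVDs themselves (concentrated rows = a genuinely stable ordering); a
high similarity over flat PVDs signals an unidentified model, not a
replicated one.

## Known limitations

- Subjects are staged on the discrete grid $0..E$; the weighted stage is
  fractional only through posterior averaging.
- No site-harmonization beyond stratified z-scoring.
- The binary-abnormality ("event-based") model variant is out of scope;
  only the z-score flavour is implemented.
- Held-out deviance and the PVD-overlap similarity are this package's
  pinned operationalizations of quantities whose source descriptions are
  informal; both are documented and tested as defined here.
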