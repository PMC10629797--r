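# sustainr

Subtype and Stage Inference (SuStaIn, z-score flavour) for progressive
regional brain atrophy, implemented end to end in R.

## Who this is for

Researchers with **cross-sectional** regional morphometry — cortical
thickness and subcortical volumes for patients and healthy controls — who
want to know (i) whether their cohort contains distinct *spatiotemporal
progression subtypes* of grey-matter atrophy, (ii) how certain the
inferred orderings are, and (iii) where each individual sits along their
subtype's course. The package was built around the epilepsy use case
(40 bilateral Desikan-Killiany-derived regions: 28 cortical, 12
mesiotemporal/subcortical; optional ipsilateral/contralateral regrouping
by seizure-focus laterality) but runs on any region set.

## The model

Regional measures are adjusted in controls with a Bayesian linear
regression on TIV, sex, age and age² (per scanner stratum), z-scored
against the control residual distribution, and sign-flipped so larger
z means more atrophy. Each region crosses fixed z thresholds
(default 1, 2, 3 — the mild/moderate/severe band boundaries); a subtype
is an ordering S of all E events, and region i's expected value at stage
t is piecewise-linear through (0, 0), (pos(z₁), z₁), …, (E, z_max).
With shared Gaussian noise σ = 1 and a uniform stage prior, the data
log-likelihood of subtypes {S_c} with mixing fractions {f_c} is

    log L = Σ_j log Σ_c f_c · (1/(E+1)) Σ_k Π_i N(x_ij; g_i(k|S_c), σ)

Sequences are fitted by multi-start greedy relocation plus EM over the
mixture; ordering uncertainty comes from a Metropolis chain over event
permutations (positional-variance diagrams); the number of subtypes is
chosen by cross-validated held-out deviance (CIC) with a parsimony
margin; subjects get membership probabilities, a probability-weighted
stage, and an assignment when membership exceeds 0.5. Details and all
numerical conventions: `vignettes/subtype-stage-inference.Rmd`.

## Worked example

A synthetic 2-subtype cohort (300 patients, 120 controls, fractions
0.6/0.4, one z-threshold per region, σ_gen = 1), taken through the whole
pipeline:

```r
library(sustainr)

sim  <- simulate_cohort(n_patients = 300, n_controls = 120, K = 2,
                        fractions = c(0.6, 0.4), z_events = 1,
                        sigma_gen = 1, seed = 7)
clin <- simulate_clinical(sim$truth, seed = 8)

cm <- fit_control_model(sim$roi[sim$roi$group == "control", ])
z  <- compute_zscores(sim$roi[sim$roi$group == "patient", ], cm)

grid  <- event_grid(colnames(z$z), z_events = 1, z_max = 5)
cfg   <- run_config(n_startpoints = 10, n_mcmc_iter = 20000)
set.seed(9)
model <- fit_sustain(z, grid, 2, cfg)
model <- mcmc_sample(z, model, config = cfg)
model
#> sustain_model: 2 subtype(s), E = 40 events, loglik = -18570.584
#> fractions: 0.555 0.445
#> MCMC: 18000 retained samples, acceptance 0.063
```

The fitted fractions (0.555/0.445) recover the generating 0.6/0.4 split.
Per-subject output: membership probabilities, weighted stage (0–40 here),
and the assignment under the strict >50% rule:

```r
head(post <- subject_posteriors(z, model), 3)
#>   subject_id prob_subtype1 prob_subtype2 weighted_stage assigned_subtype
#> 1      S0001  2.775012e-11     1.0000000      22.309200                2
#> 2      S0002  7.668327e-01     0.2331673       2.614884                1
#> 3      S0003  8.231835e-01     0.1768165       2.701989                1
```

S0001 is far along subtype 2's course (weighted stage 22 of 40);
S0002/S0003 are early. Because the clinical generator ties duration to
true stage, the association stage re-detects it:

```r
rep <- characterize_subtypes(post, clin, reps = 1000, seed = 10)
rep$stage_cor$duration[c("rho", "p", "ci")]
#> $rho [1] 0.8669245
#> $p   [1] 4.116224e-92
#> $ci  [1] 0.8354407 0.8922075
```

a bootstrap Spearman correlation of weighted stage with disease duration
(ρ = 0.87, 95% CI 0.84–0.89). `export_results()` writes the
positional-variance diagrams, sequences, per-subject posteriors and
severity-band tables as deterministic TSVs; `crossval()` +
`select_n_subtypes()` choose the number of subtypes;
`cv_similarity()` reports fold stability. A minimal CLI wraps the same
stages: `Rscript -e 'sustainr::sustain_cli()' simulate --out d --seed 1`.

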