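---
title: "Methods: modelling the stability of twin phenotypes across two waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the stability of twin phenotypes across two waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinstab)
```

# The scientific problem

Quantitative behavioural phenotypes — here modelled on adolescent psychotic
experiences and negative symptoms (paranoia, hallucinations, cognitive
disorganization, grandiosity, anhedonia, parent-rated negative symptoms) —
are moderately stable when measured twice some months apart. The classical
twin design decomposes both the variance at each wave and the *covariance
across waves* into additive genetic (A), shared-environmental (C) or
dominance (D), and nonshared-environmental (E) sources, by exploiting the
different genetic sharing of monozygotic (MZ) and dizygotic (DZ) co-twins.
If MZ correlations exceed DZ correlations, additive genetic influences are
implicated; DZ correlations above half the MZ value point to shared
environment; MZ correlations below one imply nonshared environment
(including measurement error); DZ below half MZ suggests dominance.

`twinstab` implements the full analysis chain: a seeded synthetic cohort
generator with known ground truth, preprocessing to analysis-ready
standardized residuals, constrained saturated models for phenotypic and
twin intraclass correlations, bivariate Cholesky ACE/ADE decompositions
with sex-limitation variants fitted by full-information maximum likelihood
(FIML), and a persistence-subgroup analysis with contingency and
effect-size statistics.

# The bivariate Cholesky model

Each twin contributes a two-wave phenotype vector. Per person,

$$y = X a + Y c + Z e + \mu,$$

where $a, c, e \sim N(0, I_2)$ are latent bivariate factor scores and $X$,
$Y$, $Z$ are lower-triangular $2 \times 2$ path matrices
(`cholesky_params()`). The triangular parameterization guarantees positive
semi-definite component covariances $XX'$, $YY'$, $ZZ'$, and splits the
wave-2 variance into influences *carried over* from wave 1 (the off-diagonal
path, e.g. $x_{21}$) and influences *novel* to wave 2 ($x_{22}$).

Between co-twins, A factors correlate 1 (MZ), 0.5 (same-sex DZ) or
$0.5\,r_g$ (opposite-sex DZ, with $r_g \le 1$ allowing qualitatively
different genetic factors in the sexes); C is fully shared; D (in ADE
models, which replace C) is shared 1 (MZ) and 0.25 (DZ); E is unshared. The
implied $4 \times 4$ pair covariance is
$[[W_1, B], [B', W_2]]$ with $W = XX' + YY' + ZZ'$ and
$B = k_A X_1 X_2' + k_Y Y_1 Y_2'$ (`expected_pair_covariance()`). C and D
are never estimated together: with twin data alone an ACDE model is not
identified.

Standardizing by the implied wave variances (`standardize()`) gives the
familiar quantities: per-wave $a^2, c^2, e^2$; the standardized A/C/E
shares of the cross-wave covariance ("bivariate heritability" etc.); their
proportions of the phenotypic correlation; and, from the mathematically
equivalent correlated-factors solution, the aetiological correlations
$r_A = \mathrm{cov}_A / \sqrt{\mathrm{var}_{A1}\,\mathrm{var}_{A2}}$
(likewise $r_C$, $r_E$). The identity
$\text{biv}_A = r_A \sqrt{a^2_1 a^2_2}$ ties the two parameterizations
together and is verified in the test suite on random parameter draws.

# Estimation

**FIML.** Pairs with wave-2 data missing still inform the wave-1
parameters: each pair contributes the multivariate-normal log density on
its observed coordinates. Internally, pairs are grouped by missingness
pattern and the deviance is computed from per-pattern sufficient statistics
(count, mean, scatter) in compiled code, so the objective cost is
independent of sample size. On complete data this equals the closed-form
normal deviance; the tests check agreement with an independent direct
density-summation oracle to 1e-6.

**Optimization.** Models are fitted by minimizing the deviance over raw
path coefficients — unbounded, with variances entering as squares, so no
boundary constraints are needed. Eight starts by default: a moment-based
start (sample within-person covariance split across components) plus seeded
jitter; the best converged solution wins, with an objective tolerance of
1e-8. A non-positive-definite implied covariance returns a large finite
penalty growing with the most negative eigenvalue, steering the optimizer
back rather than aborting. Nested reductions are checked against their
parents: a reduction whose deviance undercuts its parent beyond 1e-4 is
flagged as an optimization failure.

**Fit indices and selection.** $-2\mathrm{LL}$, AIC
($-2\mathrm{LL} + 2k$) and BIC ($-2\mathrm{LL} + k \log n$) are reported,
with $n$ the number of pairs contributing any data — pairs, not twins, are
the independent units. Model selection uses lowest BIC, flagging a
difference of at least 10 as decisive.

**Sex limitation ladder.** In decreasing generality:
qualitative + quantitative (sex-specific path matrices plus free $r_g$,
kept in $[0,1]$ by a logistic transform — the alternative qualitative
parameterization through a sex-specific C correlation is not
simultaneously identified and is excluded); quantitative only ($r_g = 1$);
sex-specific component *variances* with aetiological correlations equated
across the sexes (`"common_correlations"` — our reading of a "no sex
differences on the aetiological correlations" submodel, parameterized
directly in correlated-factors form per sex); and no sex differences.
Wave means are always estimated freely (FIML with missingness shifts
observed means, so they are not fixed at zero despite standardization);
sex-specific means are optional.

**Profile-likelihood intervals.** Confidence intervals for standardized
quantities use penalized profiling: the quantity is pinned at a trial value
through a quadratic penalty ($w = 10^7$) while all other parameters are
re-optimized, and the endpoint is where the profiled deviance rises by
$\chi^2_1(0.95) = 3.84$. The step size is scaled from the local curvature
of the profile and the crossing refined by bisection to 5e-4. Endpoints
landing on a natural boundary (a proportion at 0 or 1) are reported at the
boundary. Coverage of the wave-1 heritability interval is verified by
simulation in the acceptance tests (200 replicates at 1,000 pairs per
group — a size chosen to make the study well-powered yet quick to repeat).

# Saturated models and assumption testing

The constrained saturated model estimates per-group means and full
$4 \times 4$ covariances subject to equality of means, variances and the
within-twin cross-time covariance across twin order and zygosity, leaving
cross-twin covariances free per group. Phenotypic and twin intraclass
correlations are computed from the constrained model-implied covariances —
not from Pearson correlations on double-entered data, which are provided
only as a cross-check (`double_entry_correlation()`). Sex-specific
phenotypic correlations come from a variant pooling means/variances by the
twin's sex; the whole-sample value from a reduced model pooling the sexes.

`assumption_tests()` fits the conventional equality ladder — means across
twin order, then zygosity; variances likewise; finally the cross-time
covariance equalities — comparing each step to the freer model by
likelihood-ratio $\chi^2$ and BIC difference. Variances are parameterized
on the log scale; covariances are free, with non-positive-definite
proposals penalized as above. Zero-variance input is refused.

# Persistence subgroups and contingency statistics

Individuals (one twin per pair, selected at random among pairs with
both-wave data, seeded) are classified from *untransformed* scores:
`persistent` = top decile at both waves, `low_scoring` = bottom 90% at
both, `decreasing`/`increasing` = top decile at exactly one wave. The
cutoff is the $\lceil n f \rceil$-th largest observed score and ties at the
cutoff count as top: discrete questionnaire scores produce ties, so the
realized top fraction can exceed the nominal 10% and is always reported.
This nearest-rank convention is deterministic, dialect-free, and on
distinct scores puts exactly $nf$ individuals in the top group. Group
membership is invariant to any strictly monotone transform of the scores.

Distress tables (group x three ordinal distress levels, among individuals
with a positive wave-1 score and distress data) are compared with Pearson
$\chi^2$, Cramer's V ($\sqrt{\chi^2 / (N (\min(r,c) - 1))}$) and a
Monte-Carlo Fisher exact test: 10,000 tables sampled from the
fixed-margins hypergeometric null by Patefield's algorithm (base R's
`r2dtable`), with $p = (1 + \#\{P(T) \le P(\text{obs})\}) / (B + 1)$,
seeded and reproducible. Group mean contrasts use Cohen's d pooled for
unequal group sizes, with large-sample normal CIs; since significance
markers for d are convention-dependent, the report labels intervals rather
than stars. Contrasts involving groups of fewer than two members are
skipped with a warning.

# The synthetic cohort generator

Because the motivating twin-registry data are access-controlled, the
generator is a first-class module with known ground truth. Its defaults
describe the emulated study conditions: 4,870 pairs at wave 1 (MZM 750,
MZF 1,000, DZM 700, DZF 950, DZOS 1,470 — about 36% MZ and 55% female),
ages 16.32 (SD 0.68) years with a 0.75-year gap, pair-level wave-2
retention 0.30 (~1,460 complete pairs), and per-subscale Cholesky truths
with heritabilities 0.22–0.47, shared environment up to 0.38 (absent for
anhedonia, which is AE), and cross-wave phenotypic correlations near 0.6.

Latent factors are standard normal and the path matrices carry all scale,
matching how standardized estimates are reported. Raw scores are produced
by a monotone exponential warp $s \mapsto \exp(\lambda s)$ (default
$\lambda = 0.8$), clamped and scaled to a fixed 0–50 range — the published
literature describes the score distributions only qualitatively
(positively skewed), so the warp is the simplest monotone mechanism that
*forces* the downstream log-transform decision; subscales flagged
non-skewed are mapped linearly. Distress levels are generated by
thresholding the wave-1 latent severity plus ordinal noise, which
reproduces a monotone distress-by-severity gradient without claiming a
mechanism; co-occurring psychopathology scores regress on the standardized
mean wave-1 latent phenotype with configurable loadings. Missingness is
pair-level and completely at random, mirroring a design in which whole
families are invited to the follow-up; a stratified invitation mechanism is
deliberately not modelled.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: item-level response processes, floor effects and
integer scoring, cross-subscale phenotypic correlations, attrition related
to severity, rater effects beyond a shared-environment loading, and age
heterogeneity effects on the phenotype (age enters only as a preprocessing
covariate).

# Preprocessing conventions

Skewness uses the adjusted Fisher–Pearson coefficient (the convention of
mainstream commercial statistics software), so the transform trigger is
reproducible: subscales with $|\mathrm{skew}| > 1$ at a given wave are
log-transformed as $\log_{10}(x + 1)$ — the offset accommodates zero
scores and the base is immaterial for standardized fits. The decision is
made independently per subscale and wave on the pooled individual-level
distribution. Scores are then regressed on age and sex (both twins and
sexes pooled, sex as a covariate) and residuals standardized; the
standardization uses all available individuals at each wave, since the
alternative (the longitudinal subsample only) is a smaller and arbitrarily
selected base. Preprocessing already-standardized residuals is a no-op up
to numerical tolerance. Untransformed scores are kept for descriptives and
the frequency-based persistence analyses.

# Problem sizes and runtime choices

The test suite exercises parameter recovery at 5,000 pairs per group,
moment recovery and covariance agreement at 10,000 pairs per group,
CI coverage over 200 replicates of 1,000 pairs per group, and BIC
selection over 100 replicates of 2,000 pairs per group — sizes at which
the relevant sampling error is a fraction of the tolerances being
asserted. The pipeline defaults to four optimizer starts per model;
increase `n_starts` for hard sex-limitation fits.

# Known limitations

Two waves only (no trivariate extension); continuous phenotypes only (no
liability-threshold models for ordinal data); no genotype-informed
heritability; no correction for multiple testing across subscales (matching
standard practice in this literature, where none is applied); the
qualitative sex-limitation model estimates a single DZOS genetic
correlation rather than sex-specific factor structures; and the Monte-Carlo
exact test compares table probabilities with a fixed relative tolerance of
1e-7 when deciding ties, which is adequate for the table sizes in scope.
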