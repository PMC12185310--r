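---
title: "Separating direct and indirect genetic effects in twin cohorts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct and indirect genetic effects in twin cohorts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindirect)
```

## The problem

A polygenic score (PGS) predicts a phenotype in a population sample for two
distinct reasons. Part of the association is the *direct* effect of a
person's own genotype on their own phenotype. The rest travels through the
family: parents transmit genotypes *and* shape rearing environments (genetic
nurture), mates resemble each other genetically (assortative mating), and
subpopulations differ jointly in allele frequencies and environments
(population stratification). These passive gene–environment correlations all
act *between* families: they make family members similar to each other in a
way that inflates the PGS–phenotype association without any causal path from
the child's own genotype.

Dizygotic (DZ) twin pairs separate the two sources. Co-twins share their
family environment, their parents' genotypes, their ancestry, and their birth
cohort exactly, but differ in the half of segregating variation that
Mendelian sampling assigns independently to each sib. A PGS difference
*within* a pair is therefore free of every between-family confounder, and
the within-pair regression coefficient estimates the direct genetic effect.

## The two regression models

For twin $i$ in pair $j$, with phenotype $y_{ij}$ and standardized score
$g_{ij}$, the package fits two ordinary-least-squares models on complete
cases:

$$y_{ij} = \alpha_0 + \beta\, g_{ij} + \mathbf{Z}_{ij}\gamma + \varepsilon_{ij}$$

$$y_{ij} = \alpha_0 + \beta_W\,(g_{ij} - \bar g_j) + \beta_B\, \bar g_j +
\mathbf{Z}_{ij}\gamma + \varepsilon_{ij}$$

where $\bar g_j$ is the pair-mean PGS, $\beta$ is the population-level
effect, $\beta_W$ the direct (within-family) effect and $\beta_B$ the
between-family effect. The **indirect genetic effect** is defined as
$\beta_B - \beta_W$: whatever the family-level score predicts beyond the
direct path. The default covariate set $\mathbf{Z}$ is age at the outcome's
wave, sex, age × sex, genotyping platform, and ten ancestry principal
components.

Two readings of "population estimate" are possible — the single-score
coefficient $\beta$, or $\beta_B$ from the within/between model. The package
computes the indirect effect
as $\beta_B - \beta_W$ and reports $\beta$ separately, so either convention
can be reproduced; the reported *share* of the total prediction is
$(\beta_B - \beta_W)/\beta$.

A useful closed form under the package's generator (parental PGS variance 1,
segregation variance $1/2$, no assortment): the pair-mean has variance
$3/4$ and covariance $3/4\,\beta_{direct} + \eta$ with the phenotype, where
$\eta$ is the per-parent nurture path. Hence
$\beta_B = \beta_{direct} + \tfrac{4}{3}\eta$ and the indirect effect equals
$\tfrac{4}{3}\eta$ — the factor the recovery tests assert, verified
independently by a brute-force Monte-Carlo oracle before it was frozen into
the suite.

### Scaling conventions

Outcomes are z-scored on the analysis sample after listwise deletion, so
coefficients read as correlations per SD of PGS. The PGS itself is z-scored
on the genotyped sample *before* the family scores are built: the pair mean
and deviation must come from the same scale for both twins even when one
twin's outcome row is later deleted. Continuous covariates are standardized;
binary ones enter as 0/1. Variance explained by the PGS is the incremental
$R^2$ over the covariate-only model on identical rows — the standard
PGS-prediction convention, monotone in the standardized coefficient.

### Bootstrap inference

All effect estimates get bias-corrected accelerated (BCa) bootstrap
intervals, default $B = 10{,}000$ replications. The resampling unit is the
**family**, never the person: person-level resampling would break apart the
within/between construction and understate the dependence between co-twins.
The bias term $z_0$ comes from the fraction of replicates below the point
estimate, the acceleration $a$ from a leave-one-family-out jackknife.

Implementation note: every OLS statistic factors exactly through per-family
cross-products ($X_j'X_j$, $X_j'y_j$), which are additive over families. A
family resample therefore maps to a weighted column sum, one small solve per
replicate, and the jackknife becomes a vectorized subtraction. This is what
makes interval calibration measurable by simulation (1,000 replicates of
$B = 1{,}000$ at 4,000 pairs) on one CPU. A generic slow path
(`bootstrap_bca_cohort`) accepts arbitrary cohort-level statistics;
standardization is treated as fixed preprocessing in the fast path and
re-done per replicate in the slow path, a difference far inside quantile
noise at these sizes. An effect is called "significant" when its 95%
interval excludes zero; no multiple-testing correction is applied, but the
study report carries the number of tests run so readers can apply their own.

## Univariate twin models

The variance of each phenotype is decomposed over MZ and DZ pairs by
full-information maximum likelihood: each pair contributes a bivariate
normal log-density with zygosity-specific expected covariance

* ACE: MZ covariance $a^2 + c^2$, DZ covariance $\tfrac12 a^2 + c^2$;
* ADE: MZ covariance $a^2 + d^2$, DZ covariance $\tfrac12 a^2 + \tfrac14 d^2$;

C and D are never fit together (not identified with twins alone). Pairs with
one missing phenotype contribute their univariate marginal, which is what
keeps FIML valid under MCAR/MAR missingness; covariates (age, sex, age × sex)
sit in the means model *inside* the likelihood rather than being residualized
first. The ACE-vs-ADE choice follows the twin correlations: ADE when
$r_{MZ} > 2 r_{DZ}$, ACE otherwise, with the boundary ($C = D = 0$) resolved
to ACE.

Components are parameterized as squared paths, so they are non-negative by
construction, and standardized by the total fitted (pre-interaction)
variance, summing to 1 by definition. The optimizer is quasi-Newton
(`nlminb`) with five jittered restarts and a $10^{-12}$ relative tolerance;
nested models are compared by likelihood ratio with both the naive
$\chi^2$ p-value and the 50:50 mixture p-value appropriate when a variance
component is tested on the boundary of its space.

### Sibling interaction (contrast effects)

Parent-rated hyperactivity shows *contrast* effects: raters judge each twin
against the co-twin, which reshapes the pair covariance. The package models
this with a single reciprocal path $s$: the observed pair vector is
$(I - sB)^{-1}$ times the latent one, with $B$ the co-twin swap matrix, so
the expected covariance becomes $(I - sB)^{-1}\Sigma_0 (I - sB)^{-\top}$ and
the means transform the same way. The *simulator uses the identical
transform*, so the generative and fitted definitions of $s$ cannot drift
apart. Whether such a term is reciprocal or asymmetric is a modelling
choice; the reciprocal (single-$s$) form is implemented, and an asymmetric
variant is noted as future work. One caveat the tests respect: under a
pure-E generator the transform changes MZ and DZ covariances identically, so
zygosity variances do *not* separate there; they separate as soon as MZ and
DZ latent covariances differ.

Component confidence intervals default to delta-method Wald intervals from
the observed information matrix (clamped to $[0,1]$), with a nonparametric
pair-level bootstrap as the alternative; the method used is recorded in the
fit. Full likelihood-profile intervals would need a constrained
re-optimization per component per cell and add little for a simulation
study, so they were left out deliberately.

## Common factors from item-level data

Cross-sectional questionnaire scores are noisy; stable trait variance — where
genetic signal concentrates — is better indexed by a common factor over all
items across waves and reporters. The package fits a one-factor model
$x = \mu + \lambda f + u$, $f \sim N(0,1)$, $u \sim N(0, \mathrm{diag}\,\theta)$,
by FIML over missing-data patterns. Identification fixes the factor variance
at 1 (not the first loading), which keeps scores on one scale across
common, by-reporter, and by-age views; the sign convention makes the first
loading positive. Factor scores are regression-method posterior means with
pattern-specific weights, so any person with at least one observed item gets
a score; under unit factor variance their variance is bounded by the
reliability $\lambda'\Sigma^{-1}\lambda$.

Numerical choices: uniquenesses are bounded below at $10^{-4}$ (Heywood
floor, warned when active); the optimizer starts from a principal-axis
solution of the pairwise-complete covariance and uses an analytic gradient
of the FIML objective. The one-factor structure admits Woodbury identities,
so each missing-data pattern costs $O(k^2)$ and all patterns are evaluated
in a handful of matrix operations — items are treated as continuous
(the ordinal nature of real questionnaire items is a stated simplification;
polychoric estimation is out of scope).

The same machinery builds the latent parenting factor from the family-level
parenting items; its scores feed the covariate-controlled reruns.

## The synthetic cohort generator

No individual-level twin data can ship with a package, so the generator *is*
the study population, built mechanism by mechanism:

| parameter | default | meaning |
|---|---|---|
| `beta_direct` | 0.12 | direct effect of own PGS (≈1.4% of variance) |
| `eta_nurture` | 0.02 | per-parent genetic-nurture path |
| `r_assortment` | 0.10 | spousal PGS correlation (one generation) |
| `var_a_residual` | 0.45 | additive genetic variance not tagged by the PGS |
| `var_c` | 0.15 | shared environment of the stable core |
| `var_e` | complement | non-shared; completes the core to unit variance |
| `var_specific` | 0.40 | occasion/reporter noise per measure |
| `s_contrast` | 0 | reciprocal sibling-interaction coefficient |
| `missing_rate` | 0.10 | MCAR probability per measure |
| `conf_ses_loading` | 0.25 | midparent-PGS loading on family SES |

Parental PGS pairs are bivariate normal with the spousal correlation;
children get midparent plus an independent segregation deviation of variance
$1/2$, shared by MZ co-twins. This yields DZ within-pair PGS correlation
$(1+r)/(2+r)$ — 0.5 without assortment, *above* 0.5 with it, which is
exactly the between-family inflation the estimator must detect. Assortment
is deliberately one-generational rather than iterated to mating equilibrium:
one generation suffices to create the inflation, and an equilibrium model
would add parameters nothing downstream estimates. The defaults were chosen
once as a plausible externalising-type phenotype — modest PGS prediction
(≈1.4% of variance), substantial heritability through the PGS-untagged
additive component, moderate shared environment — because the magnitudes of
nurture and assortment a real cohort carries are not known quantities;
presets here are illustrative study conditions, not calibrated estimates of
any particular sample.

The `var_a_residual` component deserves a note: a measured PGS is a weak
proxy of the full breeding value, so twin-model heritability (∼50%+)
coexists with ∼1–2% PGS-explained variance. This residual additive
component carries the MZ/DZ 1 vs ½ correlation structure but is independent
of the *parental* scores; its own nurture and assortment are not modelled,
which matters only if one wanted the twin C estimate itself to absorb
nurture — a refinement out of scope here.

Stratification assigns families to subpopulations with PGS and environment
offsets; the first ancestry PC carries the stratum signal, so conditioning
on PCs attenuates the induced indirect effect — the generator reproduces the
classic confounder and its standard fix. SES loads on the midparent PGS
(passive rGE through family resources), neighbourhood deprivation is an
ordinal decile of a latent negatively correlated with SES, and an optional
`beta_ses_pheno` path routes the entire indirect effect through SES for
mediation checks. Ground-truth columns are namespaced with a `sim_` prefix
so estimators cannot silently consume them, and every stage draws from its
own derived seed, so a cohort is byte-reproducible from its configuration
and individual stages remain reproducible when called standalone.

What the generator does *not* emulate: SNP-level genotypes and LD structure,
multi-generation assortment equilibria, informatively missing data (the
analysis uses listwise deletion, which is unbiased under the MCAR the
generator produces), ordinal item scales, and rater disagreement beyond a
reporter-specific variance component. Passing tests therefore certify the
estimators against these mechanisms, not against every pathology of real
questionnaire data.

## The orchestrated study

`run_study()` walks a phenotype × age × reporter grid: the polygenic
decomposition runs on the DZ subset only (the within/between construction
needs non-identical co-twins; an MZ-only input is a structural error), twin
models use MZ+DZ, and factor views add the stability outcomes. Wherever an
indirect-effect interval excludes zero, `conditional_controls()` re-runs the
decomposition with SES, deprivation, or the parenting factor appended,
reporting whether the controlled interval includes zero and the percentage
attenuation of the direct effect. `consistency_check()` tabulates the 2×2
agreement between "C significant in the twin model" and "indirect effect
significant in the PGS model" — the design's cross-validation of the idea
that genetic nurture should surface as shared environment. ADE cells, which
have no C, are counted separately rather than forced into the table.

Every cell derives its seed from the study seed, and report files contain no
timestamps, so a rerun with the same configuration is byte-identical — run
metadata carries seeds, replication counts and sample sizes instead.

## Problem sizes used by the checks

The test suite exercises the estimators at the sizes the properties need:
estimator-recovery means over 200 replicates of 20,000 DZ pairs across a
3 × 3 grid of direct × nurture effects; interval calibration over 1,000
null replicates at 4,000 pairs with $B = 1{,}000$; twin-model recovery at
5,000 pairs per zygosity (sibling interaction at 20,000); CFA recovery at
5,000 persons complete and under 20% MCAR. The acceptance script analyses a
7,000 DZ + 3,000 MZ cohort with $B = 5{,}000$ and appends a reduced
calibration run (200 replicates). Monte-Carlo checks with ±0.01-style
tolerances are asserted on means over replicates or seeds so they sit
several standard errors from their targets rather than one.

## Known limitations

* OLS with family-bootstrap inference, not mixed models: the within/between
  regressions are fixed-effect by design; analytic cluster-robust standard
  errors are not reported, the bootstrap carries the clustering.
* Delta-method component intervals can be poor near the 0/1 boundary of a
  variance component; the pair bootstrap is the fallback there.
* The indirect effect aggregates nurture, assortment, stratification and any
  other between-family confounding; the design cannot apportion it among
  mechanisms, only the controlled reruns hint at sources.
* Factor scores are treated as observed outcomes in the downstream
  regressions; score uncertainty is not propagated.
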