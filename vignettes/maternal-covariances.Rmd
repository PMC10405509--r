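---
title: "Maternal animal models with direct-maternal genetic and environmental covariances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal animal models with direct-maternal genetic and environmental covariances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

For a maternally influenced juvenile trait such as broiler body weight,
the phenotype of bird $i$ with dam $j$ decomposes as

$$ y_i = x_i'b + a_i + m_j + pe_j + e_i + \varepsilon_i, $$

where $a_i$ is the bird's own (direct) additive genetic effect, $m_j$
the dam's maternal additive genetic effect expressed in her offspring,
$pe_j$ her permanent environmental effect common to all her offspring,
and $e_i$ the environmental (residual) effect on the record itself.
Because the dam is herself an animal with a record, two covariances
arise between the direct and the maternal channel:

* $\sigma_{am} = \mathrm{Cov}(a_j, m_j)$, the **direct-maternal genetic
  covariance**: the dam's genes for her own growth are correlated with
  her genes for mothering;
* $\sigma_{e\,pe} = \mathrm{Cov}(e_j, pe_j)$, the **direct-maternal
  environmental covariance**: the environment the dam grew up in is
  correlated with the environment she provides.

Jointly, $(a, m) \sim N(0,\, G_0 \otimes A)$ with $A$ the numerator
relationship matrix, and per animal
$(e, pe) \sim N(0, E_0)$ independently across animals.

Standard evaluation software has no slot for $\sigma_{e\,pe}$, because
the residual is not an effect one can correlate with anything.  The
package therefore always fits the model in its *dummy-residual*
reparameterization: the residual $e$ is declared a proper random effect
with its own incidence matrix and estimable variance $\sigma^2_e$, free
to covary with $pe$, while a new least-squares residual
$\varepsilon \sim N(0, \sigma^2_{dummy} I)$ is fixed at a small constant
(default 1 g²).  Any constant below the true residual variance works;
the true residual variance of the trait is then
$\sigma^2_e + \sigma^2_{dummy}$ (`total_residual_variance()`).

Five nested structures are supported (`model_config()`): `moda` (no
maternal genetic effect, both covariances null), `modam` (adds $m$),
`coram` (frees $\sigma_{am}$), `corepe` (frees $\sigma_{e\,pe}$), and
`coramepe` (frees both).  In the two-trait form, female and male body
weight are distinct, genetically correlated traits recorded on
different birds; each dam carries one $pe$ per offspring sex, and only
the *female* residual can covary with the maternal environmental
effects — males never contribute maternal effects, so
$\sigma_{e_M pe_F}$, $\sigma_{e_M pe_M}$ and $\sigma_{e_F e_M}$ are
structural zeros, enforced as hard masks.

Derived summaries use
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_m + \sigma^2_{pe} +
\sigma^2_e + \sigma^2_{dummy})$; the phenotypic-variance denominator
excludes the covariance terms and includes the dummy variance.  The
convention is not uniquely determined by the published tables it was
checked against, but this choice reproduces their heritabilities to two
decimals (see `test-variance-model.R`), and with the default dummy of
1 g² the distinction is numerically irrelevant.

## Mixed-model equations

`blup()` builds Henderson's equations with the dummy variance as the
only least-squares residual.  The genetic precision block is
$G_0^{-1} \otimes A^{-1}$, with $A^{-1}$ assembled directly by
Henderson's rules; Mendelian sampling variances use Meuwissen-Luo
inbreeding coefficients by default (`use_inbreeding = FALSE` gives the
textbook non-inbred rules).  Environmental precision is block-diagonal
per individual: a dam with her own record owns a joint block over her
$(e, pe)$ components.

Two exact reductions keep the system small:

* an $e$ level that cannot covary with anything — every record when
  $\sigma_{e\,pe}$ is masked, and every non-dam record otherwise — is
  marginalized into a record-level residual of variance
  $\sigma^2_e + \sigma^2_{dummy}$; its BLUP is recovered analytically
  afterwards.  This is plain integration over a Gaussian, not an
  approximation, and the dense-oracle tests cover both representations;
* $pe$ levels exist only for dams actually linked to records, and $e$
  levels only for phenotyped animals; unlinked levels contribute
  nothing to the likelihood.

Fixed effects use treatment contrasts; remaining aliased columns (the
dam-age classes are partially confounded with hatch-within-round) are
detected by a rank check and dropped with a message.  Records with an
unknown dam keep their direct effect but are excluded from maternal
linkage (their maternal incidence row is zero), and the count is
reported.  The coefficient matrix is factorized by sparse (supernodal)
Cholesky; one symbolic analysis on the union sparsity pattern is reused
for every numeric update, and per-iteration assembly writes
coefficients straight into the factor's slots through a precomputed
index map.

## REML

`reml()` maximizes the restricted likelihood
$-2\ell = \log|C| + \log|\Sigma| + \log|R| + y'Py$ (the
$(n-p)\log 2\pi$ constant is omitted everywhere, consistently with the
dense oracle `dense_mixed_model_oracle()`).  Iterations are Newton
steps whose curvature is the exact average-information matrix,
$\mathrm{AI}_{ij} = \tfrac12 f_i' P f_j$ with
$f_i = \dot V_i P y$, computed through multi-right-hand-side solves of
the factorized equations; the score is a central finite difference of
$-2\ell$ (relative step $10^{-4}$).  Safeguards:

* proposals outside the positive-(semi)definite cone are *bent* per
  connected mask component (eigenvalues clipped at $10^{-8}$ of the
  largest), so structural zeros are never disturbed;
* the positivity constraints get a simple active-set treatment: a
  variance may lose at most 80% of its value per step (clamped per
  coordinate, so a boundary-bound component decays geometrically
  without throttling the others), and a variance that has reached
  numerical zero with an outward-pointing score is frozen — together
  with any covariance touching it — and the Newton system is solved on
  the active set, whose curvature is not poisoned by the near-singular
  component;
* step-halving enforces monotone descent up to the numerical noise
  floor of the evaluation (relative $10^{-9}$).

Convergence is declared when the predicted gain of the feasible Newton
step falls below the numerical resolution of the likelihood
evaluation, or when the maximum relative parameter change falls below
`tol_par` ($10^{-7}$) or the deviance decrease below `tol_ll`
($10^{-6}$) — the latter two deferred while a variance is still
decaying toward the boundary.  Starting values assign
30% of the fixed-effect-corrected phenotypic variance to $\sigma^2_a$,
10% each to $\sigma^2_m$ and $\sigma^2_{pe}$, 40% to $\sigma^2_e$, and
0 to all covariances; correcting for the fixed effects first matters,
since the sex effect and the genetic trend otherwise inflate the raw
variance severely.  Standard errors come from the inverse
average-information matrix at convergence.  A warning is issued when
the dummy variance is not small relative to the initial residual —
the device requires a constant below the true residual, and the
identifiability of $\sigma^2_e$ rests on the dummy being fixed.

`ai_step()` exposes one guarded Newton iteration.  `em_step()` is a
closed-form expectation-maximization update for single-trait models; it
needs exact conditional (co)variances of the random effects and obtains
them from a dense inverse of the coefficient matrix, so it is
restricted to small and medium systems and serves as a diagnostic and
cross-check rather than the production path.  When $\sigma_{e\,pe}$ is
free, individuals missing one of the two environmental components are
completed with their conditional moments — an exact missing-data EM on
an augmented model with the same likelihood.  At production scale the
fallback for a failed AI proposal is step-halving plus bending instead
of EM.

`lrt()` reports the naive likelihood-ratio test; when a variance sits
on the boundary under the nested model the chi-square reference is
conservative, and no boundary-mixture correction is applied (the
reference tables report plain LRT values).

## The breeding-program simulator

`sim_config()` defaults describe the full program the package targets:
40 selection rounds (SR) of 7800 phenotyped birds from 52 active sires
and 520 active dams under hierarchical mating (one sire serves 10 dams,
a dam one sire), 13 males and 130 females selected per round into a
pool in which a cohort serves 4 overlapping rounds, random selection
through SR 6 (building data for variance-component estimation), then
truncation selection on single-trait `moda` pedigree-BLUP breeding
values whose variance components are estimated once, after the random
phase.  Offspring arrive in 6 hatches per round; the per-dam-per-hatch
expectation declines linearly with dam age from 2.49 to 2.15 and is
integerized by seeded largest remainder so every round totals exactly
`offspring_per_sr`.  Phenotypes follow the infinitesimal model with
Mendelian sampling variances reduced by parental inbreeding; the
residual part is drawn jointly with $pe$ at the configured
$\sigma_{e\,pe}$, and an independent unit-variance dummy noise is added
so that estimation with the dummy fixed at 1 targets exactly the
configured components.

Details the source program does not publish were fixed once as
configuration defaults: a 4-round parent service life (which reconciles
"52 sires and 520 dams" with "13 males and 130 females selected"),
6 hatches per round, hatch-within-round effects drawn with SD equal to
10% of the phenotypic SD, a +207 g male effect, and a -2 g per weekly
dam-age class slope.  All are `sim_config()` arguments.  Dam-age
classes are weekly (`(age_in_rounds - 1) * hatches + hatch`), which
makes them partially confounded with hatch-within-round — as in real
layouts — and the evaluation handles the aliasing by constraint.

What the generator does *not* emulate: heterogeneous residual variance
across rounds, mortality and fertility variation, non-additive genetic
effects, and drift in fixed effects over time.  Passing tests therefore
certify the estimation machinery under the stated generative model, not
robustness to those features of real data.

## Cross-validation

`crossvalidate()` follows the study design: variance components always
come from the full data; *forward prediction* masks all phenotypes of
the last five rounds and predicts their breeding values from earlier
relatives (`EBV_reduced`), to be compared with the true breeding
values, the phenotypes corrected for the full-data fixed effects
($y_c$), and the full-data `EBV_full` (the Legarra-Reverter
correlation).  *Half-sib prediction* splits every paternal half-sib
group in the validation window in two (the odd animal trains), masks
one half, and correlates a masked bird's $y_c$ with the predicted
breeding value of a randomly paired masked half-sib from a different
dam — pairs never share a dam, because full sibs share the very
maternal effects the test must exclude; 50 independent pairings are
averaged.  Before any correlation or slope, both variables are
corrected for the genetic trend by subtracting within-round means —
the standard construction of (co)variances conditional on a group
factor.  Inflation is the slope of the response on `EBV_reduced`;
1 is ideal, below 1 means over-dispersed predictions.

## Problem sizes used by the tests and the acceptance script

The shipped acceptance study runs 10 replicates of a reduced-scale
program: 20 rounds of 2400 birds (4 males + 40 females selected per
round, 16 active sires and 160 active dams), preserving the full
program's family structure (10 dams per sire, ~15 offspring per dam),
selection fractions, overlapping service life, random startup phase and
last-5-round validation window.  The test suite uses 4 replicates of
the same design, plus smaller populations for unit checks.  These sizes
are the package's choice of study conditions; the qualitative
phenomena (biases of the misspecified models, ranking reversal under
$y_c$, relative inflation) reproduce at this scale, but the *magnitude*
of the accuracy differences between models grows with the length of the
selection history, because the maternal contamination of a mis-specified
model's breeding values accumulates over rounds.  A reduced-round study
therefore compresses the accuracy gains relative to the full 40-round
program, and the replicate spread of single-study validation slopes is
considerably larger than at full scale, where thousands of validation
birds per sire family average family noise away.

## Known limitations

* Two traits at most; no random regression or heterogeneous residual
  classes.
* Exact EM steps only for single-trait models and moderate system
  sizes.
* No prediction-error variances/reliabilities.
* The likelihood-ratio test uses naive degrees of freedom at boundary
  hypotheses.
* Genomic (marker-based) relationship matrices and genetic groups are
  out of scope; unknown parents are treated as unrelated founders.
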