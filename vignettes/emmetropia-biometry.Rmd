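---
title: "Bigaussian analysis of ocular biometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bigaussian analysis of ocular biometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmetrics)
```

## The problem

An eye is emmetropic when its optical power matches its axial length (AL)
so that a distant object focuses on the retina. Because adult emmetropia
occurs over a wide AL range (roughly 21–26 mm), the corneal power $P_c$
and crystalline-lens power $P_l$ must co-vary with AL; refractive error is
the residual mismatch. `emmetrics` implements the full analysis chain used
to study this balance in adult cohorts: a paraxial optical model that
derives every per-eye quantity from six measured values, two-component
Gaussian ("bigaussian") models of the refractive and biometric
distributions, a covariance-ellipse rule that splits a cohort into
*Regulated* eyes (those following the common biometric template) and
*Dysregulated* eyes (those with at least one deviating component), and the
descriptive analyses around them. A seeded synthetic-cohort generator
provides population-realistic data so that the whole pipeline is testable
without access to any clinical dataset.

## The paraxial eye model

Measured inputs per eye: cycloplegic spherical equivalent SE (D), anterior
and posterior corneal radii $r_{ca}, r_{cp}$ (mm), central corneal
thickness CCT, aqueous depth AD, lens thickness LT and axial length AL
(mm). Fixed refractive indices: air 1.000, cornea 1.376, ocular humours
$n = 4/3$.

The cornea is a thick lens:
$$P_{ca} = \frac{1000 (n_c - 1)}{r_{ca}}, \quad
  P_{cp} = \frac{1000 (n - n_c)}{r_{cp}}, \quad
  P_c = P_{ca} + P_{cp} - \frac{P_{ca} P_{cp}\, \mathrm{CCT}}{1000\, n_c}.$$

The crystalline lens is modelled as a thin equivalent power $P_{lb}$
acting between fixed principal points at $0.571\,\mathrm{LT}$ behind the
anterior pole and $0.378\,\mathrm{LT}$ in front of the posterior pole (the
classical Gullstrand–Emsley proportions used by Bennett's lens-power
estimate). Cornea and lens combine into the whole-eye power

$$P_{eye} = P_c + P_{lb} - \frac{P_c P_{lb}\, d}{1000\, n}, \qquad
  d = \mathrm{ACD_{tot}} + 0.571\,\mathrm{LT} - pp_{c2},$$

with $d$ the distance from the second corneal principal point to the first
lenticular one. The *axial power* is the whole-eye power that would focus
on the retina, $P_{ax} = 1000 n / (\mathrm{AL} - pp_{eye2})$, and the model
refraction is the identity $\mathrm{SE} = P_{ax} - P_{eye}$.

All principal points come from a ray-transfer-matrix engine
(`paraxial_system()`, `cardinal_points()`), with the anterior corneal
vertex as origin and the posterior direction positive. The vectorised
closed forms used at cohort scale were derived from that engine and the
test suite holds them to within $10^{-9}$ D of it. Two published formula
strings for $pp_{c2}$ and $pp_{eye2}$ circulate with index symbols whose
definition is ambiguous; `literal_principal_points()` evaluates them under
either reading and reports the discrepancy, while the matrix engine stays
normative. One consequence of the lens model worth knowing: the lens keeps
its principal-plane pair even in the degenerate zero-power limit, so
setting $P_{lb} = 0$ leaves the ocular $pp_{eye2}$ a fixed
$0.051\,\mathrm{LT}$ behind the corneal value rather than exactly on it.

### Bennett lens power

No phakometry is assumed: $P_{lb}$ is recovered from the measured SE. The
default method (`"eq1-solve"`) finds the unique lens power for which the
forward model returns the measured refraction, by monotone bisection on
[5, 45] D to $|\Delta \mathrm{SE}| < 10^{-9}$ D — an exact round trip by
construction. The classical vergence propagation (`"vergence"`) is kept as
a cross-check; the two reference the refraction at slightly different
planes and agree within 0.25 D for refractions up to about ±8 D, drifting
quadratically beyond (≈0.7 D at ±15 D). Input SE is taken as already
referenced to the corneal plane; an optional spectacle-vertex conversion
(12 mm default, off by default) is provided but not used by the standard
pipeline.

### Axial-length scaling

`scale_to_AL()` maps each eye to a unitless frame: distances divide by AL,
powers multiply by AL/1000. Under isotropic scaling the thick-lens
combination commutes with the transform exactly, which the suite asserts
to $10^{-12}$.

## Bigaussian models

The refractive distribution of adult cohorts is leptokurtic and skewed and
is described by the sum of two Gaussian-shaped terms:

$$f(x) = a_1 e^{-\left((x - \mu_1)/\sigma_1\right)^2}
       + a_2 e^{-\left((x - \mu_2)/\sigma_2\right)^2}.$$

**The exponent carries no factor ½.** This convention is load-bearing:
each component's standard deviation is $\sigma/\sqrt{2}$, its integral is
$a \sigma \sqrt{\pi}$, and the mixing weights are
$w_i = a_i\sigma_i / (a_1\sigma_1 + a_2\sigma_2)$. Every sampling and
moment computation in the package uses this convention; mixing it up with
the standard parameterisation silently corrupts every downstream number.
The narrow component is always labelled first (ties on width go to the
larger amplitude) and is identified with the Regulated subpopulation.

`fit_bigaussian_1d()` histograms refractions on integer-centred 1 D bins
(half-integer edges, left-closed; proportions relative to the in-range
count, the only reading under which the published per-bin amplitudes are
consistent) and fits by unweighted nonlinear least squares
(`minpack.lm::nlsLM`) from a method-of-moments start plus ten seeded
jittered multi-starts. The weight estimator is consistent but noisy at
cohort scale: at $n = 2000$ a single fit recovers the narrow weight with a
spread of ~9 percentage points and a slight downward bias that disappears
by $n = 20{,}000$; conclusions about weights should therefore average over
seeds, as the acceptance analysis does.

`fit_multivariate_bigaussian()` extends the model to the five dimensions
(SE, $P_c$, $P_{lb}$, $\mathrm{ACD_{tot}}$, AL): a two-component Gaussian
mixture with full covariances, fitted by expectation–maximisation from
k-means initial conditions, restarted many times (published protocol:
1000; the package default of 50 is adequate for the synthetic cohorts —
the best log-likelihood is typically found within the first few restarts),
keeping the converged restart with the lowest AIC ($2k - 2\ln L$,
$k = 41$). Covariances receive a diagonal inflation of
$10^{-6}\,\mathrm{tr}/5$ on degeneracy. The EM log-likelihood trace of
every restart is retained and tested for monotonicity.

## Regulated / Dysregulated classification

For each of the ten parameter pairs, the Regulated component's 2×2
covariance submatrix defines an ellipse centred on the component mean with
semi-axes $\varepsilon\sqrt{\lambda_i}$ along its eigenvectors. An eye is
*Regulated* iff it lies inside all ten ellipses — implemented as the
equivalent pairwise Mahalanobis rule $d_{pair} \le \varepsilon$, which is
numerically robust and affine-consistent (unit changes cannot flip a
label). Which mixture component is "Regulated" the literature leaves
implicit; the package uses the component with the smaller covariance
determinant (most compact), with ties going to the larger weight.

The scale $\varepsilon$ is calibrated by bisection on [0.5, 5] for the
smallest value whose Regulated fraction reaches the narrow-component
weight of the 1-D refractive fit of the same cohort. The fraction is a
step function of $\varepsilon$, so the achieved fraction overshoots the
target slightly rather than matching exactly — the same step-function
artefact that makes a published 70.3% sit next to a 71.4% target. Two
coverage readings of $\varepsilon$ exist and are both reported:
one-dimensional, $2\Phi(\varepsilon) - 1$ (97.62% at 2.26), and
two-dimensional per ellipse, $1 - e^{-\varepsilon^2/2}$ (92.2% at 2.26);
the package computes both and asserts nothing about which a given cohort
"should" have.

## The synthetic cohort generator

`generate_cohort()` emulates an adult population cohort (default
$n = 2000$) in *refraction-first* mode:

1. SE is drawn from the reference bigaussian (weights 71.4/28.6%, centres
   0.372/0.226 D, widths 0.935/2.369 D), truncated to ±15 D by rejection.
2. (AD, LT, AL, $P_c$) are drawn from the Gaussian conditional
   distribution given SE implied by the reference means/SDs and
   correlation matrix. The SE variance used in the conditioning is the
   mixture's own ($\sigma \approx 1.06$ D), not the cohort-table SD
   (1.52 D): the latter includes tails beyond the ±10 D fit range, and
   using it would shrink every realised SE correlation by ~25%. With the
   mixture variance the realised second moments match the targets in
   expectation.
3. CCT is drawn independently, $N(0.53, 0.03)$ mm (no reliable CCT
   correlations are reported; independence is an assumption).
4. $P_c$ is inverted into $(r_{ca}, r_{cp})$ at the fixed classical radius
   proportion $r_{cp}/r_{ca} = 6.5/7.8$ (no radii moments are available,
   only powers), solving the thick-lens quadratic.
5. Eyes violating physical invariants, AL outside [19, 32] mm, or without
   a Bennett solution are rejected and redrawn (cap: 10× the requested
   size; typical rejection ≈ 20%).

Vitreous depth is never sampled: it arises from the accounting identity
$\mathrm{VCD} = \mathrm{AL} - \mathrm{ASL}$, and its implied correlation
with AL (0.949 in expectation vs the 0.951 target) is checked rather than
imposed. By construction the derivation chain reproduces each eye's drawn
SE exactly — `derive_biometry()` on a generated cohort is a bit-exact
round trip.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: measurement noise (each eye's optics are exactly
self-consistent); the lens power's own variability — $P_{lb}$ is a
deterministic function of the five sampled quantities, so its
cross-correlations are emergent and stronger than in measured cohorts
(e.g. $r(\mathrm{AL}, P_{lb}) \approx -0.78$ vs a reported $-0.54$); age
and sex structure (present as covariates, uncorrelated with biometry); and
the exact location of the cohort's refraction centre — the reference
mixture centres at +0.33 D, slightly hyperopic of the whole-cohort mean it
was fitted from (again a tail effect), which drags the synthetic
emmetropic-subset AL mean ~0.15 mm long of the reference table value and
makes refraction-linked parameters differ detectably between the
emmetropic subset and the full cohort. `validate_cohort()` reports
pass/fail for the moments and correlations the generator *does* control.

A *biometry-first* mode (draw all biometry plus $P_{lb}$ jointly, solve SE
forward) is provided for stress-testing only; it reproduces marginal
moments but not the refraction mixture.

## Descriptive analyses

* `descriptive_table()`: mean ± SD [range] for the emmetropic subset
  (−0.5 D ≤ SE ≤ +0.5 D, both bounds inclusive) versus the *entire*
  cohort — overlapping groups, compared by unpaired t-test at the
  Bonferroni threshold 0.05/11, reproducing the published convention
  rather than an emmetrope/ametrope split.
* `correlation_matrix()`: Pearson correlations over nine parameters with
  the same Bonferroni mask; zero-variance columns are flagged, not
  NaN-propagated.
* `binned_group_summary()`: 1 D refraction bins (integer-centred,
  half-integer left-closed edges — 0.49 D falls in bin 0, 0.50 D in bin
  +1; the bin convention is a package choice, stated here because the
  literature leaves it open), per-bin means with 95% CI, CI suppressed
  below n = 3.
* `fit_alignment_regressions()`: OLS of $\mathrm{ACD_{tot}}$ and ASL on AL
  within 20–27 mm (beyond 27 mm the linear alignment breaks down), with
  residual SDs, plus per-refractive-group slopes (1 D bins, n ≥ 20).
* `uniqueness_pairs()`: two eyes are indistinguishable when all six
  compared parameters differ by at most 1.96× the device repeatability
  (0.25, 0.12, 0.25 D; 0.009, 0.015, 0.019 mm). All unordered pairs are
  counted without removing matched eyes (three identical eyes = three
  pairs); tolerances are applied to absolute differences. The
  sorted-neighbour scan is tested against a brute-force oracle.
* `relative_scaling_profile()`: surface positions as % of AL and the power
  fractions $P_c/P_{eye}$, $P_{lb}/P_{eye}$. An alternative contribution
  that first translates each element's power to the ocular principal
  plane by vergence effectivity is computed behind a flag and labelled
  non-normative: the two readings differ by several percentage points and
  the literature does not fix which is meant.

## Numerical choices

Bisection tolerances: $10^{-9}$ D on the Bennett solve (80 halvings of a
40 D bracket), $10^{-3}$ on $\varepsilon$. EM: relative log-likelihood
tolerance $10^{-8}$, 500-iteration cap, restart seeds derived as
`seed + r`. 1-D fits: bounded Levenberg–Marquardt, amplitudes in [0, 2],
widths in [0.001, 40] D. All randomness flows from explicit integer seeds
through local RNG scopes, so identical inputs give bit-identical outputs;
nothing reads or mutates the global RNG state behind the caller's back.

## Problem sizes

The shipped tests exercise: $10^4$ random eyes for the Bennett round trip,
$n = 2000$ cohorts for the statistical analyses, 20-seed replications for
the 1-D weight recovery, and a full pipeline run at $n = 2000$ with 50
EM restarts — sizes chosen to match the reference cohort where the
statistics matter and to keep every property check comfortably
deterministic.

## Known limitations

Monocular, relaxed-accommodation paraxial optics only: no astigmatism or
toricity, no chromatic effects, no gradient-index lens structure, no
lens-surface radii (the lens is its equivalent power and principal
points). The classifier is the published pairwise-ellipse rule, not a
single 5-D ellipsoid, and assigns hard labels, not posterior
probabilities. Reference moments describe one adult cohort; other
populations need their own `cohort_spec()`.
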