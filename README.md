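# emmetrics

Biometric analysis of emmetropia and ametropia in adult eyes.

Most adults end up near emmetropia even though their axial lengths span
more than 4 mm — the cornea and crystalline lens adjust their powers to
match the length of the globe. `emmetrics` is for vision scientists and
biostatisticians who study that balance at cohort scale. It provides:

* a **paraxial eye model** that derives, per eye, the corneal thick-lens
  power, Bennett crystalline-lens power, whole-eye cardinal points, axial
  power and model refraction from six measured quantities, via a
  ray-transfer-matrix engine with vectorised closed forms;
* **bigaussian models**: the leptokurtic refractive distribution is
  described as the sum of two Gaussian-shaped terms
  `a1·exp(−((x−μ1)/σ1)²) + a2·exp(−((x−μ2)/σ2)²)` (no ½ in the exponent,
  so component SDs are σ/√2 and weights are `w_i ∝ a_i σ_i`), fitted on
  1 D histogram proportions; the five-dimensional biometric extension
  (SE, P_c, P_lb, ACD_tot, AL) is a two-component Gaussian mixture fitted
  by EM with k-means starts, many restarts and AIC selection;
* **Regulated/Dysregulated classification**: an eye is *Regulated* when it
  lies inside the ε-scaled covariance ellipse of the compact mixture
  component for all ten parameter pairs (pairwise Mahalanobis rule), with
  ε calibrated so the Regulated fraction matches the narrow-component
  weight of the refractive fit;
* a **seeded synthetic-cohort generator** whose defaults reproduce
  published adult-cohort moments and correlations, so the full pipeline
  runs and is tested without any clinical data;
* the **descriptive analyses** around them: emmetropic-vs-cohort summary
  tables with Bonferroni-corrected tests, correlation matrices,
  1 D-binned overlap summaries, alignment regressions of lens position on
  axial length, biometric-uniqueness pair counting, relative
  (AL-scaled) profiles, and ggplot2 graphics for each result type.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(emmetrics)

cohort <- generate_cohort(cohort_spec(n = 2000, seed = 11))
eyes   <- derive_biometry(cohort)

dplyr::select(eyes[1:3, ], eye_id, SE, AL, P_c, P_lb, P_eye, P_ax, AL_CR)
#> # A tibble: 3 × 8
#>   eye_id       SE    AL   P_c  P_lb P_eye  P_ax AL_CR
#>   <chr>     <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 eye00001 -1.00   24.0  41.9  24.1  61.6  60.6  3.09
#> 2 eye00002  0.952  21.8  42.3  29.2  66.5  67.5  2.84
#> 3 eye00003  2.05   20.7  44.6  32.4  70.7  72.7  2.83
```

Each row is one eye: its measured refraction `SE` (D) and axial length
`AL` (mm), the derived corneal power `P_c`, Bennett lens power `P_lb`,
whole-eye power `P_eye`, axial power `P_ax` (all D) and the AL/CR ratio
(≈3 near emmetropia). `P_ax − P_eye` reproduces `SE` exactly — eye 1 is a
1 D myope because its power exceeds what its length needs.

```r
se_fit <- fit_bigaussian_1d(eyes$SE, seed = 11)
se_fit
#> Bigaussian fit of 2000 refractions (21 histogram bins)
#> Bigaussian parameters (exponent without 1/2; component SD = sigma/sqrt(2))
#>   narrow : a = 0.3827, mu = 0.4135 D, sigma = 1.044 D
#>   broad  : a = 0.07256, mu = 0.2057 D, sigma = 2.266 D
#>   weights: 70.9% / 29.1%
#>   r2 = 0.9999

mv_fit <- fit_multivariate_bigaussian(eyes, restarts = 50, seed = 11)
cal <- calibrate_epsilon(eyes, mv_fit, target = unname(se_fit$weights["w1"]))
classified <- classify_cohort(eyes, mv_fit, cal$epsilon)
table(classified$subgroup)
#>    Regulated Dysregulated
#>         1418          582
```

The refractive distribution splits into a narrow component holding 70.9%
of the eyes and a broad one holding 29.1% (the generator's target is
71.4/28.6). Calibrating the ellipse scale to that weight gives ε = 2.49,
classifying 1418 of 2000 eyes as Regulated — biometrically on-template —
and 582 as Dysregulated.

```r
fit_alignment_regressions(eyes)$fits[, c("response", "slope", "r2", "resid_sd")]
#>   response     slope       r2  resid_sd
#> 1  ACD_tot 0.1842279 0.264808 0.2742453
#> 2      ASL 0.1107262 0.122205 0.2651252

uniqueness_pairs(eyes)$n_pairs
#> [1] 5
```

The anterior lens surface sits ~0.18 mm deeper per mm of axial length and
the posterior surface ~0.11 mm — longer eyes have relatively thinner
lenses. Even in 2000 eyes, only 5 pairs are indistinguishable within the
devices' limits of agreement: ocular biometry is nearly unique.

`run_pipeline(pipeline_config(out_dir = "run1", seed = 11, n = 2000))`
chains all of the above and writes the tables, JSON summaries, figures and
a Markdown report into a directory.

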