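# retinapulse

Harmonic regression analysis of retinal vascular pulse waves measured by
modified photoplethysmography.

## Background

Retinal vessels pulsate with the cardiac cycle, and the amplitude of that
pulsation carries physiological information: it responds to the pressure
difference across the vessel wall, so it changes when intraocular
pressure (IOP) is raised by ophthalmodynamometry and differs between
people with normal and high intracranial pressure (ICP). In modified
photoplethysmography, retinal video frames are locked to the cardiac
cycle and the intensity of each vessel pixel becomes a short periodic
time series. This package implements the full analysis chain for such
data:

1. **Per-pixel harmonic regression** (`fit_harmonic_regression`): each
   intensity trace is modelled as a Fourier series in
   cardiac-cycle-fraction time,

   *y(t) = a₀ + Σₙ [aₙ cos(2πnt) + bₙ sin(2πnt)] + s(t) + ε(t)*,

   with two harmonics by default, a linear-spline trend *s(t)* (one knot
   per cycle boundary) absorbing slow drift, and first-order
   autoregressive errors fitted by iterated Prais–Winsten whitening. The
   harmonic order can be chosen per pixel by AIC
   (`select_harmonic_order`), computed from the exact Gaussian AR(1)
   log-likelihood.
2. **Pulse amplitude** (`compute_hrwa`): the harmonic regression wave
   amplitude is the peak-to-trough range of the fitted periodic
   component over one cycle — `2 * sqrt(a² + b²)` for a single harmonic,
   a grid-plus-golden-section extremum search otherwise.
3. **Yeo-Johnson normalisation** (`yeo_johnson`, `estimate_lambda`,
   `transform_cohort`): amplitude distributions are strongly skewed; the
   exponent λ is chosen per vessel by grid search minimising the Pearson
   χ²/df normality statistic (`pearson_normality`).
4. **Hierarchical mixed models** (`fit_pulse_lmm`): transformed
   amplitude on distance along the vessel, induced IOP
   (`odf_to_iop`: IOPᵢ = 0.89·ODF + IOP_b) and ICP, including all
   interactions, with nested random intercepts for subject, eye and
   hemiretina, plus marginal/conditional R² (`r2_nakagawa`) and
   standardised betas (`standardized_betas`).
5. **Descriptive statistics and interaction reading**
   (`summarize_cohort`, `wilcoxon_test`, `levene_test`, `cell_means`,
   `classify_interaction`): rank-sum comparisons with Bonferroni
   correction, and an operationalised ordinal/disordinal classification
   of the vessel-by-ICP interaction plot.
6. **A seeded synthetic-cohort generator** (`simulate_cohort`,
   `simulate_pixel_series`) with known ground truth — fixed-effect
   surface, random-intercept structure, AR(1) pixel noise — so every
   stage above can be validated end to end.

Everything is data-frame-first: functions accept and return tibbles,
models come with `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
graphics, and `run_pipeline()` drives the whole chain from a validated
YAML/JSON configuration.

## Worked example

Fit one pixel's trace (three cardiac cycles, 75 samples, drift and AR(1)
noise):

```r
library(retinapulse)
set.seed(7)
t <- seq(0, 3, length.out = 75)
y <- 5 + 2 * cos(2 * pi * t) - sin(2 * pi * t) + 0.3 * t + rnorm(75, sd = 0.2)
fit <- fit_harmonic_regression(list(t = t, intensity = y), order = 2)
fit
#> Harmonic regression fit (order 2, 75 samples)
#>   a0 = 5.128  HRWa = 4.435
#>   harmonic 1: a = 1.955, b = -1.047
#>   harmonic 2: a = 0.02756, b = -0.02507
#>   AR(1) rho = 0.1600, sigma2 = 0.03234, AIC = -24.48
```

The generating amplitude is 2·√(2² + 1²) ≈ 4.47; the drift went into the
spline, not the harmonics. Now a full synthetic cohort (21 subjects, two
eyes, ten ODF levels, both vessels, five pixels each — 4,200 pixel rows)
and the venous mixed model:

```r
sim <- simulate_cohort(cohort_design(seed = 1))
vein <- sim$table[sim$table$vessel == "vein", ]
lmm <- fit_pulse_lmm(vein, "hrwa_yjt")
lmm
#> Pulse-amplitude mixed-effects model: hrwa_yjt ~ v_dist_mm + iop_i_mmHg + icp_cmH2O (with interactions)
#> # A tibble: 8 × 5
#>   term                              estimate std_error statistic  p_value
#>   <chr>                                <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)                     1.40       0.154        9.09   9.74e-20
#> 2 v_dist_mm                      -0.342      0.0467      -7.31   2.72e-13
#> 3 iop_i_mmHg                      0.00137    0.00416      0.329  7.42e- 1
#> 4 icp_cmH2O                      -0.00193    0.00422     -0.456  6.48e- 1
#> 5 v_dist_mm:iop_i_mmHg            0.00706    0.00154      4.59   4.51e- 6
#> 6 v_dist_mm:icp_cmH2O             0.00723    0.00126      5.73   1.02e- 8
#> 7 iop_i_mmHg:icp_cmH2O           -0.00000464 0.000113    -0.0409 9.67e- 1
#> 8 v_dist_mm:iop_i_mmHg:icp_cmH2O -0.000128   0.0000410   -3.13   1.72e- 3
#> Variance components:
#> # A tibble: 4 × 3
#>   group                     variance     sd
#>   <chr>                        <dbl>  <dbl>
#> 1 subject_id:eye:hemiretina  0.00387 0.0622
#> 2 subject_id:eye             0.00699 0.0836
#> 3 subject_id                 0.0332  0.182
#> 4 Residual                   0.115   0.339

r2_nakagawa(lmm)
#> $marginal
#> [1] 0.1484044
#>
#> $conditional
#> [1] 0.3845254
```

The estimates sit close to the generating coefficients
(`vein_interaction_coefs()`: intercept 1.69, distance slope −0.3638,
distance×IOP 0.0071, distance×ICP 0.0085, three-way −0.0001612, …), each
within sampling error of its truth. Finally, the vessel-by-ICP
interaction pattern on a cell-structured cohort:

```r
tb <- simulate_cell_cohort(seed = 42)
classify_cohort_interactions(tb)
#> # A tibble: 5 × 7
#>   parameter main_effect_normal main_effect_high interaction p_main_normal
#>   <chr>     <chr>              <chr>            <chr>               <dbl>
#> 1 hrwa_yjt  present            present          disordinal      4.22e- 14
#> 2 a_n1_yjt  present            present          none            9.28e-196
#> 3 b_n1_yjt  present            absent           ordinal         1.28e-216
#> 4 a_n2_yjt  present            present          ordinal         3.36e-202
#> 5 b_n2_yjt  present            absent           ordinal         5.57e-209
#> # ℹ 2 more variables: p_main_high <dbl>, p_interaction <dbl>
```

The pulse amplitude shows the disordinal (cross-over) vessel-by-ICP
interaction; the sine coefficients lose their vessel main effect in the
high-ICP group.

The whole chain, driven by a configuration:

```r
cfg <- read_pipeline_config(NULL)   # defaults; or a path to YAML/JSON
cfg$seed <- 7
cfg$output_dir <- "run1"
res <- run_pipeline(cfg)            # writes cohort.csv, model_report.csv, ...
```

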