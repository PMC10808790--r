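# cuspfit

Stochastic cusp catastrophe regression for survey-scale data, with the
multimodality test battery that motivates it and the linear/logistic
comparison models it must beat.

## The problem

Some outcomes respond smoothly to their predictors until a control
variable crosses a critical level, after which the outcome splits into
two coexisting regimes with sudden jumps between them.  The motivating
application is educational: reading engagement driven by liking of
reading and by classroom disorder, measured as continuous scale scores
for thousands of fourth-graders in a PIRLS-type assessment.  Ordinary
regression assumes the disorder effect is the same everywhere; the cusp
model allows disorder to act as a *splitting* factor that, past a
threshold, makes engagement bimodal and unpredictable.

The package is for analysts who want to (1) test whether an outcome is
genuinely multimodal, (2) fit Cobb's stochastic cusp model by maximum
likelihood, and (3) decide, by information criteria and likelihood-ratio
contrast, whether the cusp beats the standard linear and S-shaped
(logistic) alternatives.

## The model

The rescaled state $z_i = w_0 + w_1 Y_i$ follows the stationary density
of a diffusion in the quartic potential,

$$f(z_i) \propto \exp\!\left\{\alpha_i z_i + \tfrac12\beta_i z_i^2 - \tfrac14 z_i^4\right\},$$

with the asymmetry and bifurcation controls linear in the observed
predictors: $\alpha_i = a_0 + a_1 x_{1i}$ (liking of reading) and
$\beta_i = b_0 + b_1 x_{2i}$ (classroom disorder).  Inside the
bifurcation set $27\alpha^2 < 4\beta^3$ the density is bimodal — two
stable regimes separated by an antimode.  The six coefficients are
estimated by multi-start quasi-Newton maximum likelihood with analytic
gradients and observed-information Wald inference; see the vignette
(`vignettes/cusp-catastrophe-regression.Rmd`) for the estimation
details, numerical choices and limitations.

## Worked example

A synthetic study with the package's default generating coefficients
(the published reading-engagement estimates) and a quick look at the
pipeline:

```r
library(cuspfit)

tab <- generate_study(cusp_study_spec(n = 2420, seed = 20260920))
cmp <- compare_models(tab, n_starts = 4, seed = 21)
print(cmp)
#> Model comparison (n = 2420 )
#>     model     loglik k       AIC      AICc       BIC
#>    linear -5158.4706 4 10324.941 10324.958 10348.107
#>  logistic -5157.7375 5 10325.475 10325.500 10354.433
#>      cusp -5075.9972 6 10163.994 10164.029 10198.743
#> Likelihood-ratio contrast: chi2(2) = 164.947, p = 1.52e-36

wald_table(cmp$fits$cusp, significance = 0.01)
#>   term estimate ci95_low ci95_high      se       z          p significant
#> 1   a0 -2.97371  -3.3345   -2.6130 0.18406 -16.156  1.029e-58        TRUE
#> 2   a1  0.33426   0.2967    0.3718 0.01915  17.456  3.119e-68        TRUE
#> 3   b0 -1.24948  -1.9120   -0.5870 0.33801  -3.697  2.185e-04        TRUE
#> 4   b1  0.08519   0.0305    0.1399 0.02790   3.053  2.263e-03        TRUE
#> 5   w0 -3.41748  -3.6186   -3.2163 0.10264 -33.297 4.311e-243        TRUE
#> 6   w1  0.35655   0.3382    0.3749 0.00934  38.175  0.000e+00        TRUE
```

The cusp model beats both competitors on every information criterion
(smaller is better), the likelihood-ratio contrast against the linear
model is overwhelming, and the fitted slopes recover the generating
values (`a1 = 0.331`, `b1 = 0.112`, `w1 = 0.364`) up to sampling error
— the positive `a1` says liking of reading raises engagement smoothly,
while the positive `b1` says classroom disorder pushes observations
toward the splitting regime where engagement becomes bimodal.
Diagnostics (`fit_diagnostics`) report delay-convention residuals,
whose correlation with the fitted values is slightly negative
(−0.33 here), the expected pattern for cusp fits, and count the
observations inside the bifurcation set.

The multimodality battery works on any numeric column:

```r
y <- tab$data$engagement
dip_test(y, n_mc = 1999, seed = 11)
#> Hartigan dip test: D = 0.005433, p = 0.96 (n = 2420, 1999 MC replicates)
silverman_ladder(y, n_boot = 500, seed = 12)
#>  k_null h_crit     p
#>       1 0.4764 0.348
#> First non-rejected null at level 0.05: 1 modes
```

(As discussed in the vignette, this synthetic outcome is marginally
unimodal because very few rows fall inside the bifurcation set; the
battery exists to screen real data before a cusp analysis.)

A small example dataset ships with the package
(`inst/extdata/synthetic_reading_sample.csv`, synthetic):

```r
tab <- read_study_table(system.file("extdata", "synthetic_reading_sample.csv",
                                    package = "cuspfit"))
```

## Analysis workflow

The `analysis/` scripts run the full study end to end, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study -> results/synthetic_study.csv
Rscript analysis/02_modality.R       # dip / Silverman / SiZer battery
Rscript analysis/03_compare_models.R # linear vs logistic vs cusp
Rscript analysis/04_cusp_inference.R # Wald table + diagnostics
```

`run_pipeline(run_config(...))` does the same in one call with a single
master seed and a JSON report.

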