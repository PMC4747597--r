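# nsetrait

Bayesian nonlinear structural equations for the influence of a phenological
trait on a second quantitative trait.

## The problem

Phenological traits such as days to heading (DH) in rice control the length
of the growth period and thereby *causally* influence downstream traits such
as culm length (CL). In a diversity panel this influence contaminates genetic
evaluation: genes and polygenic effects that act on heading time masquerade
as effects on culm length, and an ordinary multi-trait linear model cannot
separate the direct from the indirect genetic routes. The package is aimed at
quantitative geneticists and breeders who want to (i) estimate the
trait-value-dependent influence of a phenological trait, (ii) recover the
*direct* major-gene and polygenic effects on the influenced trait, and (iii)
predict how the influenced trait shifts when a phenology gene is edited or
introgressed.

## The model

For line *i*, with both traits mean-centered,

```
y_iP = x_iP' β_P + u_iP + e_iP
y_iA = L(y_iP) y_iP + x_iA' β_A + u_iA + e_iA
```

with `(u_P, u_A) ~ N(0, G ⊗ K)` (K the marker-derived genomic relationship
matrix), `(e_P, e_A) ~ N(0, R ⊗ I)`, and the influence function
`L(y) = Σ_m P_m φ_m(y)` a cubic B-spline with eight basis functions on a
12-knot sequence placed from the observed range of the centered phenological
trait. The system is recursive (unit Jacobian), so the likelihood is the
bivariate normal density of the structural residuals. Dropping the influence
term gives the ordinary bi-trait linear model (OLM); fixing the residual
covariance at zero gives the constrained variant that makes a *constant*
influence identifiable. Inference is by Metropolis-within-Gibbs (conjugate
draws for everything except the spline weights, which use random-walk
Metropolis with a local-support likelihood shortcut plus a joint level-shift
move), and models are compared by WAIC. See the methods vignette
(`vignettes/nsetrait-methods.Rmd`) for priors, sampler details and design
rationale.

## Worked example: a parameter-recovery study

The real cultivar panel behind the motivating analysis is not
redistributable, so the package ships a simulator that generates
statistically comparable fixtures (related inbred lines, genome-wide
markers, major genes for both traits, including a strong early-heading
allele carried by a minority of the panel). `run_study()` performs the full
recovery experiment: it simulates a pilot dataset under a nonlinear
influence, fits the NSE to it and adopts the posterior means as the
generating truth (so the truth is self-consistent with the estimator), then
simulates replicate datasets, fits both models to each, and tabulates how
well the influence and the direct genetic effects are recovered:

```r
library(nsetrait)

st <- run_study("nonlinear", n_reps = 3, n_lines = 150, n_markers = 600,
                n_iter = 8e4, burn_in = 2e4, thin = 30, seed = 101)
st
#> Replicate recovery study, scheme: nonlinear 
#>  model cor_L_mean cor_L_sd cor_uA_mean cor_uA_sd cor_betaA_mean cor_betaA_sd
#>    nse          1 1.29e-05       0.944    0.0153          0.988      0.00370
#>    olm        NaN       NA       0.913    0.0115          0.972      0.00668
#>  waic_mean waic_sd
#>       1886    44.7
#>       1917    51.8
#> delta WAIC (NSE - OLM): mean -30.64 (SD 16.49)
```

Reading the table: the NSE recovers the per-line influence `L(y_i)` with
correlation ≈ 1.00 to the truth, and its direct polygenic (`cor_uA`, 0.944
vs 0.913) and major-gene (`cor_betaA`, 0.988 vs 0.972) effects on the
influenced trait are closer to the truth than the linear model's, whose
estimates are contaminated by the influence. The mean delta WAIC of −30.6
(NSE minus OLM; negative favors the NSE) says the information criterion
correctly prefers the structural model when a nonlinear influence is truly
present — under `scheme = "none"` the same comparison hovers around zero.
The run takes a few minutes on one core.

## Fitting your own data

```r
dat <- bivariate_data(pheno, genes = genes, manifest = manifest,
                      markers = markers, reference = "Koshihikari")
fit <- nse(dat, model = "nse", n_iter = 1.1e6, burn_in = 1e5, thin = 100,
           seed = 1)
olm <- nse(dat, model = "olm", n_iter = 1.1e6, burn_in = 1e5, thin = 100,
           seed = 1)
delta_waic(fit, olm)     # negative favors the NSE
plot(fit)                # posterior influence trajectory with 95% band
summary(fit)             # G, R, WAIC, gene effects at 2x substitution scale
trajectory(fit)          # the trajectory as a data frame
identifiability(fit)     # weight vs residual-covariance chain correlations
predict(fit, "Kirara397", edits = c(Ghd7_SNP = -1))
                         # counterfactual: phenology shift, new influence,
                         # influenced-trait deviation, with 95% intervals
```

Phenotypes, gene tables (+ a column-to-trait manifest), markers and kinship
move through plain TSV/CSV files; `write_fit()` stores every posterior block
plus a JSON manifest sufficient to rerun a fit exactly, and
`compare_command()` recomputes the WAIC comparison from two stored fits.
The same workflows are scriptable from the shell via `inst/cli/nse.R`
(`kinship`, `simulate`, `fit`, `study`, `compare` subcommands).

Be aware of one structural caveat, shared with any model of this form: a
*constant* influence is confounded with the residual covariance, so the
overall level of `L` is informed by the priors rather than the data unless
the `nse-zero-rescov` variant is used; the trajectory's shape, not its
absolute level, is the robustly identified feature. `identifiability()`
diagnoses this from the chains.

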