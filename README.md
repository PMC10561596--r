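# crisprtime

Single-cell timing of CRISPR-Cas interference and primed adaptation.

When the type I-E CRISPR-Cas system of *E. coli* is induced against a
multicopy plasmid target, clearance is fast and remarkably uniform if the
target carries a consensus PAM (direct interference), but slow and wildly
variable — spanning many generations — if the PAM carries an escape
mutation, because clearance then requires primed acquisition of a new
spacer. `crisprtime` packages the quantitative machinery for studying
this at single-cell resolution:

* an **analytic first-passage-time model** of target clearance under
  induced Cascade expression. The Cascade mean follows a delayed
  production–degradation process
  μ(t) = (σ/λ)·θ(t−τ_c)·(1−e^{−λ(t−τ_c)}); with compound removal
  probability p_d per Cascade per target, the probability that all M₀
  targets are cleared is P₀(t|M₀) = (1−e^{−p_d X(t)})^{M₀} with
  X(t) = ∫₀ᵗ μ, and the clearance-time density is FP_r = dP₀/dt.
  Priming composes an acquisition first passage (rate M₀ p_p μ) with
  clearance of the remaining targets. Densities, CDFs, exact samplers
  and maximum-likelihood fitting (`fit_pd`, `fit_pp`) are included;
* a **stochastic agent-based simulator** of a constant-size growing
  population (exact thinning kinetics with geometric expression bursts,
  binomial and multivariate-hypergeometric partitioning at division,
  PAM-dependent target binding, Cas3 destruction producing pre-spacers,
  spacer integration, logistic target maintenance), with ensemble
  drivers for copy-number, affinity/integration and burst-variability
  sweeps;
* the **lineage-tree statistics** used on time-lapse data: fluorescence
  production rates, plasmid-loss and clearance-time detection,
  exponential-decay fits, sister/cousin inheritance probabilities with
  an exact Poisson-binomial test, percentile ranking of loss lineages
  with an exact binomial median test, cumulative Cascade "search
  hours", loss-time/exposure correlation timecourses, and lineage
  autocorrelation times;
* a **synthetic fixture generator** producing mother-machine-style
  lineage trees with known ground truth, so every statistic is testable
  without experimental data.

## Worked example

The analytic model at the fitted induction parameters:

```r
library(crisprtime)
mod <- fpt_model()
mod
#> First-passage-time model of CRISPR target clearance
#> Induced Cascade expression profile
#>   delay tau_c   = 34 min
#>   production    = 3 molecules/min
#>   turnover      = 0.0061 /min
#>   steady state  = 491.8 molecules/cell
#>   p_d = 0.00044 /(molecule min), p_p = 1e-06 /(molecule min), m0 = 5
#>   mean direct-interference clearance time: 94.7 min
```

The steady state of just under 500 Cascade complexes per cell and the
~94-min mean clearance time are the two headline numbers of the direct
interference model. Parameters are recovered from data by maximum
likelihood:

```r
x <- sample_fpt(mod, 500, "direct", seed = 1)
fit_pd(x, mod$profile, m0 = 5)
#> Maximum-likelihood fit of p_d (direct pathway)
#>   estimate = 0.00044073 /(molecule min)  (n = 500, logLik = -2088.86)
```

A priming-condition ensemble of simulated microfluidic wells:

```r
ens <- run_ensemble("priming", n_experiments = 10, seed = 1)
ens
#> Ensemble of 10 experiments (priming condition)
#>   931 loss events, 0.0% censored, 0.5% without acquisition
#>   mean PLT 1518 min, CV^2 = 0.626
#>   primed losses: median adaptation 1171 min, mean interference 56 min
```

Mean plasmid loss takes ~25 h and almost all of it is the wait for
spacer acquisition (median 1171 min) rather than the interference phase
(56 min); the loss-time CV² of 0.63 is several-fold above the
direct-interference value (~0.11 at the same scale), which is the
package's reproduction of the broad-versus-narrow contrast between the
two conditions. `copy_number_sweep()`, `affinity_integration_grid()` and
`burst_variability_sweep()` drive the corresponding simulated
experiments; `generate_tree(fixture_spec(...))` builds ground-truth
lineage fixtures for the analysis functions.

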