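---
title: "Models and methods behind crisprtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtime)
```

crisprtime studies the single-cell timing of type I-E CRISPR-Cas defence:
how long it takes growing *E. coli* cells to clear a multicopy plasmid
target after the *cas* genes are induced, and why that time is narrow for
a consensus-PAM target (direct interference) but enormously variable when
the PAM carries an escape mutation and clearance requires primed
acquisition of a new spacer. The package holds three connected pieces of
machinery: an analytic first-passage-time (FPT) model, a stochastic
agent-based population simulator, and the lineage-tree statistics used on
time-lapse single-cell data, plus a synthetic fixture generator so every
statistic can be validated against known ground truth.

## The analytic first-passage model

Cascade, the crRNA-guided surveillance complex, is induced at $t = 0$ and
its mean copy number follows a delayed production--degradation process

$$\mu(t) = \frac{\sigma}{\lambda}\,\theta(t-\tau_c)\,
  \left(1 - e^{-\lambda (t-\tau_c)}\right),$$

with delay $\tau_c = 34$ min, production rate $\sigma = 3$ molecules/min
and turnover $\lambda = 0.0061$/min, giving a steady state of
$\sigma/\lambda \approx 492$ molecules per cell. Each of the $M_0$ target
copies is removed with a compound probability $p_d$ per Cascade per
minute (binding followed by destruction), so the probability that all
targets are gone by time $t$ is

$$P_0(t \mid M_0) = \left(1 - e^{-p_d X(t)}\right)^{M_0},
  \qquad X(t) = \int_0^t \mu(t')\,dt',$$

and the clearance-time density is its exact derivative
$FP_r = \mathrm{d}P_0/\mathrm{d}t$. Target-maintenance replication is
deliberately ignored here (it matters little on the fast
direct-interference timescale and keeps the parameter count minimal).
With $p_d = 4.4\times10^{-4}$/min and $M_0 = 5$ the mean clearance time
evaluates to about 94 min:

```{r}
mod <- fpt_model()
mean_fpt_direct(mod)
```

Priming is modelled as two sequential first passages: acquisition of a
consensus spacer at compound rate $p_p$ per Cascade per target
($FP_p(\tau_p \mid M_0) = M_0 p_p \mu(\tau_p) e^{-M_0 p_p X(\tau_p)}$),
followed by clearance of the remaining $M_0 - 1$ targets with the
exposure integral restarted at $\tau_p$. The marginal priming
clearance-time density has no closed form and is evaluated by quadrature
over the acquisition time. At the default parameters its squared
coefficient of variation is roughly sixteen times that of the direct
density — the acquisition step owns essentially all of the variability.

Numerical choices: the exposure integral has a closed form written with
`expm1` so the $\lambda \to 0$ limit $\sigma(t-\tau_c)^2/2$ is reached
without cancellation; quadrature upper limits are chosen where the
survival probability falls below $10^{-12}$; samplers invert the
closed-form survival functions through the exposure integral
(interpolation start, Newton polish), so sampling is exact rather than
approximate. Maximum-likelihood fitting of $p_d$ uses the closed-form
log-likelihood; fitting of $p_p$ evaluates the marginal density for all
observations at once on a 2000-point acquisition grid spanning
$[\tau_c, \max t_i]$ (acquisitions after the last observed loss cannot
contribute), which keeps each likelihood evaluation a single
matrix-vector product. On 500 self-simulated loss times the fitted
$p_d$ is typically within a few percent of truth and $p_p$ within about
ten percent.

## The agent-based population simulator

The simulator keeps a constant population of $N$ cells (default 100,
emulating a microfluidic well): each cell grows exponentially with its
own lognormal rate, divides at a lognormal division size, and at every
division one uniformly random cell of the $N+1$ is removed. Growth
defaults are a 70-min mean doubling time (`mu_p = log(2)/70`,
`sigma_p = 0.2` log-sd), division size $3.9\,\mu$m with an 11% CV, and a
Normal(0.5, 0.035) division ratio. Cell-cycle phases are initialised
uniformly: each cell starts at a uniform fraction of its own generation
time, which desynchronises the population without admitting the negative
ages a literal $U(-\ln 2/\mu_p, +\ln 2/\mu_p)$ age draw would produce.

Within each cell a reaction network runs by an exact
stochastic-simulation scheme with thinning against a propensity upper
bound, embedded in a first-division scheduling loop (advance all cells
to the next division, divide, cull, repeat). All propensities of this
network are state-only, so the bound (1.5 times the current total) is
always valid and thinning is exact; the generic R-level stepper also
accepts genuinely time-varying propensities with a user-supplied bound
and aborts if the bound is ever violated. The production loop is
implemented in C++ for speed; runs are bit-reproducible under a fixed
seed because all randomness flows through R's RNG.

The network: Cascade is produced in geometric bursts (rate `k1/a`, mean
size `a*b_c`, so the variability knob `a` conserves mean flux); crRNAs
are expressed from the array (the expanded array expresses both the
original and the new spacer) and decay unless loaded; Cascade plus crRNA
assemble into effectors; effectors bind free targets with affinity set
by the PAM (`k_on_low` for the mutated PAM, `fold_consensus` = 150-fold
higher for a consensus PAM); bound targets are destroyed, releasing
`n_f` pre-spacer fragments that either decay or are integrated into the
array (primed adaptation, a 0/1 array expansion per cell); targets are
maintained by logistic replication toward the set point `p_s` (count
form; zero targets is absorbing); a reporter is expressed from free
targets. At division, free proteins split binomially by daughter size
and target-containing entities by a stochastically rounded multivariate
hypergeometric draw, so a daughter can inherit zero targets — clearance
by unequal partitioning. The direct-interference condition is the same
network started with the expanded array.

The kinetic rate table behind the published simulations is not public,
so the shipped defaults are the package's own calibration against three
stated anchors: steady-state Cascade about 500 per cell (measured 528),
a direct-interference mean loss time of order 1.5--3 h once the 34-min
induction delay is accounted for (74 min simulated, the delay being
owned by the analytic model), and a priming loss-time distribution at
least fivefold broader than direct in CV$^2$ (measured ratio 6--7 at
100 experiments of 100 cells). With these defaults the simulator also
reproduces, without further tuning: monotone growth of the mean loss
time with target copy number under direct interference; the
non-monotone priming curve (fast loss at one copy via low-level
interference and partitioning, slowest at intermediate copy numbers,
faster again at high copy numbers as destruction events supply more
pre-spacers) together with its adaptation/interference breakdown; and
the confinement of broad loss-time distributions to the low-affinity
column of the affinity-by-integration grid — hundredfold slower spacer
integration alone does not create breadth, hundredfold lower binding
affinity does.

## A known limitation: expression burstiness and adaptation speed

Increasing the Cascade burst-variability factor to $a = 100$ at
conserved mean raises the cell-to-cell concentration CV from about 0.13
to about 0.46 and makes the primed-interference phase far more variable,
both as expected. It does not, however, accelerate adaptation in this
network: mean loss time and median adaptation time *increase* slightly.
The reason is structural, not a matter of rate choices: the acquisition
hazard here is linear in effector abundance (one effector binds one
target), and for any linear hazard with conserved mean production flux
the mean first-passage time under bursty expression is
$x/(1 - e^{-x}) \ge 1$ times the smooth-expression value (with $x$ the
per-burst exposure times the hazard), with a further slow-down from
lineage-persistent expression differences. A speed-up from burstiness
requires some superlinear dependence of acquisition on instantaneous
Cascade levels, which this network does not contain; the corresponding
acceptance assertions are therefore expected to fail and are left in
place as a documented discrepancy. The baseline concentration CV also
cannot reach arbitrarily low values: growth-rate variability
(`sigma_p = 0.2`) alone imposes a floor of roughly 0.13.

## Lineage statistics and their fixtures

The analysis layer operates on a lineage-tree container (per-cell
records plus per-frame series of length and total fluorescence per
channel) emitted by both the simulator and the fixture generator, and
validated on read (orphans, children born away from their mother's
division, non-increasing frames).

Key procedure choices, each configurable:

* **Production rate** is $\mathrm{d}F/\mathrm{d}t + k_\mathrm{bleach} F$
  on the *total* fluorescence (growth dilution cancels in the total),
  central differences within cells, smoothed by a 5-frame moving
  average.
* **Death filtering** truncates a root-to-leaf path at the first point
  where the smoothed elongation rate reaches zero and never recovers;
  transient dips are kept.
* **Loss detection** takes the first threshold crossing of the smoothed
  production rate along each path and assigns the event to the cell in
  which it occurs, so an inherited loss is counted once. The threshold
  default is the 99th percentile of plasmid-free production rates.
* **Clearance time** aligns loss traces at the loss time, averages, and
  measures back to the last time the trend exceeds 90% of its pre-loss
  plateau. On fixtures built with a 60-min linear ramp-down the
  estimate is 54--57 min; the 90% criterion on a linear ramp
  intrinsically concedes a tenth of the ramp.
* **Percentile ranks** use the strictly-below fraction with midranks
  for ties, so identical values rank at exactly 50; the two-sided
  binomial median test drops exact ties at 50. Both match exhaustive
  enumeration for small n, and on null cohorts the rank-then-test
  pipeline rejects at the attainable level of the n = 12 sign test
  (0.039, within the expected neighbourhood of 5%).
* **Autocorrelation** along root-to-leaf paths weights each observation
  pair by one over the number of leaves sharing the later cell, so
  segments shared by sister paths are not double-counted; the
  decorrelation time is the first lag whose 95% band includes zero.
  On simulated populations, Cascade concentration decorrelates several
  times more slowly than the growth rate, which is why feature-ranking
  uses short lookback windows.

The fixture generator emulates mother-machine-style chains: exponential
growth with lognormal rate variability, divisions at a fixed size,
reporter production at a plateau that ramps down linearly over the true
clearance time and stops at the injected loss time, optional
photobleaching, multiplicative measurement noise, growth-arrest
injection, a constant-concentration second channel, and loss times
either scheduled or drawn with hazard proportional to cumulative
exposure of that channel. What it deliberately does not emulate:
branching (sister pairs), segmentation artefacts, maturation delays,
and the correlated biological noise of real movies — so passing on
fixtures demonstrates estimator correctness under the stated
measurement model, not robustness to every artefact of real imaging
data.

## Problem sizes

The test suite runs its ensemble checks at the sizes the package's own
error analysis supports: the broad-versus-narrow comparison at 100
experiments of 100 cells (the jackknife-over-experiments error of the
CV$^2$ ratio is then well below the factor-of-five margin), copy-number
and grid sweeps at 8--15 experiments per point with orderings asserted
only when separated by at least two ensemble standard errors, and the
ranking calibration at 1000 seeded null cohorts. Ensembles terminate
early once every lineage has lost its targets; zero targets is
absorbing, so this is exact for loss statistics.
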