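---
title: "Methods: population-adaptive restraint design with GP surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-adaptive restraint design with GP surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restraintopt)
```

## Problem and model

A restraint system is parameterised by seven design variables $d$: belt load
limiter payouts $D0_{LL}, D1_{LL}$ (m), airbag cushion diameter $DAB$ (m),
airbag tether length $DABSTRAP$ (m), retractor belt force $F_{LL}$ (N), and
fractional adjustments of the airbag mass flow rate $MF$ and knee bolster
stiffness $Stiff$; their feasible ranges are in `design_box()`. An occupant
is described by covariates $s$ = (sex, stature in cm, BMI in kg/m²),
restricted to a per-sex box nominally covering the 5th–95th percentile of
the adult population.

A crash-simulation oracle $y(s, d)$ returns three injury measures — HIC15,
peak chest deflection (mm) and peak femur axial force (kN) — which map
through region risk curves and an independence combination to the joint
injury probability $P_{joint}$. A *design policy* $a(s)$ assigns a design to
each occupant; the target is

$$a^* = \arg\min_a \mathbb{E}_s\!\left[f(s, a(s))\right],$$

with $f$ the joint risk. The package implements the two-step approach:
(1) replace $f$ by a Gaussian-process surrogate trained on a space-filling
simulation campaign, predicting at an upper confidence bound; (2) restrict
$a$ to polynomial maps $a(s) = \sum_{j=1}^{m} B_j \phi_j(s)$ with
$\phi_j(s) = [s_1^{j-1}, \dots, s_K^{j-1}]$ and optimise the coefficients on
a Monte-Carlo sample of occupants.

## Population module

The population density is taken uniform over the per-sex covariate boxes
with equal sex weight: the optimization weights occupants equally (a
constant $p(s)$), and we make the same choice for sampling, since no survey
density is shipped with the package. The default boxes — male stature
[163, 186] cm, BMI [20.5, 39.5]; female stature [150, 172] cm, BMI
[19.5, 42.5] — are documented stand-ins for 5th–95th survey percentiles and
are configurable, as is the midsize-male reference (male, 175 cm,
BMI 25.6). Vulnerable subgroups are defined by strict thresholds: tall
obese males (BMI > 30.5, stature > 181.7 cm) and short obese females
(BMI > 37.3, stature < 157 cm), both safely interior to the default boxes.

## Synthetic simulator: what it emulates and what it does not

Real crash oracles for this problem are proprietary multibody models; the
package ships a synthetic stand-in whose *structure* reproduces the features
the method relies on, with a ground truth that makes correctness provable:

$$y_m(s, d) = b_m(s)\,\Big(1 + \sum_l w_{ml}\,(\tilde d_l - \tilde
d^*_l(s))^2\Big)\,\varepsilon,$$

* $b_m(s)$ — baselines (HIC15 600, chest 30 mm, femur 4 kN for the sedan
  preset at the reference occupant) scaled by an exponential in BMI and
  stature (0.025 per BMI unit, 0.016 per cm: a +10 BMI / +10 cm occupant
  carries ≈ 50% higher baselines) plus a female offset on chest deflection
  (+0.08 on the log scale). Strict monotonicity in BMI and stature encodes
  the higher baseline risk of large occupants. Magnitudes are stand-ins.
* quadratic "bowls" on the unit design scale with non-negative weights
  $w_{ml}$; each design variable carries weight in at least one measure, so
  the optimum is identifiable.
* $\tilde d^*(s)$ — the ground-truth optimal setting, *linear* in the
  standardised covariates and clipped to the box. Defaults make the optimal
  retractor force increase (slopes +0.18 per unit standardized BMI, +0.05
  per unit standardized stature) and the optimal mass flow decrease (−0.18,
  −0.04) for heavier occupants — tighter belt, softer airbag. Slope sums per
  variable are kept ≤ 0.25 so true optima stay within roughly [0.25, 0.75]
  of each unit range: mid-box optima are the physically plausible regime and
  keep the logistic output squash of the policy in its near-linear band, so
  the linear policy class genuinely contains a near-oracle policy.
* $\varepsilon$ — multiplicative lognormal noise, relative sd 2% by default,
  keeping measures positive.

Because the optimum is linear in $s$ and the bowls are quadratic, the
globally optimal adaptive policy is known in closed form
(`true_optimal_design()`), giving an analytic oracle for policy recovery.
Two presets ("sedan", "suv") differ in baselines and bowl weights to mirror
two vehicle programmes structurally, not numerically.

What the stand-in does **not** emulate: biofidelic crash dynamics,
interactions between design variables (the bowls are additive), posture and
belt-fit geometry, non-monotone covariate effects, or the absolute injury
levels of any real vehicle. Passing tests therefore demonstrate that the
*method* recovers known structure under realistic smoothness and noise —
not that the resulting designs transfer to hardware.

## Design of experiments

Simulation inputs are chosen by the maximum-projection criterion

$$\psi(D) = \Big[\tbinom{n}{2}^{-1} \sum_{i<j} \prod_l (x_{il} -
x_{jl})^{-2}\Big]^{1/p},$$

minimised by simulated-annealing coordinate exchange on a random Latin
hypercube: proposals swap two entries within one column (preserving the LHS
structure), improvements are always accepted, worsenings with Boltzmann
probability under geometric cooling (default 10,000 proposals, initial
temperature 5% of the mean pair score). The best design visited is
returned, so $\psi$ never exceeds the starting value. Sex is handled as a
continuous column thresholded at 0.5 during scaling: the criterion operates
on the continuous relaxation (keeping $\psi$ finite) and even run counts
yield an exactly balanced binary factor.

## Injury risk model

Region risks use standard frontal-impact AIS3+ curve forms with fixed
coefficients (`risk_params()`): head
$\Phi((\ln \mathrm{HIC} - 7.45231)/0.73998)$; chest
$[1+\exp(10.5456 - 1.568\,D^{0.4612})]^{-1}$; lower extremity
$[1+\exp(5.795 - 0.5196\,F)]^{-1}$. Anthropometric scaling divides the
chest and femur measures by the ratio of the occupant's predicted chest
depth / femur cross-sectional area to the midsize-male reference values —
equivalent to stretching the risk-curve abscissa — using linear predictors
with documented stand-in coefficients; head risk is not scaled. The joint
risk is the independence combination
$1-(1-p_h)(1-p_c)(1-p_l)$: "combining regions" is not uniquely defined by a
population average, and independence is the standard, testable choice.

## Surrogate

One GP per measure (no cross-measure covariance is assumed), over the
10-dimensional standardized input (sex 0/1, stature, BMI, unit-scale
designs), squared-exponential kernel with per-dimension lengthscales,
constant mean absorbed by target standardization, Gaussian observation
noise, and a $10^{-6}$ diagonal jitter. HIC15 is modelled on the log scale
(its response spans multiplicative factors) and back-transformed
monotonically, so the UCB commutes with the transform. Hyperparameters
maximise the marginal likelihood via L-BFGS-B with analytic gradients from
3 fixed-seed starts; lengthscales are bounded in [0.05, 50] standardized
units and the noise sd in [10⁻⁴, 2]. A zero-variance target falls back to a
constant fit with a noise floor.

The "95% upper confidence bound" is interpreted one-sided
($z = \Phi^{-1}(0.95) = 1.645$), matching upper-bound semantics; the level
is configurable. Cross-validation (`cross_validate()`) refits per fold and
reports per-measure $R^2$ on the natural measure scale.

## Policy optimization

Covariates are standardised to $[-1, 1]$ per the box (sex to $\{-1,+1\}$)
before taking powers — raw cm/BMI powers would be numerically
ill-conditioned. Sex powers collapse ($x^2 = 1$), so the feature builder
de-duplicates: order $m$ yields the intercept, sex, and stature/BMI powers
up to $m-1$. The default order is $m = 2$ (a linear policy): the policy
class is a configurable knob 1–4, and we surface rather than resolve the
tension between cubic-capacity and linear-behaviour descriptions of such
policies — with the default synthetic ground truth the optimal policy *is*
linear, and nested-class tests guarantee higher orders never do worse.

Feasibility is enforced by a smooth scaled-logistic squash onto each design
range (midpoint at the box centre), so gradients exist everywhere; hard
clipping is available for analysis. The Monte-Carlo sample is a 512-point
space-filling sample over the covariate box with uniform weights, fixed
seed. Optimization is full-batch Adam (learning rate 0.001, the standard
choice at this scale) on the coefficient matrices, with *analytic*
gradients chained through the squash, the GP posterior mean and sd, and the
risk curves; multi-start with seeded initialisations, best objective kept,
and the best-visited iterate returned, so the returned objective never
exceeds any start's initial value.

Two warm-start conventions make the expected ordering structural rather
than fortuitous: the population-constant search includes the midsize-male
optimum as a start, and the adaptive search initialises its intercept at
the population optimum. Since constants are order-1 policies and the
adaptive class nests them, mean risk(adaptive) ≤ mean risk(population
constant) ≤ mean risk(midsize constant) up to optimizer tolerance.

Problem sizes used by the shipped tests and acceptance script — 300-run
campaigns, 512-point optimization samples, 2,048-point evaluation samples,
500–3,000 Adam steps — were chosen as the smallest sizes at which the
surrogate is near-interpolating ($R^2 > 0.95$) and the optimizer converged
(tripling the step count changes the objective by < 10⁻⁵); they are the
package's own defaults for desk-scale studies.

## Evaluation

`population_risk_table()` reports population means of region and joint
risks per design plus the joint risk at the midsize-male reference;
`subgroup_report()` restricts to subgroup members (empty subgroups are
flagged, not computed); `relative_reduction()` is
$100(\mathrm{base}-\mathrm{new})/\mathrm{base}$, computed from
full-precision means and rounded only for display. The per-variable
sensitivity analysis re-optimises a policy in which exactly one design
variable adapts (its coefficient rows free) while the others are pinned at
the population-constant optimum; nesting guarantees no single-variable
reduction exceeds the full policy's.

## Known limitations

* The synthetic simulator's additive quadratic bowls exclude design–design
  interactions; methods conclusions about interaction-heavy responses are
  untested here.
* Uniform covariate sampling ignores stature–BMI correlation; subgroup
  sizes in evaluation samples will not match survey prevalences.
* Exact GP inference is $O(n^3)$; campaigns beyond a few thousand runs
  would need approximate inference, which is out of scope.
* The UCB enters the objective pointwise per measure; it is a conservative
  heuristic, not a coherent joint posterior bound on $P_{joint}$.
* Risk-curve and anthropometric-scaling coefficients are fixed, documented
  substitutions; swapping in programme-specific curves is a config change,
  and absolute risk levels should not be read as predictions for any real
  vehicle.
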