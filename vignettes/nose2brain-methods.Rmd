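---
title: "Methods: formulation optimization and nose-to-brain targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formulation optimization and nose-to-brain targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nose2brain)
```

This vignette documents the models and procedures implemented in
`nose2brain`, the assumptions behind them, the numerical choices that
were genuinely open, and what the bundled simulators do and do not
emulate. The running example throughout is the packaged berberine
nanostructured lipid carrier (NLC) study: a 17-run Box–Behnken
formulation screen over glycerol monostearate amount (100–200 mg),
poloxamer 407 concentration (1–2 % w/w) and oleic acid amount
(15–30 mg), followed by ex vivo nasal permeation and an in vivo
intranasal/intravenous brain-targeting comparison.

## The Box–Behnken design

A three-factor Box–Behnken design places runs at the midpoints of the
twelve edges of the coded cube — every sign combination of two factors
at ±1 with the third at its centre — plus replicated centre points
(five in the bundled study, giving 17 runs). Coded units map the low,
mid and high level of each factor onto −1, 0, +1:

$$x = \frac{\text{actual} - (\text{low}+\text{high})/2}{(\text{high}-\text{low})/2}.$$

Coded levels are stored exactly as −1, 0, +1 (values read back from CSV
are snapped within `1e-6`), so the linear columns are exactly centred
and orthogonal with sum of squares 8 — which is also what makes the
closed-form contrast oracle used in the tests valid: on this design the
linear coefficient for $x_j$ equals the (+1 minus −1) response sum
divided by 8, and the intercept is the grand mean.

Generated designs use a canonical row order (edge blocks by the index
of the zero factor, signs lexicographic, centres last). Tables from the
laboratory carry their own order; comparisons are made as sets.

## Response-surface models and diagnostics

Responses are modelled by ordinary least squares on a transformed scale
chosen per response: square root for particle size, reciprocal for
entrapment efficiency, identity for release and zeta potential in the
bundled configuration. The model assumes additive homoscedastic errors
*on the transformed scale*; all diagnostics are therefore computed
there, including pure error and the coefficient of variation. For the
entrapment model the %CV could equally be defined on the original
scale; this package deliberately uses the transformed scale everywhere
for internal consistency, and flags this as a convention rather than a
fact about the data.

The diagnostic panel follows the conventions of commercial DoE software
so results are directly comparable:

* **Type III ANOVA.** Each term's F statistic comes from its partial
  (drop-one) sum of squares. On the orthogonal linear block these equal
  sequential sums of squares — a built-in cross-check exercised by the
  test suite. No multiplicity correction is applied.
* **Lack of fit.** The residual sum of squares is partitioned into pure
  error (within replicate groups of identical coded settings) and lack
  of fit, with $F = (SS_{lof}/df_{lof})/(SS_{pe}/df_{pe})$. With no
  replicates the test is reported as unavailable, never as zero.
* **Predicted $R^2$** uses the PRESS statistic computed exactly from
  the hat matrix (leave-one-out without refitting).
* **Adequate precision** is the signal-to-noise ratio
  $(\max \hat y - \min \hat y)/\sqrt{p\,MSE/n}$ over the *design
  points*, with $p$ counting the intercept. The fitted-value range at
  the design points (rather than over the whole cube) is the definition
  that reproduces the bundled study's reported values.
* **Model reduction** is backward elimination: repeatedly drop the
  removable term with the largest partial-F p-value above
  $\alpha = 0.05$ and refit. Weak heredity is enforced — a linear term
  is never removed while its square or one of its interactions remains.
  On the bundled entrapment data this retains exactly the linear terms,
  the lipid–oil interaction and all three squares.

Predictions evaluate the polynomial on the transformed scale and
back-transform (square, reciprocal). Points outside $[-1.2, 1.2]^3$ are
rejected unless extrapolation is explicitly enabled, and a transformed
prediction that leaves the inverse transform's domain (e.g. a negative
value to be squared back) is an error, not a silent `NaN`.

## Desirability optimization

Each response with a goal gets a one-sided Derringer ramp between
anchors $L < U$ (weight exponent $w$, default 1):

$$d = \Big(\frac{y - L}{U - L}\Big)^w \text{ (maximize)},\qquad
  d = \Big(\frac{U - y}{U - L}\Big)^w \text{ (minimize)},$$

clipped into $[0,1]$. The overall desirability is the geometric mean,
so any fully undesirable response vetoes a candidate. Anchors default
to the observed response range over the design — the convention of
mainstream DoE software — because published optimizations rarely state
them; they are configurable precisely for that reason. Zeta potential
is excluded from the bundled objective (goal `"none"`) because its
factors show no significant effects.

The search maximizes $D$ over the coded cube with a dense grid
(41 points per axis by default) followed by a Nelder–Mead polish with
relative tolerance $10^{-6}$, coordinates clamped to the cube. The
procedure is deterministic; no seed is involved. Grid ties are broken
by the smallest prediction of the first minimize-goal response, then by
lexicographic coded coordinates. A candidate where some model's
prediction leaves its domain contributes $D = 0$. Reported optima are
monotone under grid refinement up to the polish tolerance (the test
suite checks this at $10^{-6}$).

On the bundled study the optimum sits at the high oleic acid bound with
$D \approx 0.81$. The located point is not identical to the study's
published optimal settings — with min/max anchors the desirability
surface is quite flat along a ridge in $(x_1, x_2)$ — but the package's
predictions *at* the published point agree with the published predicted
values to within about 1%.

## Release and permeation

Entrapment efficiency is the indirect estimate
$100(\text{dose} - \text{free})/\text{dose}$ from the unentrapped drug
in the filtrate.

Diffusion-cell records hold sampled receptor concentrations plus the
full cell geometry. Cumulative amount per area with sampling
replacement credits the drug removed by earlier samples:

$$Q(t_n) = \frac{C_n V_{receptor} + \sum_{i<n} C_i V_{sample}}{A}.$$

Steady-state flux is the least-squares slope of $Q$ versus time; the
default window drops only the first sample, since the steady-state
portion of a permeation curve is rarely defined explicitly, and the
window is configurable (indices or a time range). Apparent permeability
is $J_{ss}/C_0$.

Two geometry choices in the bundled configuration deserve a note,
because the study's printed protocol is internally inconsistent:

* The donor concentration $C_0$ is set to 1000 µg/mL. This is
  back-calculated from the study's own flux/permeability pairs (both
  preparations give $J_{ss}/P_{app} = 1000$); the donor volume itself
  is never printed. $C_0$ is therefore an explicit configuration field,
  never a hard-coded constant.
* The permeation cell is printed as 2.5 cm² with a 3 mg dose, yet the
  printed percent-permeated and cumulative-amount pairs imply a dose
  per area of 600 µg/cm² (i.e. 3 mg over 5 cm², the *release* cell
  area). The configuration makes area, dose and volumes all explicit;
  the bundled tests use the implied 600 µg/cm² for the percentage
  arithmetic and document the discrepancy rather than resolving it.

## Non-compartmental analysis and targeting

Profiles are strictly increasing time series of non-negative
concentrations (minutes, ng/mL), one per tissue × route × group. The
estimators are deliberately plain:

* **AUC** by the linear trapezoid over observed points up to the
  configured horizon (480 min in the bundled configuration). No
  extrapolation beyond the last observation; a horizon falling between
  observations is handled by linear interpolation, which keeps the
  integral additive and exact for piecewise-linear curves.
* **Terminal $K_e$** by log-linear regression over the last three
  positive observations (window size configurable). The window choice
  is the conventional minimal one; published tables rarely state it.
  Flat or rising windows raise an estimation error with the window
  location in the message. $t_{1/2} = \ln 2 / K_e$ is always derived
  from the unrounded $K_e$ — printed $K_e$/$t_{1/2}$ pairs in the
  literature are often mutually inconsistent after rounding, so the
  package never treats a printed half-life as an input.
* **Cmax/Tmax** directly from the observations, earliest time on ties.
* **Brain/blood ratio** at a stated time requires an observation at
  exactly that time by default; optional log-linear interpolation is
  available (exact for exponential segments), falling back to linear
  when a bracketing concentration is zero.

The targeting panel for an intranasal group against an intravenous
reference is

$$\mathrm{DTE\%} = 100\,\frac{(AUC_{brain}/AUC_{blood})_{IN}}
                            {(AUC_{brain}/AUC_{blood})_{IV}},\qquad
  B_x = \Big(\frac{AUC_{brain}}{AUC_{blood}}\Big)_{IV} AUC_{blood,IN},\qquad
  \mathrm{DTP\%} = 100\,\frac{AUC_{brain,IN} - B_x}{AUC_{brain,IN}}.$$

DTE = 100% means no preferential targeting; the two statistics obey
$\mathrm{DTP} = 100(1 - 100/\mathrm{DTE})$ identically, and both are
invariant to a common rescaling of all concentrations — both facts are
exercised as tests. On the packaged study values the panel gives
DTE = 509.2% and DTP = 80.4% for the coated carrier, which is what the
acceptance script recomputes.

## The simulators and what they (do not) show

The package can generate every input it consumes, with known ground
truth:

* **Formulation studies**: each response's truth is a polynomial on its
  transformed scale plus Gaussian noise there (matching where the
  models assume homoscedasticity); back-transformation to the response
  scale follows. Noise draws that exit a transform's domain are redrawn
  with a warning, with a retry cap. At zero noise the fitter recovers
  the generating coefficients to machine precision, and at the bundled
  study's residual noise level the intercept's sampling error matches
  OLS theory (checked over 200 replicate simulations).
* **PK studies**: blood is one-compartment (bolus for IV, first-order
  absorption of the systemic depot fraction for IN); brain follows
  linear uptake/efflux from blood plus, for IN, first-order input of
  the direct fraction `f_direct` of the dose. All four curves are
  closed-form, so the simulation also reports *exact* infinite-horizon
  AUCs and the DTE/DTP they imply. With `f_direct = 0` the implied DTE
  is exactly 100; DTP grows strictly with `f_direct`; and the
  trapezoid estimator reproduces these on a dense long grid
  (2-minute spacing to 4000 min in the tests). Default parameters are
  illustrative: they are tuned so the qualitative pattern matches a
  nose-to-brain study (IV blood peaks first and decays fastest, the
  intranasal brain curve peaks last, brain/blood AUC ratio above 1 for
  the carrier, all four curves declining over the terminal window of
  the default 10–480 min grid) — they are not a fit to any measured
  curves, which exist only as published figures.
* **Permeation runs**: a flux-plus-lag line converted back into the
  sampled concentrations that the replacement bookkeeping would have
  produced, with optional multiplicative noise.

Concentration noise is multiplicative log-normal (mean one, stated CV),
preserving non-negativity. Every stochastic generator takes an explicit
seed and is bit-reproducible given it.

What passing these tests does *not* show: the simulators generate mean
curves for a single animal-free tissue pool — there is no inter-animal
variability, no destructive-sampling design (real nose-to-brain studies
sacrifice separate animal subgroups per time point), no assay error
structure, and no saturation or efflux-transporter nonlinearity. Where
real profiles exhibit flip-flop kinetics or late secondary peaks, the
one-compartment absorption model cannot reproduce them. Agreement of
the estimators with the simulator's truth validates the arithmetic, not
the biology.

## Numerical choices and degenerate inputs

* OLS is solved by QR decomposition; rank deficiency is an explicit
  error ("singular fit"), as is a model with more terms than runs.
* Hat values (for PRESS) come from the thin Q factor, avoiding explicit
  inverses.
* A constant response (zero total sum of squares) makes $R^2$-type
  statistics an error, not `NaN`.
* Transform domain violations name the offending runs.
* Design tables are written with 17 significant digits so a write/read
  round-trip is bit-exact.
* The closed-form PK solution requires the rate constants
  $k, k_a, k_{out}, k_d$ to be pairwise distinct (the solution
  degenerates to $t e^{-kt}$ terms at equal rates); coincident values
  are rejected at parameter construction with a clear message rather
  than approximated.

## Problem sizes

The test suite runs the full 17-run study end to end (fits, ANOVA,
diagnostics, reduction, optimization at grid 41³, all in well under a
second each), 200 replicate formulation simulations for the sampling
theory check, 100 noisy permeation runs, and dense-grid PK simulations
of about 2000 points. The acceptance script is pure arithmetic on the
packaged study inputs.

## Limitations

* Only three-factor Box–Behnken designs are constructed (no central
  composite or Plackett–Burman families, no blocking).
* Desirability supports one-sided minimize/maximize goals on the cube;
  no target-value or constrained-region goals.
* No release-kinetics model fitting (Higuchi, Korsmeyer–Peppas), no
  compartmental PK fitting, no AUC extrapolation to infinity for
  observed data, and no formal statistical comparison of PK parameters
  across groups.
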