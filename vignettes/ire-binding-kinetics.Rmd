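---
title: "Methods: stopped-flow kinetics of IRE-RNA/protein binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stopped-flow kinetics of IRE-RNA/protein binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irekin)
```

## The binding model and its assumptions

`irekin` analyses rapid-mixing kinetics of iron-responsive-element (IRE)
RNA binding to two competing proteins — the translational repressor IRP1
and the initiation complex eIF4F — under a one-step bimolecular mechanism

$$\mathrm{P} + \mathrm{RNA} \underset{k_\mathrm{off}}{\overset{k_\mathrm{on}}{\rightleftharpoons}} \mathrm{RNA{\cdot}P}.$$

The model assumes no kinetically resolved intermediate: binding and any
coupled conformational change relax as one step on the observable
timescale. Its signatures, which the fitting layer is built to test, are
(i) mono-exponential traces, and (ii) an observed rate linear in the
concentration of the partner in excess,

$$k_\mathrm{obs} = k_\mathrm{on}[\mathrm{P}] + k_\mathrm{off},$$

so a titration gives $k_\mathrm{on}$ from the slope, $k_\mathrm{off}$ from
the intercept, and $K_d = k_\mathrm{off}/k_\mathrm{on}$. Two-step
("lure-and-lock") mechanisms, ionic-strength theory and IRP2 are out of
scope.

Units are fixed package-wide: concentrations in µM, time in s,
$k_\mathrm{on}$ in µM⁻¹ s⁻¹, $k_\mathrm{off}$ in s⁻¹. $K_d$ is *reported*
in nM, and the single µM→nM conversion lives in `compute_Kd()`.

## Trace synthesis: relaxation form versus full mass action

`generate_trace()` supports two mechanisms, and the distinction matters
more than it first appears.

The default, `mechanism = "relaxation"`, is the pseudo-first-order
description under which stopped-flow titrations are analysed: the titrant
(the protein in the anisotropy designs, the RNA in the fluorescence
designs) is treated as undepleted, which makes the complex concentration —
and hence the signal — *exactly* mono-exponential with rate
$k_\mathrm{on}[\mathrm{titrant}] + k_\mathrm{off}$. This is the
phenomenology the instrument records in these experiments (single
exponentials across the whole concentration range), and it makes the
generator→fitter round trip exact, which is what you want from a
correctness harness.

`mechanism = "mass_action"` integrates the full bimolecular system (via
`deSolve::lsoda`, rtol 1e-9 / atol 1e-12 — rates span roughly 5–430 s⁻¹
and traces span ms to s, so a stiff-capable integrator with tight
tolerances is the safe default). Association from unmixed species is then
*not* exactly exponential: depletion of the titrant lowers the late-time
relaxation rate below $k_\mathrm{on}[\mathrm{P}]_0 + k_\mathrm{off}$. A
single-exponential fit to such a trace under-estimates $k_\mathrm{obs}$ by
about 3% at 20-fold titrant excess, about 10% at 4-fold, and the bias only
falls below 1% near 100-fold excess; at equal concentrations the trace is
visibly non-exponential. The test suite pins both regimes. Dilution
experiments are different: they start *near* equilibrium, so the
mass-action relaxation is well approximated by one exponential at the
linearised rate
$k_\mathrm{on}([\mathrm{R}]_\mathrm{free,eq} + [\mathrm{P}]_\mathrm{free,eq}) + k_\mathrm{off}$,
and `generate_dilution_trace()` therefore always uses the full integrator.

This split also explains a deliberate asymmetry in the analysis layer: the
dilution trace is generated by mass action, but `analyze_dilution()`
inverts the idealised relation $k_\mathrm{obs} = k_\mathrm{off}([P]/K_d + 1)$,
as the original analysis does. On synthetic data the recovered
$k_\mathrm{off}$ lands within ~5% of the generating value — the same order
of disagreement the published work shows between its intercept (6.2 s⁻¹)
and dilution (8.3 s⁻¹) estimates for the same quantity. The package
reports both routes and resolves nothing.

## What the generator emulates, and what it does not

The instrument model: 1-ms dead time (points before it are discarded),
1000 points per shot on a uniform grid, 5 shots averaged per trace with
per-shot child seeds derived from the master seed by fixed arithmetic (so
averaging is reproducible shot-by-shot), acquisition window
$t_\mathrm{end} = \max(10/k_\mathrm{obs},\ 50\ \mathrm{ms})$. The built-in
design presets mirror the published experiments: labelled RNA fixed at
0.05 µM with IRP1 at 0.05/0.2/0.5/1.0 µM (anisotropy), eIF4F fixed at
0.1 µM with RNA at 0.1/0.2/0.5 µM (fluorescence), each optionally repeated
at 0/5/25/50 µM Mn²⁺ with the tabulated rate constants, and 2-fold
dilution relaxations. All stated concentrations are final (post-mix).

Signal constants are package inventions — the source records none — chosen
so the amplitude-to-noise ratio is ~50, consistent with visibly clean
single-exponential records: anisotropy baseline 0.05, bound span 0.15,
σ = 0.002; fluorescence baseline 1.0, quench fraction 0.3, σ = 0.005.
Noise is homoscedastic Gaussian per point. Real anisotropy noise is
heteroscedastic (it is a ratio of photocurrents), real instruments drift
and photobleach, and dual-channel raw acquisition is not modelled — the
generator emits the computed observable only. Passing tests therefore
demonstrate correctness of the *analysis chain*, not robustness to every
instrument pathology.

An optional `active_fraction` multiplier on protein totals accommodates
preparations that are not fully binding-competent (~85% is typical for
recombinant IRP1); the default is 1.0 so that stated concentrations mean
what they say.

## Fitting and model selection

Fits are unweighted Levenberg–Marquardt least squares (`minpack.lm`),
initialised deterministically: offset from the tail mean (last 10% of
points), amplitude from first-point-minus-tail, rate from a log-linear
regression of |signal − tail| over the early decay; the two-component fit
is seeded at $k/3$ and $3k$ with the amplitude split evenly. Convergence
uses a relative tolerance of 1e-8 on parameters with at most 500
iterations. Rates are bounded below by zero; double-fit rates are reported
sorted. Because the single model is nested in the double one, the double
fit is collapsed onto the single solution (and flagged) whenever the
optimiser fails to beat it, so SSR(double) ≤ SSR(single) holds by
construction.

Model choice is an extra-sum-of-squares F-test (default α = 0.05) with a
parsimony tie-break: the single model wins unless the improvement is
significant. Degenerate inputs are handled explicitly: a flat trace
returns amplitude ≈ 0 with a warning and an `amplitude_degenerate` flag
(the rate is unidentifiable), and non-convergence is always flagged, never
silent. Residual diagnostics (residual SD, lag-1 autocorrelation, runs
test) give the standard evidence that a single exponential suffices —
structured residuals flag a mis-specified model long before the F-test
does.

The $k_\mathrm{obs}$ regression is ordinary (unweighted) least squares,
matching a balanced replicate design; per-point SEs are recorded but not
used as weights. A negative fitted intercept is reported with a warning,
not clamped — clamping would bias the K_d column. Two-point designs are
allowed but warned about (the line is exact and SEs are undefined); the
published designs always have 3–4 concentrations.

## Equilibrium and competition solvers

One protein: closed-form quadratic, in the numerically stable form
$2RP/(b + \sqrt{b^2 - 4RP})$ with $b = R + P + K_d$, which avoids
cancellation when binding is tight. Two proteins: the free-RNA
concentration solves a monotone scalar mass-balance equation, found by
bounded root search on $[0, R_\mathrm{tot}]$ plus one Newton polish —
robust where picking the physical root of the equivalent cubic is not.
The ODE steady state and this closed form agree to better than 1e-6 µM
over randomised systems, which is the package's cross-check that the two
routes implement the same thermodynamics.

Competition is exposed twice on purpose: `equilibrium_partition()` answers
"who holds the RNA at equilibrium", `kinetic_partition()` answers "who
captures it first" via the instantaneous association-flux fractions
$k_{\mathrm{on},i}P_i / \sum_j k_{\mathrm{on},j}P_j$ (no rebinding). The
interesting biology is that the two answers cross between 0 and 50 µM
Mn²⁺ — the repressor dominates both at low metal, the activator at high —
and the qualitative claim is all the flux approximation is asked to carry;
the time-resolved answer is always available from
`simulate_binding_ode()`.

## Numerical choices and problem sizes

Tabulated rate constants (`rate_lookup()`) cover FRT·IRP1, ACO2·IRP1 and
FRT·eIF4F at 0/5/25/50 µM Mn²⁺; interpolation between metal levels, when
requested, is linear in log-rate (rates are positive and respond
multiplicatively). The tabulated values imply one internal inconsistency
worth knowing about: for FRT·IRP1 at 50 µM Mn²⁺ the rate ratio is
65/400 = 0.1625 and the implied $K_d$ is 184.6 nM, whereas derived tables
elsewhere print 0.20 and 227 nM; likewise ACO2 at 50 µM prints 727 nM
where the constants give 747.7. This package always computes ratios and
$K_d$ from the rate constants and does not attempt to reproduce the
derived-table variants. Similarly, `rate_parameters()` requires
$k_\mathrm{on} > 0$ (a zero association rate makes $K_d$ undefined);
"no binding" controls are represented by a negligible
$k_\mathrm{on}$ instead.

Suite and acceptance problem sizes were chosen for desk-scale runs: 1000
points per trace, 3–16 traces per pipeline, 100 random systems for the
equilibrium cross-check, and 50 seeds for the stochastic-recovery check
(median $k_\mathrm{on}$ bias < 3% at default noise). The whole test suite
runs in well under a minute.

## Known limitations

* The one-step model is an approximation the data happen to support;
  conformational intermediates faster than the dead time are invisible to
  it, and the package makes no attempt to detect them beyond the
  double-exponential comparison.
* KCl (ionic-strength) series are supported as a generic condition
  variable through the same table machinery, but no reference constants
  are bundled for them.
* Standard errors are first-order (local linearisation of the fit and OLS
  formulas); no error propagation beyond that, and no cross-condition
  hypothesis testing.
* The mass-action fitting bias discussed above means recovered rate
  constants from `mechanism = "mass_action"` titrations are *expected* to
  sit a few percent low at the published concentration ratios; use the
  relaxation mechanism when the question is the analysis chain, the
  mass-action one when the question is the approximation itself.
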