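---
title: "CSP titration analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSP titration analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftbind)
```

This vignette explains the science inside `shiftbind`: the binding model
and its assumptions, the statistics layered on top of it, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices a maintainer should know about.

## The fast-exchange CSP model

A protein P with a single weak site for a ligand L equilibrates as
P + L ⇌ PL with dissociation constant $K_d = [P][L]/[PL]$. When the
exchange rate between free and bound forms is much faster than the
chemical-shift difference between them (in frequency units) — always the
case for mM-range ion binding — each backbone amide shows *one* peak at
the population-weighted average position,
$\delta_{obs} = \chi_{free}\,\delta_{free} + \chi_{bound}\,\delta_{bound}$.
The observed perturbation of residue $r$ at total ligand $L_0$ and total
protein $T_0$ is therefore

$$\Delta\delta_{obs,r} = \Delta\delta_{max,r}\cdot
  \frac{T_0 + L_0 + K_d - \sqrt{(T_0 + L_0 + K_d)^2 - 4\,T_0 L_0}}{2\,T_0},$$

the exact quadratic-root solution of the 1:1 mass balance (`isotherm()`).
The bracket is the bound fraction; it is monotone and concave in $L_0$ and
never exceeds $\min(1, L_0/T_0)$. No ligand-excess approximation is made in
the fit, although in the regime this package targets (protein at ~0.1 mM
monomer, $K_d$ of several mM) the exact form and the hyperbola
$L_0/(L_0+K_d)$ differ by well under 0.1% — a property the test suite
verifies at $T_0/K_d = 10^{-3}$ across $L_0 \in [0, 100\,K_d]$.

Key assumptions, and when they break:

* **Fast exchange.** Peaks that broaden, disappear or double during the
  titration (intermediate/slow exchange) violate the model; such residues
  should simply be left out of the peak lists. The package does no
  lineshape analysis.
* **1:1 independent sites.** Each site is fitted separately with its own
  shared $K_d$; no competition or cooperativity between sites is modelled.
* **Per-monomer bookkeeping.** $T_0$ is the *monomeric* protein
  concentration, because the sites are defined per subunit. If you know
  the tetramer concentration, `fit_site(..., tetramer = TRUE)` applies the
  ×4 conversion.

## The combined CSP and the significance rule

Amide ¹H and ¹⁵N shifts move on very different ppm scales, so the two axes
are combined as
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 6.5)^2}$
(`combined_csp()`). The divisor 6.5 is the conventional ratio of amide
¹⁵N to ¹H shift dispersions; it is configurable (`scale_N`) since parts of
the literature use 5. CSPs are always referenced to the zero-ligand (apo)
spectrum, matched by assignment — there is no nearest-neighbour tracking
of unassigned peaks. A residue missing from one titration point is marked
untracked at that point only; a residue missing from the apo reference
cannot be referenced at all and is excluded with a warning.

Significantly perturbed residues at a point are those whose combined CSP
strictly exceeds the ensemble mean plus two sample (n−1) standard
deviations, both computed over the *tracked* residues at that point
(`significance()`). The strict inequality means a zero-variance profile
flags nothing. Two properties are worth knowing:

* The statistic is scale-equivariant: multiplying all shift changes by
  $c>0$ multiplies mean, sd and threshold by $c$ and leaves the flagged
  set unchanged (tested as an invariant).
* **The rule is descriptive, not a calibrated test.** Because the combined
  CSP of pure peak-position noise has a Rayleigh-like distribution, a
  residue exceeds the self-estimated mean + 2σ with probability of roughly
  4% regardless of the noise level, so on a panel of $n$ residues the
  chance of at least one spurious flag grows quickly with $n$ (it is the
  norm, not the exception, for $n \gtrsim 20$). Conversely, for panels of
  five or fewer the flag can never fire at all, since the largest
  studentized deviation in a sample of $n$ is bounded by $(n-1)/\sqrt n$.
  Flags should therefore be read as "residues that stand out from this
  panel", to be confirmed by the titration fit — not as hypothesis tests
  with a controlled false-positive rate.

The cation-vs-salt comparison (`salt_comparison()`) evaluates both
profiles at a matched ligand concentration (nearest point within 10%),
reports each profile's mean ± sd of $\Delta\delta_H$ — the statistic used
to characterise bulk solvent/susceptibility effects — and defines the
cation-specific set as the residues flagged in the test titration but not
in the control.

## Global fitting: parameters, initialisation, uncertainties

`fit_site()` minimises
$\sum_{r}\sum_{j}\left(\Delta\delta_{obs,r,j} - \Delta\delta_{max,r}\, b(L_j; K_d)\right)^2$
over one shared $K_d$ and one amplitude per residue, using bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`). The fitted observable is the
combined CSP with a single amplitude per residue, not separate H/N fits;
because both axes scale with the same bound fraction, the combined
statistic is itself exactly isotherm-shaped. Numerical choices:

* **Bounds**: $K_d \in (0, 10^4]$ mM, $\Delta\delta_{max} \in [0, 10]$
  ppm — generous physical ranges that keep the optimizer out of
  pathological corners.
* **Initialisation**: $K_d$ starts at the ligand concentration of
  half-maximal mean site CSP (linear interpolation between bracketing
  points); amplitudes start at each residue's largest observed CSP. Three
  $K_d$ starts log-spaced over a 100-fold range around the half-max guess
  guard against local minima; the best-deviance solution wins.
* **Zero-ligand points are kept in the fit** — they pin the baseline.
* **Under-determination is an error**: every site residue must be tracked
  at ≥ 3 points, and observations must outnumber parameters.
* **Non-convergence is a result, not an exception**: the returned object
  carries `converged = FALSE` plus optimizer diagnostics.
* **Uncertainties**: the parameter covariance is
  $\hat\sigma^2 (J^\top J)^{-1}$ with $J$ the central-difference Jacobian
  at the optimum and $\hat\sigma^2$ the residual variance; `kd_se` and
  `dmax_se` are its square roots. Replicate-simulation tests check that
  the empirical scatter of recovered $K_d$ agrees with the mean reported
  standard error within a factor of two.
* **Fit quality**: $R^2 = 1 - SS_{res}/SS_{tot}$ pooled over all
  residue-point observations. The p-value is an F-test of the fitted
  isotherm against the all-zero (no binding) model. This is a deliberate,
  documented interpretation: "p-value of a titration fit" has no single
  standard definition, and the F-test against no-binding is the natural
  null here.

`fraction_bound()` uses the ligand-excess hyperbola
$\chi_{bound} = L/(L+K_d)$, appropriate when free ligand ≈ total ligand
(ion at mM, protein at µM); the default physiological calcium
concentration in `run_pipeline()` is 2.4 mM, the normal extracellular
level. Reported percentages and folds (`kd_ratio()`) round half away from
zero, so 3.76-fold prints as the conventional "4-fold".

## Ion-contact persistence

`persistence()` counts, per residue, the frames in which any ion lies
within a distance cutoff of any of the residue's atoms, and reports the
fraction as an exact frame-count ratio. Defaults follow the field's
conventions for Ca²⁺: cutoff 3.5 Å (first coordination shell) and
persistence threshold "strictly more than 50% of frames". The atom scope
can be restricted to backbone or side-chain atoms (to distinguish, e.g.,
carbonyl vs carboxylate coordination), and hydrogens can be excluded for
a heavy-atom criterion; by default all atoms are included, since a plain
"within 3.5 Å of the protein" criterion does not restrict atom type.

Ions in PDB input are selected by *residue* name (default `CA`/`CAL`),
never by atom name, because the PDB atom name "CA" collides with alpha
carbons; a warning notes when such a collision was present. No periodic
minimum-image correction is applied — the trajectory is assumed wrapped
upstream — but if the file carries a CRYST1 box, any ion–protein distance
exceeding the box diagonal triggers a warning. Multi-model files with
mismatched atom counts across MODELs are rejected outright; a file
without MODEL records is treated as a single frame with a warning.

## What the synthetic generators emulate — and what they don't

`simulate_titration()` reproduces the *design* of a weak-binding NMR
titration: 8 points at 0, 5, 10, 20, 40, 60, 80, 100 mM ligand, 0.1 mM
protein monomer, two sites with $K_d$ 8.7 and 13.5 mM read out by 2 and 3
residues, saturation amplitudes giving combined CSPs of 0.05–0.3 ppm (the
plausible range for ion binding; real per-residue amplitudes are not
published for the motivating system, so these are explicitly synthetic),
plus a panel of inert residues. Peak positions get independent,
homoscedastic Gaussian noise of σ_H = 0.002 ppm and σ_N = 0.01 ppm — the
typical digital resolution of 2D correlation peak positions. An optional
dropout rate marks residues untracked at random non-reference points,
emulating overlap/broadening losses; the apo panel stays complete because
a residue absent from the reference would leave the profile entirely
rather than model point-wise loss.

What is *not* emulated: lineshapes, peak overlap and mis-assignment,
exchange-regime transitions, temperature or pH drift between points,
correlated (systematic) shift errors, and dilution (real titrations keep
volume changes ≤ 1.5%, a negligible effect). Passing tests on this
generator therefore demonstrate the *estimator's* correctness and
calibration under the stated noise model — they do not certify robustness
to assignment errors or exchange-regime violations in real spectra.

`simulate_trajectory()` is a purely geometric construction: single-atom
residues on a 10 Å grid and one ion placed within 0.9 × cutoff of a
residue in exactly the prescribed number of frames (and > 3 × cutoff from
everything otherwise), so contact fractions are exact rationals by
construction. Demands exceeding one contact per frame are resolved at the
grid midpoint only when the cutoff reaches it (≥ 5 Å); otherwise the
construction refuses. There is no physics in these trajectories; they
exist to make persistence arithmetic exactly checkable.

## Problem sizes used by the test suite

The suite fits ~50 simulated titrations per scenario for recovery and
coverage checks, 100 noise-only titrations for the null-calibration
measurement, 30 replicates for the standard-error calibration, and 20
random instances for the brute-force-oracle comparison; these sizes give
stable medians and proportions while keeping the whole suite fast enough
to run on every change. The brute-force $K_d$ oracle (400-point log grid
with analytically profiled amplitude, polished by golden-section search)
and the all-pairs persistence oracle are implemented independently in the
test helpers and share no code with the package internals.

## Known limitations

* The mean + 2σ flagging rule has no controlled false-positive rate (see
  above); the package reports it because it is the field's convention,
  and the titration fit is the confirmatory step.
* Standard errors are Wald-type (local curvature); for strongly
  correlated $K_d$/amplitude posteriors at sparse designs, profile
  likelihood or bootstrap would be more faithful. The `simulate()` method
  on a `site_fit` provides the building block for a parametric bootstrap.
* Salt screening is handled by fitting each condition separately and
  comparing $K_d$; no ternary protein–ligand–salt thermodynamics.
* Trajectory analysis assumes wrapped coordinates and matching atom
  tables across frames; it does no alignment, clustering or energetics.
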