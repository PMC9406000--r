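# shiftbind

Quantifying weak protein–ligand binding from NMR chemical shift
perturbations.

## The problem

Many physiologically meaningful protein–ion interactions are *weak*:
dissociation constants in the millimolar range, far beyond what ITC or SPR
resolves comfortably. 2D ¹H–¹⁵N correlation spectroscopy sees them
residue-by-residue: as ligand is titrated in under fast exchange, each
backbone amide cross-peak moves continuously from its free position toward
its bound position, and the size of that movement maps the binding surface.
The motivating case is calcium binding to transthyretin, a plasma transport
protein whose Ca²⁺-bound fraction — though small — is more susceptible to
the proteolytic cleavage that triggers amyloid aggregation.

`shiftbind` implements the complete quantitative workflow for this kind of
study, for NMR spectroscopists and structural biologists:

1. **Peak-list I/O** — read assigned Sparky-style `.list` files or a
   long-format shift CSV, one table per titration point
   (`read_sparky_list()`, `read_shift_csv()`).
2. **CSP profiling** — per-residue combined perturbation against the apo
   reference, Δδ = √(Δδ_H² + (Δδ_N/6.5)²), with per-point tracking flags
   (`build_profile()`), significance flagging by the mean + 2σ rule
   (`significance()`), and cation-vs-salt specificity comparison
   (`salt_comparison()`).
3. **Global Kd fitting** — the core of the package. For a binding site
   reported on by residues r = 1…R, the observed CSPs at total ligand L₀
   and total protein (monomer) T₀ follow the exact 1:1 isotherm

   Δδ_obs,r(L₀) = Δδ_max,r · [ (T₀+L₀+K_d − √((T₀+L₀+K_d)² − 4·T₀·L₀)) / (2·T₀) ]

   fitted as one system of equations with a single shared K_d and one
   amplitude per residue (`fit_site()` → a `site_fit` model object with
   `print`, `summary`, `coef`, `vcov`, `confint`, `predict`, `fitted`,
   `residuals`, `plot`, `simulate` methods).
4. **Physiological interpretation** — occupancy at a given free ligand
   concentration (`fraction_bound()`) and fold changes between salt
   conditions (`kd_ratio()`).
5. **MD contact persistence** — per-residue fraction of trajectory frames
   with an ion within a distance cutoff, from multi-model PDB coordinates
   (`read_multimodel_pdb()`, `persistence()`).
6. **Synthetic data** — ground-truth-known generators for titrations and
   contact-patterned toy trajectories (`simulate_titration()`,
   `simulate_trajectory()`), used throughout the tests.
7. **Orchestration** — `run_pipeline()` drives input → CSP → significance →
   fits → occupancy (→ contacts) from a config list or YAML file and writes
   a structured JSON report (`validate_report()`).

## Worked example

A synthetic calcium titration (8 points, 0–100 mM, 0.1 mM protein monomer,
two binding sites with true K_d 8.7 and 13.5 mM, realistic peak-position
noise), profiled and fitted:

```r
library(shiftbind)
sim  <- simulate_titration(titration_sim_spec(seed = 1))
prof <- build_profile(sim$tables)
significance(prof, 8)
#> CSP significance at 100 mM (25 tracked residues):
#>   mean = 0.0220 ppm, sd = 0.0424 ppm, threshold (mean + 2 sd) = 0.1068 ppm
#>   flagged residues: 10, 99

fit <- fit_site(prof, ttr_sites()[["site-1"]], T0 = 0.1)
summary(fit)
#> 1:1 isotherm fit, site 'site-1' (2 residue(s), 16 observations)
#>   Kd = 8.619 +/- 0.229 mM
#>   R^2 = 0.9993, p = 9.35e-25
#> parameters (mM for kd, ppm for dmax):
#>         estimate      se
#> kd       8.61860 0.22933
#> dmax_66  0.09967 0.00086
#> dmax_99  0.16937 0.00108
```

The fit recovers the true K_d of 8.7 mM within one standard error; the
flagged residues are exactly those whose saturation amplitude clears the
ensemble threshold. Translating a fitted K_d into in-vivo terms — at the
normal extracellular calcium concentration of 2.4 mM, with the
high-salt-condition site-1 K_d of 32.7 mM:

```r
fraction_bound(2.4, 32.7)
#> occupancy at 2.4 mM ligand (Kd = 32.7 mM): fraction bound 0.0684 (~7%)
kd_ratio(32.7, 8.7)
#>     fold  rounded
#> 3.758621 4.000000
```

i.e. about 7% of the protein is ligand-bound at physiological calcium, and
physiological salt weakens the site roughly 4-fold by electrostatic
screening.

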