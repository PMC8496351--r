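---
title: "A seven-compartment model of the ex vivo cotyledon perfusion assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A seven-compartment model of the ex vivo cotyledon perfusion assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotyledonsim)
library(dplyr)
```

## The assay and the model

In the dual (ex vivo) perfusion assay, a single cotyledon of a delivered
human placenta is cannulated on both sides and perfused with
protein-supplemented buffer: a maternal circuit bathes the intervillous
space and a fetal circuit runs through the villous capillaries. Drug placed
in one reservoir washes across the trophoblast layer and appears in the
other; the two reservoir concentration–time curves carry the information
about placental transfer.

`cotyledonsim` represents this assay as seven well-stirred compartments
arranged as a tree:

```
M_res -- M_perf -- M_int
              \
               F_cell -- F_int -- F_perf -- F_res
```

maternal reservoir, maternal perfusate in the intervillous space, the
intervillous interstitial (septal) tissue, the trophoblasts, the
intravillous interstitial stroma, the fetal capillary perfusate, and the
fetal reservoir. The decidua has no compartment: it is shed at delivery and
rinsed off during preparation, so it is not part of the perfused cotyledon.
This compartmentalization deliberately mirrors the placenta sub-structure
of maternal–fetal whole-body PBPK models, so that parameters learned here
can be copied across (`export_parameters()`).

Six exchange links connect the compartments. Reservoir–cotyledon exchange
on each side is flow-limited, `Q (C_res − C_perf)`. Perfusate–interstitial
exchange on each side is permeability-limited across the endothelium,
`fu · P_endo · SA · (C_perf − C_int/K_int:perf)`, with the endothelial
permeability set high (100 cm/min) so it is never rate-limiting — for
efflux-transporter substrates a user would lower it. The basolateral
trophoblast flux balances free water concentrations,
`P · SA · (C_int · fu_fetus/K_F_int:perf − C_cell · fu/K_F_cell:perf)`, and
the apical flux carries the model's asymmetry:

    P · SA_villi · fu · ( f_in · C_M_perf − f_out · C_F_cell / K_FM_cell:perf )

`f_in` and `f_out` are dimensionless factors scaling the apical
permeability in the maternal→fetal and fetal→maternal directions; unequal
values encode asymmetric transfer. Every link flux is bilinear in
concentrations, so the whole system is linear, `dN/dt = E C`, with a 7×7
exchange matrix `E` (`exchange_matrix()`) whose columns sum to zero — mass
conservation is structural, not numerical.

## Physicochemistry

The fraction unbound is scaled between fluids with different albumin
content by the linear-binding relation implemented in
`scale_fraction_unbound()`: the bound:free ratio is proportional to the
binder concentration. With an adult reference of 0.82 at 47 g/L albumin,
the maternal (40 g/L BSA) and fetal (30 g/L BSA) perfusates give 0.84 and
0.88. The reference concentration of 47 g/L is a calibration choice: it is
the value at which the adult unbound fraction maps onto those two printed
perfusate values, and bovine and human albumin are treated as equivalent
binders.

Interstitial:perfusate partition coefficients come from a
protein-corrected water-partitioning expression
(`partition_interstitial_perfusate()`): water fractions 0.935
(interstitial) and 0.926 (perfusate), with an interstitial:perfusate
protein ratio of 0.37 taken from adult tissue. The same functional form is
used on the maternal side with the maternal fraction unbound — a documented
approximation, since the general tissue-composition equation reduces to
this form for protein-and-water tissue.

The trophoblast cell:perfusate coefficient is computed by the
Rodgers–Rowland tissue-composition method (`partition_cell_perfusate()`),
neutral/weak-electrolyte branch: intracellular water partitions according
to the ionization ratio between intracellular pH 7.0 and perfusate pH 7.4,
neutral lipids scale with `10^logP`, and phospholipids with
`0.3·10^logP + 0.7`. Strongly basic drugs, whose partitioning is dominated
by acidic-phospholipid association, are outside the implemented branch and
raise an error; so do the alternative partition methods whose interface
slots are reserved (`schmitt`, `poulin`, `pksim_standard`). The bundled
placental composition preset (`placenta_composition()`) is a synthetic
best-effort set — intracellular water 0.85, neutral lipids 0.010,
phospholipids 0.006 — chosen as typical soft-tissue values because no
placenta-specific composition table is bundled; every field is
overridable, and the acetaminophen coefficient it produces (≈ 0.74) is
asserted in tests only against a ±0.05 band around the composition-based
literature estimate of 0.76.

## Defaults and units

All computation is carried out in mg, L, min and dm (permeabilities
dm/min, areas dm², concentrations mg/L); `to_canonical()` converts common
laboratory units, and configuration files must declare a unit on every
numeric field — a missing unit is an error, never a guess. Because the
system is linear, mass- and molar-based formulations are equivalent.

The assay constants default to: flows 14 / 6 mL/min (maternal / fetal),
reservoir volumes 280 / 284 mL, intervillous / intravillous cotyledon
volumes 23 / 35 mL, and a villous surface area of 1178/35 ≈ 33.7 dm² (the
term-placenta total divided by the ~35 cotyledons). Two sets of constants
are not experimentally anchored and are therefore configurable defaults:
the sub-volume fractions splitting the cotyledon sides (0.80/0.20
perfusate/interstitial intervillously; 0.50/0.30/0.20
trophoblast/interstitial/capillary intravillously) and the surface-area
density of the internal interfaces (1000 dm² per litre of adjoining tissue
volume). Both shape only the fast transients: steady-state levels depend
on flows, partition coefficients and the `f` factors alone, which is why
the estimation results are robust to them.

## Simulation and the analytic oracle

`simulate_perfusion()` integrates the system from a dose placed entirely
in one reservoir. Two paths are implemented. The default is `lsoda`, a
stiff-capable integrator (the endothelial links are orders of magnitude
faster than the reservoir wash-out, so the system is stiff) at rtol 1e-8 /
atol 1e-10. The second path, `eigen`, solves the linear system exactly by
eigendecomposition of the rate matrix; it is hundreds of times faster and
is what the fitting loop uses. The two paths are cross-checked in the test
suite. Concentrations within 1e-9 of zero (relative to the trajectory
maximum) are snapped to exact zero so that relative-error metrics see true
zeros — the un-dosed reservoir at t = 0 being the practically relevant
case. Total mass drift beyond 1e-6 relative raises an error.

Because the compartment graph is a tree, the steady state solves six
zero-flux equations plus mass balance in closed form (`steady_state()`).
Back-substitution from the maternal perfusate gives, among others,
`C_F_cell = K_FM_cell:perf · (f_in/f_out) · C_M_perf`: with the fitted
parameter set (K = 4.31, f_in = 0.060, f_out = 0.051) the trophoblast
concentration sits 4.31 · 0.060/0.051 ≈ 5.07-fold above the maternal
perfusate at steady state, while the partition coefficient itself is the
4.31-fold cell:perfusate ratio at equal free-water driving concentrations.
The analytic solution doubles as an independent oracle: the test suite
checks it against long-horizon integration for 100 randomized valid
systems, and `f_out = 0` with `f_in > 0` — a one-way valve into the
trophoblast, with no finite joint steady state — is flagged explicitly.

## Parameter estimation

Four nested scenarios are supported (`fit_scenario()`): a single symmetric
factor `f`; asymmetric `f_in`/`f_out`; either of those plus a shared
trophoblast partition coefficient `K = K_FM_cell:perf = K_F_cell:perf`.
Freeing `K` is the mechanism that lets the model move drug out of the
reservoirs into the trophoblasts without modeling metabolism.

The loss is relative, so the washed-in and washing-in reservoirs — whose
concentrations differ by orders of magnitude early on — contribute
comparably. Two residual conventions are implemented
(`transfer_objective()`): `(pred − obs)/obs` and `log(pred/obs)`. The
fitting default is the log-ratio form because it is exactly the least
squares implied by a multiplicative lognormal error model, which is both
what bioanalytical assay error looks like and what the campaign generator
produces. This choice matters beyond aesthetics: with 1/obs weighting the
expectation of `1/obs` under lognormal noise exceeds `1/E[obs]` (a Jensen
effect), which pushes fitted predictions a few percent low; mass
conservation converts that small push into a substantial upward bias in
the weakly identified `K` (the reservoirs can only drop by storing more in
the trophoblasts). Log-ratio residuals with median-centred noise have no
such term, and recovery simulations confirm the estimator is unbiased.
Observations equal to zero carry no relative-error information and are
excluded (counted in the fit object).

The optimizer is multi-start: `n_restarts` (default 50) log-uniform draws
within the bounds (`f` factors in [1e-4, 10], `K` in [0.01, 100]), the
best five starts refined by bounded Levenberg–Marquardt on the
log-parameter scale, and one further refinement from the winner. A
least-squares polish was chosen over derivative-free simplex search after
direct comparison: the (f_in, f_out, K) objective forms a narrow curved
valley — the factors and the partition coefficient are strongly correlated
— in which Nelder–Mead stalls far from the optimum, while
Levenberg–Marquardt reaches machine precision from almost any start. The
finite-difference step of the Jacobian is kept well above the linear
solver's noise floor. With a fixed `seed` the whole procedure is bitwise
reproducible.

Confidence intervals are linearized: central-difference Jacobian of the
residuals at the optimum, `cov = σ² (JᵀJ)⁻¹` with `σ² = loss/(n − p)`,
half-widths `1.96·se`. A singular Jacobian yields flagged `NA` intervals
rather than silent numbers, and the estimate correlation matrix is
reported with a warning above |r| = 0.95 — which the scenario-4 fit
routinely triggers, reflecting the genuine weak identifiability of
permeability factors versus partitioning noted for this assay design.
`mpe()` and `mape()` implement the signed and absolute mean prediction
error in percent; MAPE ≥ |MPE| always.

## Synthetic campaigns

`generate_campaign()` emulates the acetaminophen perfusion series: 14
experiments (10 maternal-dosed, 4 fetal-dosed), initial concentration
10 mg/L, both reservoirs sampled, multiplicative lognormal noise with 10%
CV (`obs = pred · exp(N(0, s))`, median-1 multiplier, the standard
proportional-error model). The default schedule has 15 points over 0–180
min, dense during wash-in — {0, 2, 5, 10, 15, 20, 30, 45, 60, 75, 90, 105,
120, 150, 180} — giving 28 series and 420 values, close to the source
campaign's ≈25 values per series; the published schedule itself is not
available. The generating parameters ride along as a truth record
(`campaign_truth()`) so recovery can be verified.

What the generator does *not* emulate is worth stating: adsorption to
tubing, sampling-volume loss, placental metabolism, LLOQ censoring,
between-cotyledon variability, and any misspecification between the model
and the real assay. Passing recovery tests therefore demonstrate that the
estimation machinery is correct and well-calibrated under the model's own
assumptions — not that the model is a complete description of a real
perfusion experiment.

## Sensitivity analysis and export

`local_sensitivity()` sets both trophoblast partition coefficients to each
value of a grid (default {0.76, 2.5, 4.31}: the composition-based
estimate, an intermediate value, and the fitted value), holds everything
else fixed, and reports the pooled mean prediction error over all
residuals jointly, plus per-experiment errors. On data generated at
K = 4.31 the pooled MPE falls monotonically along that grid — higher K
stores more drug in the trophoblasts and lowers the simulated reservoir
plateaus — reaching zero at the generating value. The corresponding
published errors against the digitized assay data are reproducible only if
a user supplies that data; the machinery accepts any observed-data table.

`export_parameters()` assembles what a maternal–fetal PBPK model needs:
the four partition coefficients, effective directional apical
permeabilities `f_in·P` and `f_out·P` (for acetaminophen ≈ 2.6×10⁻³ and
≈ 2.2×10⁻³ cm/min against the unmodified 4.29×10⁻² cm/min), the total
villous surface area (default 1178 dm²) the whole-placenta transfer rate
scales with, the per-cotyledon area, and the fetal fraction unbound at
delivery recomputed from fetal albumin (32 g/L → 0.87). The export
annotates that no cotyledon-derived parameter exists for the decidua
compartment of the PBPK model.

## Numerical choices and limitations

Problem sizes in the test suite are deliberately desk-scale: recovery
checks use campaigns of 3–6 experiments and 10–15 restarts, the full
14-experiment, 50-restart fit is exercised once, and the oracle property
runs 100 randomized systems — the eigendecomposition path makes all of
this cheap.

Known limitations: no placental metabolism (accumulation via `K` is the
chosen surrogate, and the two are confounded in reservoir data); no
endothelial-cell compartment (a lowered `P_endo` can mimic the transfer
resistance but not accumulation there); no saturable transport; the
composition preset is generic soft tissue rather than measured placenta;
and the interface surface areas are defaults, not measurements. The
sensitivity analysis is local by design — a single-parameter grid, not a
variance-based global method.
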