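---
title: "Modelling pH-mediated microbial interactions with phfeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pH-mediated microbial interactions with phfeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Bacteria change the pH of their surroundings — urea cleavage alkalizes,
fermentation acidifies — and the pH in turn gates their growth. `phfeedback`
studies the feedback loop this creates, for one or two species sharing one
environmental variable. The state is `(n_a, n_b, p)`: two population
densities and an abstract proton concentration `p` confined to `[0, 2b]`.
High `p` displays as low pH; the display axis is the reversed linear map
`pH = 11 - 0.9 p` (a convention, not log-chemistry).

Each density follows logistic growth whose rate factor is a Gaussian
function of `p`:

$$\frac{dn_i}{dt} = n_i\left(1 - \frac{n_i}{K}\right)
  \left(e^{-(p - p_{\mathrm{pref},i})^2/\sigma_i^2} - \delta_i\right),$$

so growth peaks at the preferred proton concentration
$p_{\mathrm{pref},i}$, falls off with niche width $\sigma_i$, and turns
into net death (at most rate $\delta_i$) far from the optimum. The
populations drive the proton concentration in proportion to their density:

$$\frac{dp}{dt} = \Big(\sum_i c_i\, d_i\, n_i\Big)\, q(p), \qquad
  q(p) = \frac{p\,(2b - p)}{b^2},$$

with `c_i` the signed per-density drive (positive = acidifier), `d_i` a
relative drive strength used in coculture comparisons, and `q(p)` a
quadratic boundary factor that pins `p` to `[0, 2b]` (the chemical-potential
limit on how far a cell can push its environment). The `1/b^2`
normalization is this package's declared convention: it makes `q(b) = 1`,
so `c` reads directly as the mid-scale proton change per unit density per
unit time. The constant is exposed (`boundary_norm`) for sensitivity
analyses.

### Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `p_pref` | preferred proton concentration | species-specific | proton scale |
| `sigma`  | niche width | 4 | proton scale |
| `delta`  | maximal death rate | 0.5 | 1/time |
| `c`      | proton drive | ±0.1 | proton units / (density · time) |
| `d`      | relative drive strength | 1 | — |
| `K`      | carrying capacity | 10 | density |
| `b`      | half-range of the proton scale | 5 | proton scale |

The four shipped archetypes span the 2 × 2 design of drive direction ×
self-effect: `Lp` (acidifier preferring acid, `p_pref = 8`), `Ca`
(alkalizer preferring alkali, `p_pref = 2`), `Pv` (alkalizer preferring
acid, `p_pref = 8`), and `Sm` (acidifier with a mildly alkaline optimum,
`p_pref = 3.5`). The niche optima of `Lp`, `Ca` and `Pv` are declared
assumptions — the archetype classification (which side of neutral, which
drive direction) is what matters, not the exact numbers — while `Sm`'s 3.5
is fixed by the single-species suicide scenario the model is checked
against.

### Domain restrictions worth knowing

Two artifacts of the logistic-times-rate-factor form shape several
defaults:

* `n = K` is an invariant manifold — at exact carrying capacity the
  density never moves, whatever the pH, because the death term carries the
  same `(1 - n/K)` factor. Initial-density grids therefore top out at
  `K/2`; a grid row at exactly `K` would survive artificially.
* For `n > K` with a negative rate factor the same term flips sign and
  densities diverge in finite time. Inocula above carrying capacity are
  outside the model's domain and `integrate_batch()` rejects them.

## Simulation

`integrate_batch()` integrates the system with `deSolve::lsoda`
(`rtol = 1e-8`, `atol = 1e-10`). The right-hand side carries one-sided
guards at the absorbing boundaries (zero growth source for non-positive
densities, zero proton drive outside the scale) so that states pushed a
rounding error across a boundary cannot re-enter the dynamics with the
wrong sign; extinction is absorbing. A deliberately simple fixed-step
Euler integrator (`integrate_euler()`) ships as a cross-validation oracle
and the test suite holds the two to within `1e-3` relative at trajectory
endpoints.

`run_serial_transfer()` models daily batch-transfer culture: grow for
`cycle_length` time units (default 5, the nominal image of a 24 h cycle —
a convention, not a calibration), then divide densities by the dilution
factor `D` and reset the proton concentration to
`p/D + ((D-1)/D) p0` with `p0` the fresh-medium value; the pre-transfer
`p` enters the mixing formula. Dilution interacts non-monotonically with
ecological suicide: moderate `D` rescues a self-poisoning population
(the environment is refreshed faster than it is ruined) while large `D`
outdilutes it.

```{r, eval = FALSE}
library(phfeedback)
arc <- archetype_species()
tr <- run_serial_transfer(system_state(0.1, 0, p = 9),
                          arc$species$Pv, NULL,
                          ph_environment(b = 5, p0 = 9),
                          transfer_protocol(dilution_factor = 3,
                                            n_cycles = 12))
tail(tr[tr$event == "pre_dilution", ])
```

## Phase diagrams and motif labels

`sweep_single()` and `sweep_pair()` integrate every cell of an
initial-condition grid and classify survival at the horizon (default
threshold `1e-3 K`; a sensitivity test verifies the archetype
classifications are unchanged from `1e-2 K` to `1e-4 K`). Defaults: 21
log-spaced densities in `[1e-4 K, K/2]` (single) or 21 fractions at total
inoculum `N = 1 = 0.1 K` (pair), 21 initial proton values in `[0.5, 9.5]`,
horizon 200. The horizon is set by the model's own slow time scales:
suicide from the smallest inocula completes around `t ≈ 130`, and the
coculture limit cycles (below) have period ≈ 65, so the end-of-run state
at `t = 200` reflects the asymptotic outcome. Oscillation is flagged when
a surviving species shows at least two density maxima in the final 60% of
the run, a window wide enough for two cycle periods.

`label_motif()` turns one pair diagram plus the two single-species
diagrams into a motif label using ordered, explicit rules (stabilization,
successive growth, extended suicide, bistability, coexistence, exclusion
— see its help page for the exact cell conditions). All matching rules
are reported; a multi-match resolves to the first in order and is
messaged, never silent. With the shipped archetypes the four canonical
pairs label as `bistability` (Lp + Ca), `successive_growth` (Sm + Lp),
`extended_suicide` (Pv + Lp) and `stabilization` (Pv + Sm).

One coculture needs a drive asymmetry: with `d = 1` both ways, Pv and Lp
are mirror species (identical niches, exactly opposite drives), their
density ratio locks, and the pair coexists statically everywhere — no
murder-suicide region at all. The shipped pair list therefore gives the
suicidal alkalizer `d = 2` in that pairing, the minimal asymmetry that
produces the expected diagram: joint extinction over most of the plane
and, at low suicidal-species fractions, a limit cycle (period ≈ 65) in
which the victim repeatedly rescues the pH and the killer recovers —
oscillatory coexistence.

## Stability analysis

`find_fixed_points()` enumerates the analytic candidates (densities at 0
or `K`; `p` at the scale ends or at the Gaussian roots
`p_pref ± sigma * sqrt(log(1/delta))`), polishes each with damped Newton
iterations on the exact right-hand side using the analytic Jacobian
(`jacobian_at()`, itself cross-checked against central finite
differences), deduplicates within `1e-6`, and keeps points with residual
below `1e-9`. Classification is by eigenvalue real parts with
hyperbolicity tolerance `1e-8`. The sterile set `n = 0` is a continuum of
fixed points: representatives are reported at grid nodes, always as
non-hyperbolic, with a separate transverse (invasion) classification. For
the bistable pair the two single-winner boundary states are the only
stable points and each attracts a `1e-3`-perturbed simulation,
consistent with the phase diagram.

## The fuzzy-logic counterpart

The fuzzy backend replaces the differential equations with 200
synchronous rule-based updates, showing the interaction structure does
not depend on the Gaussian/logistic functional forms. Inference is
classical Mamdani: min for AND, max for aggregation, centroid
defuzzification, over trapezoidal membership partitions declared in
`inst/extdata/fuzzy.yaml` (pH on the display scale 0–14 with label
crossovers at 6.2 and 8.2; density normalised to `[0, 1]`).

Growth rules compare the fuzzified current pH with the species'
fuzzified preferred pH: same label → positive per-capita change, adjacent
→ zero, distant → negative, and high density saturates growth (the fuzzy
carrying capacity). pH rules map density to a change magnitude (more
bacteria, faster change), signed per species and damped by the display
image of the ODE's quadratic boundary factor. Two choices required care:

* the magnitude output universe is symmetric about zero with a 'none' set
  centred at 0, so that zero cell density defuzzifies to exactly zero pH
  drive — on a one-sided universe the centroid of 'none' is positive and
  extinct populations keep pushing the pH, eventually resurrecting
  themselves;
* the pH-label crossovers sit away from the display image of the neutral
  point, so no grid state is inference-dead (exactly zero density change
  and zero drive forever).

The per-iteration gains (0.18 per-capita density, 0.7 pH) set the fuzzy
model's time scale relative to its fixed 200-iteration budget. They were
calibrated once, against the qualitative behaviour the backend must
reproduce — the four archetype pair motifs on matched grids, single-species
Allee and suicide fates, and a stabilization region at least as wide as
the ODE backend's (the coarseness of fuzzy labels makes mutual rescue
more forgiving, which is exactly the property of interest) — and then
frozen; the acceptance suite asserts those properties at these defaults.

## Characterization and prediction

`fit_ph_response()` estimates a species' niche from a fold-growth vs
starting-pH table by nonlinear least squares of
`log(fold) = A exp(-(p - p_pref)^2 / sigma^2) + k` (Levenberg–Marquardt,
`minpack.lm`), with `delta = -k/A`. Log-transforming stabilises the
variance and makes `p_pref`/`sigma` estimates exactly invariant to
rescaling all fold values; `delta` additionally requires absolute
final/initial ratios (fold < 1 = net death is what identifies it). Flat
tables are flagged degenerate rather than fitted. `estimate_ph_drive()`
takes the median endpoint shift with a 0.1-pH-unit noise floor.

`predict_pair_motif()` is the package's explicit reconstruction of the
narrative prediction rule: classify each species as self-serving or
self-harming according to whether its drive moves `p` from the assay
starting point (display pH 7) toward its own optimum, then map the pair
of classes — both self-serving and opposed → bistability; both
self-harming and opposed → stabilization; a self-harmer whose drive
conditions the environment for its partner → successive growth, against
the partner → extended suicide; both self-serving and aligned → plain
competition. The direction test is evaluated at the assay starting pH
only; drives that reverse their benefit beyond the optimum are out of
scope. On synthetic assays near the archetypes this shortcut agrees with
the full sweep-and-label route in every one of 50 seeded pairs tested.

## Synthetic data

The generator emulates the package's three input table kinds with known
ground truth, always emitted alongside the noisy values. Fold-growth
tables freeze `p` during growth (the buffered assay's purpose) and use
the low-density exponential fold `exp(T g(p))` with lognormal noise
(default sd 0.1). Endpoint tables run one batch cycle and add Gaussian
meter noise (sd 0.05 display units). Serial-transfer records emit, per
day and species, Poisson colony counts over a 1/10 dilution series (8
steps, 10 µL-equivalent volume, counts capped at 300 per spot as
countable), the CFU estimate back-calculated from the first countable
step, and a noisy pH reading. With the default `1e6` cells per model
density unit the plating detection limit sits at `1e-4` density units,
two decades below the extinction threshold, which is why survival flags
recover essentially perfectly from the noisy records. All noise
magnitudes are invented defaults (none are reported for the real assays)
and are config keys.

What the generator does **not** emulate: growth saturation in the
fold-growth assay, colony-morphology confusion between species, plate-level
overdispersion beyond Poisson, pH meter drift. Passing recovery tests
therefore demonstrate the estimators are correct and well-conditioned
under the declared noise model, not that they are robust to every
real-world artifact.

## Problem sizes

Default analyses use 21 × 21 grids per phase diagram (441 integrations,
a few seconds each diagram), 1000-point brute-force scans as bisection
oracles, and recovery studies of 100 tables / 50 pairs / 100 transfer
records; the end-to-end consistency study runs its sweeps on 9 × 9 grids.
These sizes were chosen so a full reproduction completes in minutes on a
laptop while keeping every classification far from its decision
boundaries.

## Known limitations

* One environmental variable; no buffering kinetics, oxygen, or nutrient
  depletion. The framework is generic in the environmental parameter, but
  this implementation is single-variable.
* Quantitative phase-diagram extents depend on the declared archetype
  optima and the `d = 2` murder-suicide asymmetry; only the qualitative
  motif structure is asserted.
* The fuzzy backend's neutral 'zero' band can leave slow-starving states
  above the extinction threshold at iteration 200 in a few cells of a
  single-species diagram; the per-cell motif rules are robust to these
  stragglers, but single-species fuzzy labels near the neutral pH should
  be read with the 200-iteration window in mind.
* The motif vocabulary is an end-state classification; transient
  structure (e.g. how long successive growth takes) is visible in
  trajectories but not in the labels.
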