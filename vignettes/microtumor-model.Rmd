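---
title: "The microtumor compartment model: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microtumor compartment model: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtumor)
```

## The scientific question

In 3D tumor spheroids a few hundred micrometres across, nutrient and
oxygen supply decays from the surface toward the core. Proliferating
(Ki-67-positive) cells occupy a broad outer zone, but the serine-synthesis
enzyme PHGDH is expressed only in the outermost cell layers. If both
proliferation factors and PHGDH were driven by nutrient availability
alone, their spatial profiles would have to coincide, so the narrower
PHGDH zone implies an additional repressive signal. The compartment model
in this package formalizes that argument: variant **M1** contains only the
nutrient gradient and predicts perfectly co-varying profiles; variant
**M2** adds a core-derived inhibitor of PHGDH expression and reproduces
the observed restriction. Because the argument is structural rather than
quantitative, the package's emphasis is on making the *qualitative* steady
state patterns reproducible, testable, and robust over wide parameter
ranges.

## Geometry and transport

The spheroid is modelled as three concentric compartments — core
(0–300 µm), inner shell (300–450 µm), outer shell (450–600 µm) — inside an
extracellular bath. Shell volumes follow the sphere-shell closed form
$\tfrac{4}{3}\pi(r_2^3 - r_1^3)$ and interface areas $4\pi r^2$;
`build_geometry()` validates strict ordering of the radii and the exact
partition of the full sphere volume.

Transport across an interface is first-order in the source compartment's
copy number with constant

$$k_{a \to b} = P \, \frac{A_{ab}}{V_a},$$

where $P$ is a permeability (µm per time unit) and $A_{ab}$, $V_a$ are the
interface area and source volume. This is the convention under which the
net flux is $P A_{ab} (\,[X]_a - [X]_b\,)$, so pure diffusion equilibrates
*concentrations* rather than copy numbers, and transport constants across
the smaller core|inner interface are automatically down-weighted relative
to the larger outer interfaces — the surface-area adjustment the geometry
demands. The bath is assigned a nominal volume (one tumor volume by
default) purely for bookkeeping: since the extracellular nutrient is
clamped at a fixed concentration, the bath volume cancels out of the
influx $k_{e\to o} N_e = P A_{oe} \cdot \mathrm{conc}_{NU_e}$ and never
affects the dynamics.

## Species, rules, and the 26/31 accounting

Four species occupy the compartments: nutrients `NU` (all four),
proliferative factors `KI67`, the enzyme `PHGDH` and the inhibitor `INH`
(microtumor compartments only; `KI67` and `PHGDH` never leave the
compartment where they are expressed). The default rule inventory is:

| block | rules | kind |
|---|---|---|
| NU transport e↔o, o↔i, i↔c | 6 | transport |
| NU → KI67 in o, i, c | 3 | production |
| NU → PHGDH in o, i, c (inhibited) | 3 | production |
| PHGDH → PHGDH + NU in o, i, c | 3 | catalytic production |
| KI67 → ∅ in o, i, c | 3 | degradation |
| PHGDH → ∅ in o, i, c | 3 | degradation |
| NU → INH in the core (M2 only) | 1 | production |
| INH transport c↔i, i↔o | 4 | transport |

Total: 26 rules in M2, each with its own rate constant. Five further
constants complete the table of 31: the clamped extracellular
concentration `conc_nu_e`, the inhibition constant `K_I`, and three
first-order INH clearance constants. The clearance terms are carried in a
dedicated `decay` slot of the model object rather than in the rule list —
they are part of the parameter table but not of the counted reaction
inventory — which keeps the rule/constant counts at exactly 26/31 while
still giving the inhibitor the sink it needs for a bounded steady state.
(`KI67`/`PHGDH` degradation is likewise a modelling necessity: continuous
production without a sink has no steady state.)

M1 is M2 with the single INH production rule removed. The inert INH
transport and decay entries remain, acting on an identically zero
abundance, so both variants share one 31-entry constant table and the
reduction `M2 with k_exp_inh_c = 0` is *exactly* M1 — a property the test
suite checks to relative tolerance 1e-6.

Production rules consume one `NU` per product molecule (including INH
production). "Produced at a constant rate in the core" is implemented as a
constant *rate constant* on a first-order rule in core nutrients, which
both keeps the nutrient bookkeeping consistent (all expression draws on
the same pool) and guarantees INH production shuts down gracefully when
the core is fully starved.

PHGDH expression carries the inhibition factor

$$\frac{1}{1 + \left([\mathrm{INH}]/K_I\right)^h},$$

with $[\mathrm{INH}]$ the local inhibitor concentration (copy number over
shell volume) and Hill coefficient $h = 1$ by default (configurable via
`build_model(hill = )`). Nothing beyond "inhibits expression" is known
about the mechanism, so the simplest saturating law is used.

## Parameter defaults

All units are abstract — copy numbers, copy numbers per µm³, and model
time units; no physical calibration is attempted. The defaults are:

| parameter | default | role |
|---|---|---|
| `perm_nu` | 1 µm/tu | nutrient permeability; sets transport constants ~5e-3–1e-2 |
| `perm_inh` | 0.1 µm/tu | slower inhibitor exchange, steeper INH gradient |
| `conc_nu_e` | 1 | clamped bath concentration (scale-setting) |
| `k_exp_ki67_*` | 5e-3 | nutrient consumption by proliferative factors |
| `k_exp_phgdh_*` | 1e-3 | nutrient consumption by PHGDH expression |
| `k_syn_nu_*` | 1e-7 | PHGDH-catalysed nutrient replenishment |
| `k_deg_ki67_*`, `k_deg_phgdh_*`, `k_deg_inh_*` | 1e-3 | first-order turnover (timescale 1000 tu) |
| `k_exp_inh_c` | 2e-3 | core inhibitor expression (M2) |
| `K_I` | 0.02 | inhibition constant, concentration units |

The choices follow four design constraints, fixed once at design time.
First, expression rates are on the same scale as inter-shell transport
(~5e-3 per tu), so consumption competes with diffusion and a clear
nutrient gradient forms — with much weaker consumption the shells would
equilibrate with the bath and all profiles would flatten. Second, PHGDH
expression is a smaller draw on the nutrient budget than the aggregate
proliferative-factor class (1e-3 vs 5e-3): it stands for a single enzyme
against a whole biomass-production programme, and this keeps the M2
inhibition of PHGDH from noticeably perturbing the nutrient field, which
is what makes the M1 and M2 `KI67` profiles nearly identical. Third, the
catalytic replenishment `k_syn_nu` is a small correction
(gain $k_{syn} k_{exp}/k_{deg} \approx 10^{-7}$ against consumption
~6e-3): de novo biosynthesis tops up the pool but does not dominate it,
and — importantly for the robustness properties below — the positive
feedback loop stays subcritical even when every parameter is moved by a
factor of ten in the unfavourable direction. Fourth, `K_I` is placed an
order of magnitude below the core inhibitor concentration that the M2
defaults themselves generate (~0.3 copies/µm³, against ~0.02 in the outer
shell), so core PHGDH expression is strongly suppressed while outer-shell
expression is barely touched.

## Simulation and the steady-state criterion

`derive_rates()` turns the rule list into a stoichiometry matrix and
mass-action flux vector; `simulate_model()` integrates with the
stiff-capable `deSolve::lsoda` (defaults rtol 1e-8, atol 1e-10) from the
seed state — all microtumor abundances zero, bath clamped — over 600,000
time units, sampling on a log-spaced grid of 300 points. Small negative
solver excursions (relative magnitude below 1e-12) are clipped to zero
with a warning; anything larger is an error, and a property test checks
non-negativity across random parameter draws.

"Steady state" is operationalized as: the earliest sampled time from which

$$\max_s \frac{|dx_s/dt|}{\max(x_s, 1)} < 10^{-8} \ \text{per time unit}$$

holds at every later sampled time, with the derivative re-evaluated
exactly from the rate laws (not finite-differenced). The abundance floor
of 1 copy keeps identically zero species (M1's INH) from producing 0/0.
Both the threshold and the floor are conventions — only the 600,000-unit
horizon and the fact that it suffices are given — and both are
configurable. Under the defaults the slowest timescales are turnover
(1/k_deg = 1000 tu) and the criterion is met around 15,000 time units,
comfortably inside the horizon; `scripts/acceptance.R` recomputes this
entry time from scratch.

`steady_state_nu_linear()` provides an independent cross-check: with the
catalytic feedback and inhibitor expression switched off, the nutrient
subsystem is linear and its steady state is solved directly as a 3×3
balance system, which the integrator must reproduce to relative tolerance
1e-6.

## The two variants and their structural properties

At steady state each expression/degradation pair gives
$X_s^{ss} = (k_{exp,X}/k_{deg,X})\, NU_s^{ss} \cdot f_s$, with $f_s = 1$
for `KI67` and $f_s$ the inhibition factor for `PHGDH`. Two consequences
are worth stating because the tests treat them as *structural*, not
numerical, facts:

- **M1 exact correlation.** With no inhibitor, $f_s \equiv 1$, so the
  outer-normalized `KI67` and `PHGDH` profiles both collapse onto the
  normalized nutrient profile — they are equal identically, for any
  parameter values that share each species' constants across
  compartments. The suite verifies this to rtol 1e-6 at defaults and over
  100 random draws from a ±10× hypercube.
- **M2 directional suppression.** Any positive core INH expression makes
  the INH concentration strictly decrease outward (source in the core,
  sinks everywhere), hence $f_c < f_i < f_o$ and normalized `PHGDH` falls
  strictly below normalized `KI67` in the inner shell and core. The
  *magnitude* of the suppression is parameter-dependent; following the
  reported pattern, "strongly reduced" is operationalized as the
  normalized core PHGDH value in M2 being at most half its M1
  counterpart, a declared convention (the threshold is an argument of
  `compare_variants()`).

The ±10× hypercube is taken over the model's eleven free parameters — the
two permeabilities (scaling each species' transport constants jointly, so
the surface-area adjustment is preserved), the per-species expression,
synthesis and degradation rates (one multiplier shared by the three
compartment copies, which are a single parameter expressed per shell),
`k_exp_inh_c`, `conc_nu_e` and `K_I`. Drawing all 26 rule constants
independently would instead randomize the *structure* (unequal
per-compartment expression of the same gene, transport decoupled from
geometry) and the correlation identity above would rightly fail; the
grouped hypercube is the family of models over which the structural
claims are well-posed.

## Synthetic microscopy and quantification

The imaging layer exists to exercise the quantification code against
known ground truth, not to model optics or biology.

**Ring images** (`ring_truth()` / `generate_microtumor_image()`) emulate a
mid-plane cross-section: a disk split at radius fractions 0.5 and 0.75
(mirroring 300/450/600 µm) into core/inner/outer rings, each ring carrying
a per-channel mean intensity, plus flat background, optional Poisson
resampling and Gaussian read noise (default sd 300 on a 16-bit scale),
rounded to the integer grid. The default two channels mimic the observed
pattern: a proliferation-marker channel high in outer and inner rings, a
PHGDH-like channel high only in the outer ring.

**Monolayer fields** (`cell_truth()` / `generate_monolayer_field()`)
emulate 2D cultures with stochastic two-state expression: disk-shaped
cells with concentric nuclear disks on a jittered grid (disjoint by
construction; the packing limit is enforced), each cell independently ON
with probability `p_on` per channel, and per-cell intensities lognormal
around the state mean with a latent bivariate-normal correlation `rho`
between the nuclear and cytoplasmic channels. The lognormal dispersion is
small (`sigma_log` 0.15), so the intensity-scale correlation differs from
the latent `rho` only in the third decimal and sample correlations at
n = 500 recover `rho` within Fisher-z sampling bounds. This generator is a
declared synthetic convention: it reproduces the *statistical shape* of
ON/OFF clone fields and partially overlapping two-channel expression, and
nothing else.

Quantification follows the corresponding field practice.
`radial_linescans()` casts 9 rays (configurable; equal angular spacing
from a stated start angle) with nearest-pixel sampling every half pixel,
binned into equal-width radial bins. `compartment_means()` uses pixel
masks with the same boundary convention as the generator (core
$r \le b_1 R$, inner $b_1 R < r \le b_2 R$, outer $b_2 R < r \le R$), so
zero-noise recovery is exact rather than approximate.
`per_cell_intensities()` measures the nuclear channel over the nucleus
mask and the cytoplasmic channel over the whole-cell mask, taking masks
from the generator's truth table — blind segmentation is deliberately out
of scope — and summarises the across-cell correlation with a Fisher-z
interval (undefined below 3 cells). `model_vs_image_check()` compares
rank orderings of outer-normalized triplets, pair by pair, with ties
resolved by a relative tolerance.

What passing these tests shows: the quantification pipeline is unbiased
and within standard-error bounds on images whose generative model is
known, rotation- and intensity-scale-equivariant, and consistent with the
generator's conventions. What it does not show: robustness to uneven
illumination, out-of-focus light, segmentation error, or any other
real-microscopy nuisance explicitly excluded from the generators.

## Problem sizes and numerical conventions in the tests

The suite integrates the 13-state system in ~0.1 s, so the robustness
property uses 100 hypercube draws; image tests use 257×257 ring images
(20 noisy replicates for the standard-error property) and 500-cell
monolayer fields for the distributional checks (binomial ON-fraction
bounds, Fisher-z correlation bounds at 99%). Linescan symmetry and
step-recovery assertions exclude bins within 1.5 bin widths of a ring
boundary or the rim, where nearest-pixel sampling legitimately mixes
rings; interior bins must agree exactly. Serialization tests require
bit-exact round-trips (constants are written with 17 significant digits).

## Known limitations

- The rule inventory realizes printed counts and stated mechanisms; where
  the original inventory is not recoverable, the package's inventory is a
  documented convention, and `read_model()` accepts any conforming
  plain-text specification as an override.
- Deterministic ODE semantics only; no stochastic simulation, no spatial
  PDE limit, no bifurcation analysis.
- Abstract units throughout; rate constants are not calibrated to
  experimental intensities, so only normalized profiles and rank patterns
  are meaningful outputs.
- The inhibitor is a lumped proxy for unknown stress signalling; its
  first-order clearance and transport are parsimony choices, not
  mechanism.
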