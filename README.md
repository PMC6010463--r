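# microtumor

Tumor spheroids grown to a few hundred micrometres develop radial
microenvironments: a nutrient-rich outer layer in contact with the growth
medium, an intermediate shell, and a nutrient-starved core. In such
spheroids the serine-synthesis enzyme PHGDH is expressed only in the
outermost proliferative cell layer, while proliferation markers such as
Ki-67 extend deeper — a spatial pattern that a pure nutrient gradient
cannot produce on its own. `microtumor` implements, simulates and analyses
a compartmental reaction model of this phenomenon, and provides synthetic
fluorescence-image generation and quantification so the model's predicted
compartment profiles can be confronted with image-derived ones without any
experimental data. It is aimed at systems-biology users who want a small,
fully testable model of emergent expression gradients in 3D cell
ecosystems.

## The model

The spheroid is partitioned into an extracellular bath (e) and three
concentric compartments — outer shell (o), inner shell (i), core (c) with
default radii 600, 450 and 300 µm. Four species interact through
mass-action kinetics:

- `NU` — nutrients, clamped at concentration `conc_nu_e` in the bath and
  diffusing through the shells with first-order transport constants
  `k = P · A / V_source` (permeability × interface area / source volume),
  so pure diffusion equilibrates concentrations;
- `KI67` — an aggregate proliferative-factor class, produced from local
  nutrients (`NU_x → KI67_x`) and degraded first-order;
- `PHGDH` — produced from local nutrients under inhibition,
  `rate = k_exp_phgdh · NU_x / (1 + ([INH_x]/K_I)^h)`, degraded
  first-order, and catalysing nutrient replenishment
  (`PHGDH_x → PHGDH_x + NU_x`) to represent de novo biosynthesis;
- `INH` — a hypothetical inhibitor aggregating stress-induced factors,
  expressed from nutrients in the core only (variant **M2**; variant
  **M1** omits this rule), transported between shells and cleared
  first-order.

The default M2 build has 26 reaction rules and 31 rate constants. At
steady state, M1 produces a strictly decreasing nutrient gradient toward
the core with outer-normalized `KI67` and `PHGDH` profiles *exactly*
equal; M2 adds an inhibitor gradient running opposite to the nutrient
gradient, which suppresses `PHGDH` in the inner shell and core while
leaving the `KI67` profile essentially unchanged — the observed
restriction of PHGDH to the outer layer.

## Worked example

```r
library(microtumor)

m1 <- build_model("M1"); m2 <- build_model("M2")
m2
#> Microtumor compartment model, variant M2
#>   26 reaction rules, 31 rate constants
#>   rules by kind: catalytic_production=3, degradation=6, production=7, transport=10
#>   clamped: NU_e (concentration 1)

res1 <- simulate_model(m1); res2 <- simulate_model(m2)
res2
#> Microtumor simulation (M2), t_end = 600000
#>   steady state reached: TRUE (entry time 15164.77, tol 1e-08)
#>   NU    o/i/c: 2.77e+08 / 8.142e+07 / 2.006e+07
#>   KI67  o/i/c: 1.385e+09 / 4.071e+08 / 1.003e+08
#>   PHGDH o/i/c: 1.667e+08 / 2.696e+07 / 1.844e+06
#>   INH   o/i/c: 6.918e+06 / 1.085e+07 / 2.234e+07

normalize_to_outer(res2, "PHGDH")
#> PHGDH compartment profile (outer-normalized): o=1 i=0.1617 c=0.01106

compare_variants(res1, res2)
#> Variant comparison (deltas = second - first, outer-normalized)
#>       o       i       c
#> NU    0  0.0086 -0.0027
#> KI67  0  0.0086 -0.0027
#> PHGDH 0 -0.1236 -0.0640
#> verdicts:
#>   nu_gradient_preserved    TRUE
#>   ki67_comparable          TRUE
#>   phgdh_inner_suppressed   TRUE
#>   phgdh_core_suppressed    TRUE
```

The simulation output lists steady-state copy numbers per compartment:
nutrients fall ~14-fold from outer shell to core, and in M2 the inhibitor
rises toward the core, cutting the normalized core PHGDH value (0.011) to
well below both the normalized core KI67 value (0.072) and its M1
counterpart. The comparison deltas quantify exactly that: KI67 barely
moves between variants while PHGDH drops in the inner shell and core.

Closing the loop against (synthetic) microscopy:

```r
tr  <- ring_truth(seed = 42)              # ground-truthed ring image
img <- generate_microtumor_image(tr)
cm  <- compartment_means(img$image, tr$center, tr$radius)
cm
#> Compartment mean intensities (columns outer / inner / core)
#>              o       i       c
#> ki67  12001.76 8994.58 2001.03
#> phgdh 11998.65 3001.22 1495.26
#> pixel counts: o=16580, i=11924, c=9477

model_vs_image_check(normalize_to_outer(res2, "PHGDH"), cm,
                     channel = "phgdh")$concordant
#> [1] TRUE
```

The recovered compartment means sit within a few intensity units of the
generator's truth (12000/9000/2000 and 12000/3000/1500 at noise sd 300),
and the rank ordering of the M2 PHGDH profile agrees with the
PHGDH-like image channel in every compartment pair.

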