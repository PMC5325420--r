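# crosstalksim

Kinetic simulation of signaling-crosstalk modules, and in-silico screens of
how crosstalk architecture shapes targeted-drug resistance and
drug-combination synergy.

## The problem

Parallel signaling cascades — the motivating case is the
EGF/EGFR/Ras/MEK/ERK and HGF/HGFR/PI3K/AKT axes converging on a shared
anti-apoptotic output — talk to each other through crosstalk activation and
inhibition. When a targeted drug hits one node, crosstalk can bypass the
block, or the drug can relieve a crosstalk inhibition and reactivate the
other pathway: both make the cell look drug-resistant without any mutation.
`crosstalksim` is for modellers who want to ask, topology by topology,
*which* crosstalk architectures confer resistance, which drug pairs defeat
them synergistically, and how the answer moves with crosstalk strength.

## The model

Five species as activation fractions: G1 → A → B → O and G2 → C → D → O,
with B and D converging on the output O. Kinetics are Michaelis–Menten,

```
dX_i/dt = Σ_j V_{j,i} · S_{j,i} / (g_i·K_{j,i} + S_{j,i}) · X_j − d_i·X_i + f_i(t)
```

where the saturating substrate is the inactive fraction `S = 1 − X_i` for
activating edges (`V > 0`) and, by default, the active fraction `S = X_i`
for inhibiting edges (`V < 0`), which keeps every state in `[0, 1]`. The
inputs `f_1, f_3` are saturating functions of the growth-factor stimuli. A
targeted drug at dose `D` inflates its target's activation constants by
`g_i = 1 + D/K_D` (competitive inhibition). Nine module topologies M0–M8
share the four-edge backbone and differ in their crosstalk links; module 0
(no crosstalk) is the baseline.

Scores:

* **Relative drug efficacy** `RDE(i) = (1 − IO_drug(i)/IO_no_drug(i)) −
  (1 − IO_drug(0)/IO_no_drug(0))`, where `IO = ∫₀¹⁰⁰ O(t) dt`.
  `RDE < 0` is crosstalk-mediated resistance.
* **Bliss combination index** `CI = R12 − (R1 + R2 − R1·R2)` on fractional
  output reductions; `CI > 0.05` synergy, `< −0.05` antagonism, otherwise
  additivity.

Integration is fixed-step classical RK4 (`h = 0.01`, horizon 100), with
piecewise-constant inputs sampled at step midpoints so the scheme keeps
fourth-order accuracy across stimulus on/off switches.

## Worked example

```r
library(crosstalksim)

res <- single_drug_screen(screen_config())
res[, c("module_id", "io_no_drug", "io_drug", "rde")]
#>   module_id io_no_drug   io_drug         rde
#> 1         0   24.37375 17.591591  0.00000000
#> 2         1   27.93820 22.590170 -0.08683300
#> 3         2   19.15322  9.676524  0.21652674
#> 4         3   28.40577 19.039497  0.05147466
#> 5         4   19.51407 15.024013 -0.04816321
#> 6         5   48.31291 22.390192  0.25830222
#> 7         6   17.39079 15.500392 -0.16955571
#> 8         7   20.95057 15.540196 -0.02001202
#> 9         8   20.95057 16.508213 -0.06621686
```

Modules 1, 4, 6, 7 and 8 score `RDE < 0`: their crosstalk dampens the
B-targeting drug (bypass via A→D in M1, inhibition relief of B⊣C in M4,
mutual rewiring in M6–M8). Module 2 is the most sensitised (+0.217), and
module 5's mutual activation gives the largest untreated output (48.3) but
loses its persistence under drug.

Pairing the anchor with the other pathway's effector D rescues the
resistant module 4, both in efficacy and synergy:

```r
combo <- combination_screen(screen_config(modules = 4))
subset(combo, partner == "D",
       select = c(module_id, rde_single, rde_combo, ci, label, direction))
#>   module_id  rde_single  rde_combo        ci   label direction
#> 8         4 -0.04816321 -0.0316204 0.2913719 synergy  increase
```

And module 7 switches from resistant to sensitive when its crosstalk is
ten-fold stronger:

```r
scan <- strength_scan(screen_config(modules = 7, scale_grid = c(1, 10)))
attr(scan, "switching")
#>   module_id rde_min_scale rde_max_scale       switch
#> 1         0          0.00         0.000         none
#> 2         7         -0.02         0.236 to_sensitive
```

A thin command-line wrapper over the same functions lives at
`inst/cli/crosstalk-screen.R` (subcommands `simulate`, `screen-single`,
`screen-combo`, `scan-strength`, `scan-stimulus`). The methods vignette
(`vignettes/crosstalk-modules.Rmd`) documents the model, conventions and
numerical choices in full.

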