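# tumorphase

A finite-volume simulator for a viscous multiphase (mixture-theory)
model of solid tumor growth in vascularized healthy tissue, with
M1/M2 macrophage dynamics and a TGF-β-receptor-blocking immunotherapy.

## Who this is for

Mathematical-oncology modelers who want a tested, configurable
implementation of a seven-phase tumor–immune continuum model: healthy
cells, cancer cells, vasculature, interstitial fluid, pro-inflammatory
(M1) macrophages, pro-tumor (M2) macrophages, and a drug-bound M1
compartment. Each phase θᵢ obeys a mass balance with advection,
chemotaxis and reactions,

    ∂ₜθᵢ + ∇·(uᵢθᵢ) + χ_J ∇·(θᵢ∇J) = qᵢ,

and a creeping-flow momentum balance with full deviatoric viscous
stress, inter-phase drag d_ij θᵢθⱼ(uⱼ−uᵢ), and a cell-density pressure
closure Σ(θ) = Λ(θ−θ*)/Σᵢ(θᵢ−θ)² that switches on above the natural
tissue density θ* = 0.6. Six cytokines (oxygen, VEGF, CSF-1, CXCL12,
EGF, TGF-β) and the drug are quasi-steady reaction–diffusion fields,
D_J∇²J + s_J = 0, with biphasic hypoxia-driven VEGF/CSF-1 production
c/(c_a+c)². The drug follows a pulsed oral schedule with exponential
elimination between doses. Everything is dimensionless (time unit: one
healthy-cell doubling ≈ 1 day; length unit: 400 µm); defaults are the
published dimensionless parameter tables.

The model reproduces, at reduced resolution, the hallmark behaviors of
the published study: M1 macrophages slow tumor growth while alternative
activation to M2 accelerates it; multiple merging lesions create
hypoxic niches that favor M2 polarization; and pulsed TGF-β-receptor
blockade transiently freezes M1 macrophages in their anti-tumor
phenotype, suppressing both tumor growth and the M2/M1 ratio until the
drug washes out.

## Worked example

```r
library(tumorphase)

## healthy-tissue equilibrium used as the initial condition
homeo <- solve_homeostasis(model_parameters())
homeo
#> Homeostatic equilibrium (dimensionless):
#>   theta_v0   = 0.0174978
#>   theta_int0 = 0.382502
#>   c0         = 0.253203
#>   g0         = 0.600296
#>   k_ang implied by the vessel balance = 0.00810695
#>   max |residual| = 2.78e-17
```

The four equilibrium values match the published initial-condition table
(0.0175, 0.3825, 0.25, 0.6) to their printed rounding. The implied
angiogenesis constant differs from the published 4.87·10⁻³ — a
documented internal inconsistency of the source model (the printed
value solves the vessel balance only if the VEGF level is replaced
by 1); the simulator keeps the published value as its default and
reports the implied one alongside.

```r
## scaled-down single-seed scenario: disk radius 15, 60 radial cells
sc <- scenario(seeds = list(seed_spec()),
               domain = list(mode = "radial_1d", R = 15, n_cells = 60),
               t_end = 60, output_every = 10)
run <- run_scenario(sc)
tail(run$observables[, c("t", "theta_bar_c", "theta_bar_M2",
                         "ratio_M2_M1", "tumor_radius")], 3)
#>     t theta_bar_c theta_bar_M2 ratio_M2_M1 tumor_radius
#> 5  40  0.01234321  0.002087166   0.2538805     2.574328
#> 6  50  0.02963025  0.005864972   0.3814206     3.545356
#> 7  60  0.06515997  0.013832970   0.5311837     4.632159
```

`theta_bar_*` are disk averages of each phase, `ratio_M2_M1` is the
pro-tumor to anti-tumor macrophage ratio (M2 over M1 + drug-bound M1),
and `tumor_radius` the outermost radius where the cancer concentration
crosses 0.01. Comparing macrophage modes at `t = 60` reproduces the
published ordering: `m1_only` (0.011) < `inert` (0.053) < `both`
(0.065) for the average cancer concentration.

A command-line front end mirroring the package functions lives at
`inst/cli/tumorphase.R`:

```sh
Rscript inst/cli/tumorphase.R equilibrate
Rscript inst/cli/tumorphase.R run --config my_scenario.yaml --outdir out/
Rscript inst/cli/tumorphase.R sweep --param k_aa --values 0.1,0.5,2.5 --out sweep.csv
```

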