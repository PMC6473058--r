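# fieldsteer

Electric-field modeling and current steering for multi-electrode
transcranial direct-current stimulation (tDCS), with a cerebellar
lobule-targeting workflow.

## The problem

Cerebellar tDCS delivers weak scalp currents (≤ 2 mA) toward the
cerebellum, whose lobules map to distinct motor and cognitive
functions — lower-limb (ankle) control, for example, involves the
posterior-inferior lobules VII–IX. Published two-electrode montages
produce rather non-focal fields, so dosing a chosen lobule set
requires (i) a forward model of where the injected current actually
goes and (ii) an optimizer that distributes currents over a
multi-electrode array to shape the field. `fieldsteer` provides both,
end to end, for researchers developing stimulation protocols and for
methodologists studying focality and dose.

At quasistatic frequencies the head is an Ohmic volume conductor: the
potential solves

∇·(σ∇Φ) = 0 in Ω,  σ∇Φ·n̂ = Jₑ at the electrodes, 0 elsewhere on Γ,

and the field is **E** = −∇Φ. Region-averaged fields are linear in
the electrode currents, **b** = LF·**x**, where the *lead-field
matrix* LF (one matrix per field direction X/Y/Z) is assembled from
unit bipolar simulations against a common vertex reference. Montage
design is then the convex program

argminₓ ‖W(LF·x − b)‖²  s.t.  Σxₙ = 0,  Σ|xₙ| ≤ 4 mA,

(zero net current; total injected magnitude capped at 4 mA, i.e. at
most 2 mA total anodal), solved exactly by a split-variable quadratic
program.

Everything runs on a synthetic five-tissue spherical head phantom
(scalp/skull/CSF/gray/white, conductivities 0.465/0.010/1.654/0.276/
0.126 S/m) with a 28-region wedge "pseudo-cerebellum" plus pooled
non-cerebellar brain, so the whole pipeline is testable without any
imaging data; a closed-form Legendre-series solution for concentric
shells serves as the independent verification oracle for the finite
element solver. See the vignette (`vignettes/current-steering.Rmd`)
for the model, the numerical choices and their limits.

## Worked example

```r
library(fieldsteer)

mesh <- build_shell_phantom(default_head_shells(), resolution = 8)
mesh
#> head_mesh: 25299 nodes, 143856 tetrahedra, 5 tissue label(s)
#>   volume 3.251e+06 mm^3

parc <- build_parcellation(mesh, spacing = 1)      # 28 lobules + brain mask
sol  <- solve_potential(mesh, make_montage_preset("celnik", mesh))
tab  <- lobule_means(rasterize_field(sol, field_grid(mesh)), parc)
subset(tab, region %in% c("Left_Crus_I", "Right_Crus_I", "Right_VIIb",
                          "Right_IX", "NonCerebellarBrain"))
#>                region n_voxels     Ex   Ey      Ez Enorm
#> 4         Left_Crus_I     8680 -0.063 0.18 -0.0570  0.20
#> 14       Right_Crus_I     8680  0.181 0.43 -0.1225  0.49
#> 16         Right_VIIb     8340  0.197 0.39 -0.0901  0.45
#> 19           Right_IX     8741  0.228 0.31 -0.0033  0.39
#> 29 NonCerebellarBrain  1866051  0.112 0.18 -0.0229  0.24
```

The classic cerebellar montage (5×5 cm anode lateral to the inion,
cathode on the cheek, 2 mA) concentrates ~0.4–0.5 V/m on the right
cerebellar lobules — about 2.5× the contralateral side — with the
posteroanterior component Ey dominant under the anode, while the rest
of the brain averages ~0.24 V/m. Electrode current densities follow
the pad areas:

```r
current_density(2, 25)    # 5x5 cm pad at 2 mA
#> [1] 0.08
current_density(1, 3.14)  # 3.14 cm^2 high-definition disc at 1 mA
#> [1] 0.32
```

Steering a uniform 0.3 V/m inferosuperior (Z) field onto the right
posterior-inferior lobules with an 8-electrode catalog:

```r
catalog <- candidate_layout(mesh, n = 8)           # vertex reference "Cz"
lf <- assemble_leadfield(mesh, catalog, parc)      # one FEM solve per electrode
target <- uniform_target(lf, c("Right_VIIb", "Right_VIIIa",
                               "Right_VIIIb", "Right_IX"),
                         direction = "Z", magnitude = 0.3)
optimize_montage(lf, target)
#> montage_solution (direction Z): residual 0.4628, net current 0.00e+00 mA, total |I| 4.000 of 4.000 mA
#>   active electrodes (mA):
#>     E06      +1.428
#>     E05      -1.044
#>     E03      -0.940
#>     E04      +0.572
```

The returned currents always balance to zero and respect the 4 mA
safety cap (here the cap binds: the target demands more field than
4 mA can deliver, and the residual reports the remaining L2 error in
V/m). `predict_fields(lf, x)` gives the per-region field of any
zero-sum current vector by superposition, and the CLI `verify` stage
re-simulates an optimized montage by FEM to confirm the prediction.

A command-line interface over the same functions is installed at
`inst/cli/fieldsteer.R` (subcommands `phantom`, `simulate`,
`extract`, `leadfield`, `optimize`, `verify`, `stats`), driven by a
YAML config with a fixed seed.

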