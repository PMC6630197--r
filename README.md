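# amphisurf

Amphoteric phospholipid surfaces — like the DPPC/DPPE bilayers that coat
articular cartilage — carry both an acidic phosphate group and a basic amine
group, so their net charge and their interfacial tension depend on the pH of
the surrounding solution. `amphisurf` is an R package for the physical
chemistry and trajectory analysis of such surfaces. It is aimed at membrane
biophysicists who want to (i) model and fit interfacial-tension-versus-pH
curves, (ii) prepare and characterize the Britton–Robinson universal buffers
those experiments are run in, and (iii) quantify the hydrogen-bond "glue"
(water bridges and direct lipid–lipid contacts) in bilayer molecular
dynamics trajectories.

## The model

Two acid–base equilibria tie the headgroup to the solution,

    PO4^- + H+  <-> PO4H      (X^-  -> XH,  association constant K_X)
    NH3^+ + OH- <-> NH3OH     (Y^+  -> YOH, association constant K_Y)

and the measured bilayer tension is the speciation-weighted sum of four
component tensions:

    gamma(pH) = gamma0_X- /(1 + K_X a_H)  + gamma0_XH  K_X a_H /(1 + K_X a_H)
              + gamma0_Y+ /(1 + K_Y a_OH) + gamma0_YOH K_Y a_OH/(1 + K_Y a_OH)

with `a_H = 10^-pH`, `a_OH = 10^(pH - pKw)`. **`K_X`, `K_Y` are association
constants, `K = 10^pK`** (DPPC: `10^2.58`, `10^5.69`) — not conventional
dissociation pKa values; mixing the two conventions flips the curve. The
isoelectric point follows the two-group mean rule `pI = (pK_X + pK_Y)/2`
(4.14 for DPPC, 4.20 for DPPE). Raw measurements convert through the
Young–Laplace relation `2 gamma = R dp`, buffer capacity is the slope
`beta = dH+/dpH` (generalized to tension/friction responses), and water
bridges are single water molecules hydrogen-bonded simultaneously to two
different lipids.

Only the baseline `B = gamma0_X- + gamma0_Y+`, the amplitudes
`A_X = gamma0_XH - gamma0_X-`, `A_Y = gamma0_YOH - gamma0_Y+` and the two pK
exponents are identifiable from tension data; fitting works in that
five-parameter space (see `vignette("amphisurf-methods")`).

## Worked example

```r
library(amphisurf)

p <- dppc_params()                     # calibrated DPPC reference fixture
gamma_of_pH(p, 7.4)                    # 0.003285 N/m at physiological pH
locate_maximum(p, 0, 14)
#> pH_at_max gamma_max
#>  5.333769  0.003500

titration_curve(britton_robinson_recipe(), c(0, 20, 50))
#>   titrant_volume       pH added_base
#> 1              0 1.874524      0.000
#> 2             20 3.438836      0.004
#> 3             50 6.897344      0.010

ds  <- gen_tension_dataset(tension_fixture("DPPC", sigma = 0.02, seed = 42))
fit <- fit_tension_curve(ds$curve)
fit
#> Acid-base tension model fit
#> Identifiable tension-model parameters
#>   baseline B 0.00349879 N/m, amplitudes A_X -0.00118853, A_Y -0.00202887 N/m
#>   pK_X 2.5275  pK_Y 5.6641
#>   gamma_max 0.00349492 N/m at pH 5.315; pI estimate 4.096
#>   residual norm 0.000424 N/m; converged: TRUE (11 iterations)

surface_energy(fit$gamma_max, 85.4)    # 1797 J/mol at the curve maximum
```

The fit recovers the generating exponents (2.58, 5.69) to a few hundredths
under 2% multiplicative noise; the pI estimate 4.096 is within 0.04 of the
generating 4.135. The tension maximum is the tabulated 3.5e-3 N/m by fixture
calibration, and the buffer pH values land within 0.15 of the classic
Britton–Robinson checkpoints (1.81, 3.29, 6.80).

Trajectory analysis runs on multi-model PDB (or XYZ + topology CSV) input:

```r
pl  <- random_plant_spec(16, 100, 50, seed = 1)     # planted ground truth
toy <- gen_toy_trajectory(16, 100, pl, n_frames = 50, seed = 1)
bonds   <- detect_hbonds_trajectory(toy$trajectory)
bridges <- do.call(rbind, lapply(split(bonds, bonds$frame),
                                 find_water_bridges))
bridge_map(bridges)                    # normalized pair-frequency map
event_durations(bridges, frame_spacing = 50)  # lifetime distribution, ps
```

A command-line umbrella (`exec/amphisurf`, or `run()` from R) exposes the
same operations: `pI`, `laplace`, `titrate`, `beta`, `fit`, `simulate`,
`hbonds`, `bridges`, `contacts`, `durations`, `map`, `compare`.

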