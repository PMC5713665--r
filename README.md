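# pfxverify

Independent dose and shot-time verification for Leksell Gamma Knife
Perfexion radiosurgery plans.

Gamma Knife treatments are usually delivered in a single fraction, so an
error in the treatment planning system's dose calculation cannot be caught
and corrected over later fractions. Standard practice is therefore a
*second check*: an independent program recomputes the focus dose and
irradiation time of every shot from the plan parameters and compares them
with the planning system's values against clinical tolerance (±3%) and
action (±5%) limits. `pfxverify` is such a second-check engine for the
Perfexion geometry, written for medical physicists: it needs only the plan
parameters, the skull-scaler measurements, and a machine-definition file —
no connection to the vendor system.

## The model

The Perfexion carries 192 Co-60 sources in 8 independently collimated
sectors (16, 8 or 4 mm, or blocked) times 5 rings. The patient skull
surface is reconstructed from frame-based skull-scaler measurements by a
real spherical-harmonic least-squares fit of radius over direction
(default degree 4), and each source-to-focus beam axis is ray-traced
through that surface to obtain its tissue depth *d*. The dose rate at a
point *P* from source *i* is

```
dD/dt_i(P) = (dD/dt)_cal,16 · 1/192 · OF_c
             · exp(−μ (d − df − R_cal))
             · (1 − df / vSFD_i)^(−2)
             · OAR( OAD_f / (1 − df / SSD_i) )
```

where `(dD/dt)_cal,16` is the calibration dose rate (16 mm collimator,
`R_cal` = 80 mm depth), `OF_c` the collimator output factor (1, 0.92, 0.81
for 16, 8, 4 mm), `μ` = 0.0065 /mm a single effective linear attenuation
coefficient, `df` the signed axial offset of *P* from the focus along the
beam axis, `vSFD_i` the (collimator, ring)-specific virtual source-to-focus
distance, `OAD_f` the off-axis distance of *P*, and `SSD_i` the virtual
source-to-surface distance. Shot dose rates are the sum over all unblocked
sources; plan doses are the duration-weighted sum over shots, giving
per-shot focus doses/times, full 3D dose grids (NRRD/CSV export), isodose
masks at 12.5/25/50/75/90% of maximum, and the verification report.

Vendor beam data is proprietary: the shipped machine file uses documented
placeholder geometry and profiles, and every value can be overridden by
your own measured/commissioned data.

## Worked example

```r
library(pfxverify)
machine <- load_machine()                  # shipped 192-source model
phantom <- phantom_spec("sphere", 80)      # QA phantom, radius 80 mm
pl      <- make_plan(3, phantom, seed = 31)
surface <- attr(pl, "surface")

computed <- compute_focus_table(pl, surface, machine)
computed
#>   shot_id dose_rate_gy_min focus_dose_gy time_min
#> 1 shot-01            2.606         6.667    2.558
#> 2 shot-02            2.827         6.667    2.359
#> 3 shot-03            3.066         6.667    2.175

# reference values as a planning system would report them (here: the
# computed doses perturbed by 0%, +2% and +6%)
ref <- data.frame(shot_id = computed$shot_id,
                  focus_dose_gy = computed$focus_dose_gy / c(1, 1.02, 1.06),
                  time_min = computed$time_min)
verify_plan(computed, ref)
#> Plan verification: 3 shot(s), ratio 1.027 +/- 0.031 [1.000, 1.060], ACTION
#>   shot_id computed_focus_dose_gy reference_focus_dose_gy ratio ... flag
#> 1 shot-01                  6.667                   6.667  1.00 ... pass
#> 2 shot-02                  6.667                   6.536  1.02 ... pass
#> 3 shot-03                  6.667                   6.289  1.06 ... action
```

Each shot was planned to deliver 20/3 ≈ 6.67 Gy to its own focus; the
computed/reference ratio of 1.06 on `shot-03` exceeds the ±5% action limit
and flags the plan for review. The full 3D dose distribution:

```r
g <- compute_dose_grid(pl, surface, machine)
g
#> Dose grid 26x26x26 voxels, spacing (2, 2, 2) mm, origin (66.62, 91.21, 68.64) mm
#>   dose range 0.07662 - 4.293 Gy
max_dose_location(g)$point      # (116.62, 97.21, 118.64) mm
sum(isodose_mask(g, 50))        # 45 voxels at or above half-maximum
write_nrrd(g, "plan_dose.nrrd")
```

A command-line front end (`verify`, `dosegrid` subcommands) is installed
at `system.file("cli", "pfxverify.R", package = "pfxverify")`.

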