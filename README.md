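# pibsim

Markerless lung tumors are hard to see on treatment-room X-rays: the signal
of everything between source and detector — chest wall, spine, sternum —
piles on top of the tumor, and at unfavorable gantry angles the tumor
disappears entirely behind the vertebral column. `pibsim` implements and
evaluates **prior information-based subtraction (PIBS) radiography**: the
planning CT, already part of every radiotherapy record, is used as prior
knowledge to simulate the radiograph of the *non-essential* (NE) tissues —
everything outside the thoracic cavity — and that simulated image is
subtracted from the treatment-day radiograph, leaving only the cavity
contents (lung and tumor) visible.

The package is aimed at medical-physics researchers who want a fully
synthetic, fully reproducible test bench for this idea: an anthropomorphic
digital thorax phantom with a mobile spherical tumor, a cone-beam DRR
projector, bone-driven rigid registration, the subtraction pipeline itself,
and quantitative evaluation of tumor visibility and trackability.

## The method

Let \(\mu(\mathbf{x})\) be the linear attenuation map derived from CT
numbers via \(\mu = \mu_\text{water}\,(1 + \mathrm{HU}/1000)\) (zero for
HU ≤ −1000). A radiograph pixel in the line-integral (optical depth) domain
is \(L = \int_\text{ray} \mu\, dl\). Because line integrals are additive,

\[
L_\text{treatment} - L_\text{NE} \;=\; L_\text{cavity contents},
\]

*exactly*, provided the NE tissues in the treatment-day volume occupy the
same positions as in the planning CT. The workflow is therefore:

1. segment the thoracic cavity on the planning CT and override it to
   −1024 HU → the *NE planning CT*;
2. align NE tissues by rigid registration of the treatment-day volume to
   the planning CT (3D/3D on volumes, or 2D/2D on orthogonal 45°/135°
   projections with least-squares back-projection of the in-plane shifts),
   i.e. the clinical couch correction;
3. resample the treatment-day CT onto the planning grid, project both it
   and the NE planning CT at the desired gantry angles (100 cm SAD /
   150 cm SID cone beam, exact Siddon ray tracing), and subtract.

Tumor visibility is quantified by the contrast-to-noise ratio
\(\mathrm{CNR} = |\bar{T} - \bar{B}| / \sigma_B\) with ROIs placed from the
simulation ground truth, and trackability by template-matching localization
of the tumor across respiratory states.

## Worked example

```r
library(pibsim)

study <- make_study()          # planning CT + 3 treatment-day CTs
study
#> <study_bundle> 160x128x120 voxels @ 2.5x2.5x2.5 mm; 3 treatment state(s), SI shifts (0, 10, 20) mm
#>   setup error t = (8, -5, 12) mm, r = (1, -1, 2) deg; seed 1, noise SD 0 HU

run <- run_pipeline(study, angles_deg = c(45, 135, 150), mode = "3d3d")
run
#> <pibs_run> 3 state(s) x 3 angle(s), line_integral domain, alignment mode 3d3d
#>   registration: converged, metric 0.9337

tidy(run$registration[[1]])    # recovered couch correction (~ minus the setup error)
#>   term  estimate unit
#> 1 tx      -7.98  mm
#> 2 ty       5.25  mm
#> 3 tz     -11.4   mm
#> 4 rx      -1.14  deg
#> 5 ry       0.922 deg
#> 6 rz      -2.03  deg

report <- evaluation_report(run, track_angle = 150)
report$cnr_ratio
#>   angle_deg cnr_pibs cnr_conventional ratio
#> 1        45     6.32            0.883  7.16
#> 2       135     3.02            2.39   1.27
#> 3       150     1.68            0.321  5.22
```

The recovered transform matches the inverse of the injected setup error to
a fraction of a voxel. At gantry 150° — where the tumor projects squarely
onto the vertebral column and is invisible on the conventional image — the
PIBS image improves the tumor CNR five-fold, and the superior/inferior
motion trace recovered from the three PIBS images reproduces the injected
0/10/20 mm tumor shifts to better than 0.1 mm:

```r
report$motion[, c("state", "displacement_mm", "truth_mm", "error_mm")]
#>   state displacement_mm truth_mm error_mm
#> 1     1             0          0   0
#> 2     2            10.1       10   0.0844
#> 3     3            20.0       20  -0.0303
```

`plot(run$pibs[[1]][["150"]])` displays any radiograph;
`ggplot2::autoplot(report)` plots CNR against gantry angle.

A command-line wrapper with `simulate`, `drr`, `register`, `run`,
`evaluate` and `demo` subcommands is installed at `inst/cli/pibs.R`; all
subcommands take `--config <yaml|json>`, `--seed` and `--out`, and log the
fully resolved configuration next to their outputs.

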