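# hipcalib

Bi-planar radiograph calibration for pre-operative templating of total hip
arthroplasty.

Digital templating needs the magnification ("calibration factor",
CF = 100 · SDD / z₀, in %) of the coronal plane through the hip joint
centre. A spherical external calibration marker (ECM) placed on the skin in
front of the pubic symphysis lies 50–110 mm anterior to that plane, so its
shadow magnification is biased; errors above 1.5 percentage points (pp) can
change the templated implant size. The bi-planar method adds one lateral
radiograph: the ECM's shadow in the anteroposterior (AP) view gives the
marker-plane factor and depth, the lateral view gives the marker's anterior
offset from the hip plane (corrected for subject rotation via the projected
hip-centre separation), and the hip-plane factor follows from the shifted
depth.

`hipcalib` provides

* an exact cone-beam forward model of sphere-to-ellipse projection
  (`project_sphere()`, with an independent sampling oracle),
* the iterative single-marker solver used for the internal reference
  marker (`single_marker_plane_cf()`, `icm_reference_cf()`) and the
  bi-planar hip-plane solver (`biplanar_hip_cf()`),
* a virtual phantom reproducing the proof-of-concept factorial design —
  ECM at 3 anterior × 4 lateral offsets, lateral views at 0/10/20/30°
  rotation, 60 radiograph-equivalents (`phantom_config()`,
  `generate_study()`), with an optional Gaussian PACS-caliper noise model,
* the statistical pipeline: per-set CF table, summary tables, MCID counts,
  paired t and Kruskal–Wallis tests, ICC(2,1) reliability
  (`compute_study_table()`, `table2_summary()`, `mcid_report()`, ...),
* command bindings and a CLI wrapper (`cmd_simulate()`, `cmd_calibrate()`,
  `cmd_study()`; `inst/cli/hipcalib.R`).

## Worked example

```r
library(hipcalib)

g   <- beam_geometry(1150)          # focus-detector distance, mm
cfg <- phantom_config(ecm_anterior_mm = 50, ecm_lateral_mm = 40,
                      rotation_deg = 20)
ap  <- simulate_ap(cfg, g)          # h,i,k,m,n,o,p  (AP distances, mm)
lat <- simulate_lateral(cfg, g)     # a,b,c,d        (lateral distances, mm)

biplanar_hip_cf(ap, lat, 25, g, g)
#> <calibration_result> CF 126.312% (marker plane 138.889%)
#>   est. depth 910.44 mm; 4 iterations; converged: TRUE; residual 1.05e-06 pp

plane_cf(908, g)                    # true hip-plane factor
#> [1] 126.652
```

The marker's own plane magnifies at 138.9%; the bi-planar reconstruction
transfers it to the hip plane at 126.31%, 0.34 pp from the true 126.65% even
at 20° subject rotation and 40 mm marker misplacement.

The full noiseless study (48 AP/lateral sets):

```r
tab <- compute_study_table(generate_study())
tapply(tab$abs_diff_pp, tab$rotation_deg, max)   # pp vs the ICM reference
#>          0         10         20         30
#> 0.00274205 0.17611934 0.34784692 0.51363096
mcid_report(tab)
#> <mcid_report> 0/48 sets (0.0%) beyond 1.5 pp
```

Errors are zero at the strict lateral position and grow with rotation —
the pattern observed on the physical phantom — while staying inside the
1.5 pp clinical threshold through 20° and inside the observed 1.84 pp
maximum at 30°.

From a shell:

```sh
Rscript inst/cli/hipcalib.R study --seed 1 --noise --out study_out
```

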