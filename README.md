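# kneepose

Post-operative 3D component position analysis for total knee arthroplasty
(TKA), referenced to the patient's pre-operative anatomy.

## The problem

After a TKA, surgeons and engineers want to know where the femoral and
tibial components actually ended up **relative to the patient's own
anatomic axes**, and how much bone was resected to get them there. A
post-operative CT alone cannot answer either question: the resected
anatomy is gone, the metal component flare corrupts the nearby bone
segmentation, and patient-specific landmarks are hard to identify through
an implant. Combining the **pre-operative** planning CT (full bone
surfaces and landmarks) with the **post-operative** CT (partial,
flare-cropped bone surfaces and the implant itself) recovers both.

The pipeline:

1. **Bone registration** — each pre-operative bone surface is registered
   into the post-operative CT frame with trimmed iterative-closest-point
   (ICP) registration (k-nearest correspondence, fixed-fraction trimming
   for the partial overlap, annealed distance gating), seeded
   deterministically from the implant pose (`implant_seeded_init()`).
2. **Landmark propagation and anatomic frames** — the pre-operative
   landmarks are carried through the bone transform; patient-specific
   orthonormal frames are built from them (femur: mechanical axis
   hip-to-knee centre and the transepicondylar axis; tibia: malleolar
   midpoint to the tubercle/PCL midpoint, with the tubercle-to-PCL line as
   the AP axis).
3. **Implant pose** — the component's known local fiducials are registered
   onto their observed CT positions with the closed-form Kabsch (SVD)
   solution.
4. **Component position report** — alignment angles
   (flexion/extension FE, varus/valgus VV, internal/external rotation IE,
   as projection angles of the component axes in the anatomic planes),
   placement translations along AP/ML/SI, and the six bony resection
   thicknesses (signed plane distances from the pre-operative bone's
   regional extreme points to the posed resection planes).

The package also implements the accompanying reproducibility and
reliability statistics (maximum deviation from the mean with z-based 95%
confidence half-widths, ICC(2,1)/ICC(3,1) with clinical interpretation
bands, effective-dose conversion) and a fully parametric synthetic knee
phantom with analytically known ground truth, so the entire pipeline is
testable without patient data.

## Worked example

Simulate a noisy post-operative case (vertex noise 0.3 mm, fiducial noise
0.2 mm, CT frame offset 10 degrees / 20 mm) and analyse it:

```r
library(kneepose)

sim    <- simulate_tka_case(phantom_spec(seed = 11))
report <- analyze_case(sim$case, sim$implants)
print(report)
```

```
TKA component position report (right side)
  convention: projection angles; flexion, varus, internal rotation positive; anterior, lateral, superior translations positive; side-aware

Femoral component:
  alignment (deg): FE +2.09  VV -1.08  IE +0.96
  placement (mm):  AP -0.95  ML +0.50  SI -0.58
  resections (mm):  distal_medial 8.83, distal_lateral 7.66, posterior_medial 9.25, posterior_lateral 8.02
  fiducial fit rms 0.321 mm; ICP rms 0.464 mm (14 iter)

Tibial component:
  alignment (deg): FE +3.31  VV -0.16  IE -5.18
  placement (mm):  AP +0.50  ML -0.54  SI -1.08
  resections (mm):  plateau_medial 11.27, plateau_lateral 10.76
  fiducial fit rms 0.329 mm; ICP rms 0.459 mm (14 iter)
```

The femoral component sits in 2.1 degrees of flexion, 1.1 degrees of
valgus (VV negative) and 1 degree of internal rotation relative to this
phantom's mechanical and transepicondylar axes, with ~8-9 mm distal and
posterior condylar resections; the generator's ground truth for this seed
is FE 2.00, VV -1.00, IE 0.96, so every angle is recovered to within a
tenth of a degree under CT-scale noise. `as.data.frame(report)` gives the
same numbers as one row per component; `cmd_analyze()` runs the identical
pipeline from STL/JSON files on disk and writes JSON + CSV reports.

The reproducibility statistics work on long-format measurement tables:

```r
t1 <- cmd_stats(system.file("extdata", "reproducibility_alignment.csv",
                            package = "kneepose"), tempdir())
subset(t1$summary, case == "case1" & variable == "femoral_FE")
#>    case   variable n max_abs_dev      ci95 max_abs_dev_rounded ci95_rounded
#> 1 case1 femoral_FE 6   0.2166667 0.0935431                 0.2          0.1
```

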