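# gaparea3d

Quantitative 3D CT assessment of tibial plateau fracture displacement.

Tibial plateau fractures break the articular surface of the knee into
displaced fragments, and the degree of that initial articular disruption
largely determines whether the patient will eventually need a total knee
arthroplasty (TKA). The conventional measure — maximum gap and step-off on
one 2D CT slice — is observer-dependent and underestimates displacement.
This package implements the **3D gap area**: the area (mm²) of the surface
spanning *all* fracture lines between *all* fragments at the articular
level, measured on 3D bone models segmented from the diagnostic CT.

For a fracture line of length *L* separated by an in-plane gap *g* and a
step-off *s*, the spanning surface is the ruled sheet between the two
articular edges, with area

&nbsp;&nbsp;&nbsp;&nbsp;*A = L · √(g² + s²)*,

so the total gap area aggregates every inter-fragment articular
discontinuity into one number. The prognostic layer stratifies patients
into four groups (excellent ≤ 150, good 150–550, moderate 550–1000, poor
> 1000 mm²), flags high risk at the Youden-optimal cut-off of 550 mm², and
models native-knee survivorship (Kaplan–Meier, log-rank, Cox with
adjustment for age, sex, smoking, BMI and reduction adequacy).

The package contains the full pipeline (HU ≥ 226 thresholding,
connected-component fragment labelling, marching-tetrahedra meshing with
volume-preserving smoothing, articular delineation, fracture-line
trimming, loop closure, spanning-surface triangulation), the statistical
layer, and synthetic fracture phantoms plus cohort simulators with
analytic ground truth so that everything is testable without patient data.
Intended users are musculoskeletal imaging researchers and trauma
epidemiologists working with 3D fracture models.

## Worked example

A cylinder phantom (radius 25 mm, 0.5 mm voxels) split by a diametral cut,
the lateral half displaced by a 3 mm gap and a 4 mm step-off. The analytic
gap area is 2·25·√(3² + 4²) = 250 mm².

```r
library(gaparea3d)

ph <- make_phantom(split_cylinder_spec(g = 3, s = 4))
ph
#> <phantom> cylinder, 2 fragment(s), analytic gap area 250 mm^2

report <- run_pipeline(ph)
report
#> Gap-area report (config eef69c17)
#>   fragments: 2, fracture lines: 2, loops: 1
#>   total 3D gap area: 248.627 mm^2 -> good
```

The measured 248.6 mm² is within 0.6% of the analytic truth; 250 mm² falls
in the *good* prognostic band (150–550 mm²] and below the 550 mm²
high-risk cut-off. On real data, `run_pipeline()` takes a NIfTI CT volume
plus per-vertex articular annotations (`read_volume()`,
`read_annotations()`) instead of a phantom.

The cut-off machinery reproduces the published operating points:

```r
select_cutoff(gap_cutoff_table())
#> [1] 550
#> attr(,"youden_j")
#> [1] 0.502
```

and a simulated cohort with the default hazard structure behaves like the
clinical one:

```r
co <- simulate_cohort(n = 534, seed = 42)
prognosis_report(co)
#> Prognosis report (config eef69c17)
#>   AUC: 0.778, selected cut-off: 574.43 mm^2
#>   log-rank: chi-sq 97.3 on 3 df, p = <2e-16
#>   adjusted HR (high risk): 9.09 (4.97-16.64)
```

A thin command-line front end (`inst/scripts/gaparea3d`) exposes the verbs
`segment | measure | classify | prognosis | simulate | run`.

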