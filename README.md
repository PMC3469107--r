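# ptxquant

Automated quantification of pneumothorax from chest CT.

A pneumothorax — air trapped in the pleural space between lung and chest
wall — is graded for treatment largely by its size relative to the
hemithorax: collections under roughly 20% are usually managed conservatively.
Radiographic estimates of that size are crude and reader-dependent; CT sees
the full 3D extent, but manual slice-by-slice contouring takes hours per
scan. `ptxquant` implements a fast, automated CT pipeline for radiologists
and imaging researchers who need an objective relative pneumothorax volume,
plus the synthetic phantoms and agreement statistics to validate it without
patient data.

## Method

The pipeline runs in two tiers.

**2D processing (per slice).** Each slice *f*(*x*, *y*) is smoothed with a
discretized Gaussian kernel (σ = 0.5, 5×5). A fixed cut at
Th<sub>M</sub> = −500 HU yields a body-mask candidate; enclosed holes (lung
parenchyma and intrathoracic air, which fall below the cut) are restored by
binary morphological reconstruction: complement the mask, reconstruct the
border-connected background, complement again. The morphology layer
implements the standard set algebra — dilation
*A* ⊕ *B* = {*c* | *c* = *a* + *b*, *a* ∈ *A*, *b* ∈ *B*}, erosion
*A* ⊖ *B* = {*c* | *c* + *b* ∈ *A* ∀*b* ∈ *B*}, the duality
(*A* ⊖ *B*)ᶜ = *A*ᶜ ⊕ *B̌*, the erosion chain rule
*A* ⊖ (*B* ⊕ *C*) = (*A* ⊖ *B*) ⊖ *C*, and reconstruction of a mask from a
marker as the union of the connected components meeting the marker — with
the 2×2 disk structuring element. Two adaptive cutoffs are then estimated
from the HU histogram of the masked volume: Th<sub>A</sub> separating air
from lung parenchyma (typically near −870 HU) and Th<sub>L</sub> bounding
parenchyma against soft tissue (between the parenchyma and soft-tissue
modes). Voxels below Th<sub>A</sub> are labeled air, voxels in
[Th<sub>A</sub>, Th<sub>L</sub>) lung.

**3D processing.** The per-slice air labels are stacked and connected
components are labeled in 3D (26-connectivity by default). A pneumothorax
must have finite boundaries inside the pleural cavity, so any component
continuous with air spaces outside it — touching non-body voxels or the
volume's end slices (trachea, esophagus, bowel gas entering the scanned
range), seeded as the tracheal lumen, or smaller than a noise guard — is
excluded whole. Surviving air voxels and the lung voxels give

> V<sub>ptx</sub> = V<sub>air</sub> / (V<sub>air</sub> + V<sub>lung</sub>)

with volumes in mm³ from the voxel spacing.

The package also ships: a synthetic thorax phantom generator (lungs,
carvable pleural crescent of exact target fraction, trachea, bowel gas,
bone, Gaussian noise) with ground-truth labels; DICOM-series and NIfTI
readers and NIfTI writers; agreement statistics (absolute errors, Pearson r,
paired t, OLS trendline) for comparing automated against reference
measurements; and a command-line interface.

## Worked example

Agreement between the published eight-case automated and manual
measurements:

```r
library(ptxquant)
tb <- table1_preset()
mc <- compare_methods(tb$auto_pct, tb$ref_pct, tb$case_id)
print(mc)
#> method_comparison over 8 cases
#>   mean absolute error: 0.99%
#>   Pearson r: 0.996
#>   paired t: t = 0.16, p = 0.8771
#>   trendline: auto = 1.083 * ref + -1.071 (R^2 = 0.992)
```

The two methods disagree by 0.99 percentage points on average, correlate at
r = 0.996, and the paired t-test (t = 0.16, p = 0.88) gives no evidence of a
systematic offset.

End-to-end run on a synthetic phantom with a known 20% pneumothorax:

```r
ph <- generate_phantom(phantom_spec(ptx_fraction = 0.20, seed = 42))
ph$achieved_ptx_fraction
#> [1] 0.1999953
res <- run_pipeline(ph$volume, case_id = "demo")
print(res$report)
#> volume_report
#>   V_air :     19641.65 mm^3
#>   V_lung:     85114.22 mm^3
#>   V_ptx : 18.75%
#>   components kept/excluded: 1/193
#> threshold_set (histogram_estimated): th_m = -500, th_a = -885.196, th_l = -425 HU
```

The pipeline recovers 18.75% against a 20.00% ground truth (−1.25
percentage points, dominated by partial-volume voxels on the air/chest-wall
interface at this 128×128 grid); the trachea, the bowel gas and 191 noise
speckles were excluded, the pleural pocket kept as the single retained
component.

### Command line

```sh
Rscript inst/cli/ptxquant.R phantom  --ptx-fraction 0.2 --seed 42 --out ph/
Rscript inst/cli/ptxquant.R quantify --input ph/volume.nii.gz --out out/
Rscript inst/cli/ptxquant.R evaluate --preset table1 --out eval/
```

(After installation the script lives at
`system.file("cli", "ptxquant.R", package = "ptxquant")`.)

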