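# spinefuse

Automated contour-focused rigid registration of a planning CT with a
CT-myelogram for postoperative spine SBRT planning — plus the digital
phantom, evaluation metrics and non-inferiority statistics needed to test
whether the automated registration can stand in for a trained human
operator.

## The problem

After surgical stabilization of spinal metastases, the fixation hardware
often rules out MRI, so the spinal cord is delineated on a CT-myelogram and
fused to the planning CT by a rigid registration accurate to 1 mm / 1°. The
lesioned vertebra is typically destroyed by tumor, so the registration must
be driven by the neighbouring intact bone and the hardware, not by point
landmarks. The automated workflow (A-RIR) implemented here:

1. selects the landmark vertebral levels from the lesion annotation
   (a 1–2 vertebra lesion is extended one level up and down; 3+ lesioned
   vertebrae are used as-is);
2. extracts a bone + hardware contour from the planning CT (≥ 650 HU within
   the selected levels, closed 1 mm, dilated 2 mm);
3. aligns the whole images by maximizing normalized mutual information
   (the *baseline*);
4. refines the alignment by maximizing NMI restricted to the contour.

The similarity metric is

NMI(A, B; T) = [H(A) + H(B) − H(A,B)] / H(A,B),

computed from a 64×64 joint histogram of intensities paired under the
candidate rigid transform T — Studholme's overlap-invariant measure shifted
onto a 0–1 scale, equal to 1 exactly when the images are identical and
perfectly aligned. Optimization is Nelder–Mead through a 3-level image
pyramid with a multi-candidate coarse grid search, so the search survives
the near-periodicity of a stack of similar vertebrae.

Because the study's patient scans are not distributable, the package ships
a digital spine phantom generator (vertebral bodies with posterior
elements, pedicle-screw hardware, a lytic lesion, contrast-enhanced CSF in
the myelogram phase, CT texture and noise) with exact, analytically-applied
ground-truth misalignments — every registration claim in the test suite is
checked against known truth.

## Worked example

```r
library(spinefuse)

# a phantom pair whose secondary is misaligned by a known rigid transform
ctr <- c(51.015, 51.015, 80)
spec <- phantom_spec(noise_sd = 15, seed = 3,
                     true_transform = rigid_transform(3, -2, 4, 1.5, -1, 2,
                                                      center = ctr))
pair <- generate_phantom_pair(spec)

ann <- list(lesion_levels = pair$truth$lesion_levels,
            level_boundaries = pair$truth$level_boundaries)
fit <- run_arir_workflow(pair$primary, pair$secondary, ann)
summary(fit)
#> A-RIR fit summary
#>   parameters (mm / deg):
#>      tx      ty      tz      rx      ry      rz
#>  3.0527 -2.0323  3.9888  1.5752 -0.9548  2.0239
#>   rotation center: (50.96, 49.34, 81.33) mm
#>   masked NMI baseline/final: 0.1905 / 0.1967 (delta +0.0062)
#>   landmark levels: 3, 4, 5, 6; contour voxels: 99941; metric evaluations: 12521

decompose_difference(fit$transform, spec$true_transform,
                     center = mask_centroid(fit$mask))
#> Translation error (AP, LR, CC): 0.004, 0.016, 0.034 mm; |t| = 0.038 mm
#> Rotation error (axial, coronal, sagittal): 0.023, 0.046, 0.076 deg
```

The six recovered parameters sit within a fraction of a voxel of the true
misalignment; the masked NMI improves over the whole-image baseline (the
`delta` is the per-case quantity the study compares between the automated
and human arms); and the error decomposition reports the per-axis
translation (mm), per-plane rotation (degrees) and absolute 3D translation
gap between two registrations — here, recovered vs truth.

The statistics layer reproduces the study's decision rule from vote counts
alone:

```r
records <- c(rep(list(rep("ARIR", 3)), 17),
             rep(list(rep("EQUIV", 3)), 4),
             rep(list(rep("HRIR", 3)), 7))
noninferiority_test(records, margin = 0.45)
#> Blinded review: A-RIR 17, equivalent 4, H-RIR 7 (n = 28)
#> A-RIR preferable or equivalent: 0.75 (95% CI 0.55-0.89)
#> Non-inferior at margin 0.45: yes
```

`run_study_demo()` chains everything end to end on generated phantoms:
baseline + A-RIR registration, an emulated human arm (truth plus ≤ 0.5 mm /
0.3° jitter), per-case evaluation over the A-RIR contour, an emulated
three-evaluator blinded review, and the vote/t-test/ANOVA statistics.

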