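---
title: "Contour-focused rigid registration for postoperative spine SBRT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-focused rigid registration for postoperative spine SBRT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Postoperative spine SBRT needs the spinal cord delineated on the planning CT.
When surgical hardware makes MRI unusable, the cord is taken from a
CT-myelogram (intrathecal iodinated contrast outlining the CSF) and fused to
the planning CT by a rigid registration. The clinical accuracy requirement is
1 mm / 1 degree — both scans are acquired at 1 mm slices — and the lesioned
vertebra is typically too destroyed for point landmarks, so the registration
is driven by the intact neighbouring bone and the fixation hardware.

`spinefuse` implements the automated version of that workflow (A-RIR):

1. select landmark vertebral levels from the lesion annotation,
2. extract a bone + hardware contour from the planning CT by thresholding,
3. align the whole images by normalized mutual information (the baseline),
4. refine by maximizing NMI restricted to the contour.

It also implements the surrounding study machinery: a digital spine phantom
with known ground truth, the per-case quantitative evaluation, and the
non-inferiority statistics used to compare automated against human
registration.

## The similarity metric

For volumes $A$ (planning CT) and $B$ (myelogram) and a candidate rigid
transform $T$, intensities are paired by sampling $B$ with trilinear
interpolation at $T(p)$ for every voxel $p$ of $A$ inside the contour. Pairs
mapping outside $B$ are dropped. Both intensities are clipped to
$[-200, 1500]$ HU and binned into a $64 \times 64$ joint histogram, from
which Shannon entropies $H(A)$, $H(B)$, $H(A,B)$ are computed in nats.

We report
$$\mathrm{NMI} = \frac{H(A) + H(B) - H(A,B)}{H(A,B)},$$
i.e. the overlap-invariant measure $(H(A)+H(B))/H(A,B)$ shifted down by 1.
This maps its $[1,2]$ range onto $[0,1]$ with the value 1 attained exactly
when the two images are identical and perfectly aligned, which is the scale
used throughout. The ratio is invariant to the logarithm base. When
$H(A,B) = 0$ (both images constant), the images are trivially matched and
the value is defined as 1. Values are clamped to $[0,1]$ against
floating-point drift.

Choices a different implementation might make differently, all configurable:
64 bins per axis (a common default that keeps ~50+ samples per occupied bin
on contour-sized samples), the clip range (covers soft tissue through
hardware; extreme metal values compress into the top bin), and plain
trilinear sampling rather than partial-volume histogramming. Absolute NMI
values depend on all three, so only NMI *differences* and orderings are
meaningful across implementations — the study design (improvement from a
common baseline, perturbation losses) uses exactly those.

## The landmark contour

Levels: a lesion confined to 1–2 vertebrae is extended one level up and one
down (3–4 landmark vertebrae); a lesion spanning 3+ vertebrae is used as-is.
The extension clips at the image boundary.

Mask: voxels of the *primary* (plain planning CT) at or above 650 HU within
the craniocaudal range of the selected levels, morphologically closed (1 mm)
and dilated (2 mm). The threshold exceeds contrast-enhanced CSF (~600 HU) so
that myelographic contrast could never enter the contour even if the
extraction were run on the secondary; on plain CT it captures cortical bone
and hardware (metal HU being far above bone). The dilation admits a thin rim
of adjacent soft tissue, which stabilizes the histogram; closing protects
thin cortical shells from noise punch-through. All three parameters are
user-configurable; vertebral level identification itself is taken from the
annotation rather than learned, keeping the component deterministic and
auditable.

## The optimizer

Six parameters: translations (mm) along the LPS axes and rotations (degrees)
applied intrinsically in the order axial (z) → coronal (y) → sagittal (x),
about a stated center — the contour centroid for the refinement (it is the
registration target, minimizing translation–rotation coupling), the volume
center for the baseline. At the sub-degree errors relevant here the Euler
order is numerically immaterial, but it is fixed and serialized with every
transform.

Search is derivative-free Nelder–Mead through a 3-level mean-pooling image
pyramid (factors 4, 2, 1), with parameters naturally scaled (1 mm ≈ 1
degree). Mean-pooling doubles as the antialiasing filter. Each level allows
up to 800 metric evaluations; on coarse levels a collapsed simplex is
restarted (fresh simplex at its own best point, up to 3 times) because an
init far from the optimum can collapse prematurely.

The baseline starts from a translation grid search (±20 mm, 5 mm steps) at
the coarsest level. On a stack of similar vertebrae the coarse metric can
prefer an alignment shifted by one level: the mismatched end slab leaves the
overlap and drops out of the histogram while everything else lines up. The
search therefore keeps up to 8 spatially distinct grid candidates (adjacent
grid points suppressed), refines each at the coarsest level, and — when the
leaders are within 0.08 NMI of each other — refines the top basins one
level deeper and then briefly at full resolution before comparing them. An
unrefined candidate under-reports its basin, so basins are always ranked
after refinement. In the full workflow the final comparison runs on the
landmark contour rather than the whole image: a one-level shift mismatches
vertebral body size and trabecular texture throughout the contour and is
punished decisively there, while on the whole image it is diluted by the
surrounding soft tissue. At the two finest levels the whole-image metric
subsamples every second voxel in-plane, a standard cost control with
negligible effect at these sample counts.

Two further safeguards address known pathologies of histogram metrics.
First, the finest-level *search* objective samples a lightly smoothed copy
of the secondary (separable 1-2-1 kernel, σ ≈ 0.7 voxel): joint histograms
of a sharp image reward grid-aligned transforms, whose integer-shift
sampling avoids interpolation and keeps the histogram artificially tight,
and on textured data this bonus can out-score the true sub-voxel alignment.
Smoothing the moving image removes the bonus; every *reported* metric value
uses the plain images. Second, after Nelder–Mead converges at the finest
masked level, a cyclic per-axis line search (±1.2 mm/degree in 0.15 steps)
sweeps each parameter and the simplex re-converges from any improvement —
this rescues the search from the shallow, noise-rippled valleys the masked
NMI shows along rotation axes.

Transforms that retain fewer than 25% of the sampled points are scored
below every valid NMI value, which repels the rank-based simplex without
aborting the search. The refinement never returns a transform whose
full-resolution masked NMI — the plain, reported one — is below its
initialization's, so the contour stage can only improve on the baseline.

## The phantom

The generator emulates the features of the clinical scans that the
registration actually uses, on the study's grid (1.074 × 1.074 × 1.0 mm
spacing, 96 × 96 in-plane, 8 levels of 20 mm by default):

* vertebral bodies (bone, 700 HU) with posterior arches, spinous and
  transverse processes around a canal containing cord (30 HU) and CSF
  (15 HU plain / 600 HU with contrast — iohexol-enhanced CSF sits above
  soft tissue and far below metal);
* paired pedicle screws (3000 HU) two levels above and below the lesion;
* a lytic lesion replacing bone by soft tissue over a seeded blob;
* additive Gaussian noise (default sd 15 HU), independent between the two
  volumes;
* a known rigid misalignment realized *analytically*: the secondary is the
  same tissue model evaluated at inverse-transformed coordinates, so the
  ground truth is exact and free of resampling blur.

Two anatomical details matter for identifiability and were added for that
reason. The posterior elements break in-plane rotational symmetry — a plain
cylinder stack cannot pin down axial rotation. And the vertebral body radius
tapers caudally (0.9 mm per level, as thoracic vertebrae grow toward
lumbar), breaking the level-to-level translation symmetry that would
otherwise make a one-level shift near-optimal. A smooth zero-mean intensity
texture (periods 6–9 mm, amplitudes 60 HU in bone, 15 HU in soft tissue)
rides on the tissue means and is carried rigidly with the anatomy: real CT
is textured, and a piecewise-constant phantom would reward grid-aligned
misalignments over sub-voxel-correct alignments, because interpolation at
fractional offsets smears the joint histogram while interior voxels carry
no alignment information.

The lesion geometry is seeded separately from the noise (`lesion_seed` vs
`seed`), so the structure masks are invariant across noise realisations.
An optional anterior soft-tissue mass that moves between the two phases
(`distractor_shift_mm`) creates anatomy that disagrees outside the bony
landmarks; it is how the tests isolate the contour restriction's advantage
over whole-image registration.

What the phantom does **not** emulate: metal streak artifacts and beam
hardening, curved or scoliotic spines, realistic trabecular texture
statistics, patient-to-patient anatomical variation, and the commercial
workflow's (undisclosed) metric variant. Passing phantom tests therefore
demonstrates correctness of the algorithmic machinery under controlled
conditions — capture range, sub-voxel convergence, the benefit of the
contour restriction — not clinical performance on patient scans.

## The study emulation

The demo pipeline mirrors the study design on generated cases. Human
registration, absent human operators, is emulated as truth plus a small
uniform jitter (±0.5 mm per axis, ±0.3 degrees per plane), consistent with
an operator working to a 1 mm protocol; with both arms near truth this
centers the automated-vs-human absolute translation gap on a few tenths of
a millimetre. The three blinded evaluators are emulated as thresholded
comparisons of the masked NMI of the two arms (individual thresholds 0.005,
0.01, 0.02, plus a small seeded perceptual noise), voting "equivalent"
inside their threshold. These are stand-ins for human behaviour, documented
as such; the statistics downstream of the votes are exact implementations.

Statistics: majority vote per case with three-way splits scored equivalent;
the proportion preferring the automated arm or equivalent gets an exact
Clopper–Pearson 95% interval (the exact method reproduces the published
two-decimal interval for 21/28, which a Wilson interval does not), and
non-inferiority requires the lower limit to *strictly* exceed the 0.45
margin. NMI improvements are compared by a one-sided paired t-test;
Pearson correlations across baseline/automated/human by one-way ANOVA with
Tukey HSD gated on the overall p < 0.05, as specified in the study protocol
(ungated Tukey is common practice, but the gate is what the protocol
states). The paired sample-size helper implements the standard
normal-approximation formula with effect = mean difference + margin; the
study's stated inputs (sd 0.11, difference 0.03, margin 0.05) yield 12
under this formula — and no standard variant we tried reproduces the
published 24 — so the function exposes its full arithmetic rather than
asserting any particular output.

## Numerical conventions and degenerate inputs

* Patient frame: LPS; AP error = y-component, LR = x, CC = z. NIfTI files
  are reconciled to LPS on read; only axis-aligned (possibly permuted or
  flipped) orientations are supported, oblique scans are rejected by name.
* Angles are stored in degrees; rotation matrices are built in double
  precision and transforms round-trip through JSON losslessly.
* Error decomposition between two registrations reports the parameters of
  $T_B^{-1} \circ T_A$ about the contour centroid; the absolute translation
  is the Euclidean norm of the translation components, exactly.
* Volumes are stored internally as 32-bit float HU; files are written as
  int16 when representable, float32 otherwise.
* Degenerate cases fail loudly rather than silently: empty landmark masks,
  zero retained histogram pairs, constant series in the correlation,
  all-zero paired differences in the t-test.
* Zero-magnitude perturbations report a loss of exactly 0 by construction.

## Problem sizes in the shipped tests

Unit tests run on a reduced phantom (64 × 64 × 64, four levels of 16 mm)
that preserves every structure; the end-to-end accuracy study uses 20 cases
at the full 96 × 96 × 160 geometry with misalignments up to 5 mm / 3 degrees
and noise sd 15 HU, and the demo-based checks use 5 such cases. These sizes
were chosen so the complete suite exercises the full-resolution pipeline
while remaining comfortable to run on one CPU.

## Known limitations

* The commercial system's metric variant, optimizer and contour mechanism
  are undisclosed; this package targets behavioural equivalence (sub-voxel
  recovery, the improvement-over-baseline structure), not bit-level
  reproduction, and absolute NMI values are implementation-specific.
* The rotation center about which the study reported its rotational errors
  is not stated; we use the contour centroid, and at the sub-degree errors
  involved the choice moves translation components by well under 0.1 mm.
* Vertebral level identification is annotation-driven, not automated.
* Registration of multiple separate lesions, deformable registration, and
  MRI fusion are out of scope.
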