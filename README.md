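# fluoromotion

Cardiac and respiratory motion limit how accurately an image-guided
intervention (IGI) system can overlay preprocedural 3D anatomy onto live
X-ray fluoroscopy. On a monoplane C-arm the 3D position of a device
marker must be reconstructed from two *sequentially* acquired views, and
a reference 3D position (e.g. a marker identified in postprocedural
cardiac MR) is only valid for the cardiac and respiratory phase in which
that reference was acquired. `fluoromotion` implements the complete
analysis pipeline for quantifying this motion-dependent accuracy, aimed
at researchers in interventional cardiology and image-guided therapy who
want to measure — or simulate — how much accuracy is lost when frames
from the wrong cardiac or respiratory phase are used.

## What it computes

**Two-view localization.** The marker identified at detector positions
in two views is back-projected to its projection lines. Because the
lines are skew in real data, the marker estimate is the midpoint of the
*Nadir points* — the mutually closest points on the two lines:

    P_pair = (N_a + N_b) / 2,   gap = ||N_a - N_b||

The image-plane consistency of `P_pair` is measured by re-projecting it
onto each view and reporting the distance to the identified marker
(ε_2DXRproj). Its 3D accuracy is the distance to the co-registered
reference marker P_CMR.

**Single-view localization.** With only one view, the marker estimate is
the Nadir point of P_CMR on the single back-projected ray
(P_single); the perpendicular point-to-line distance is the single-view
error sample. Displacement components along the view axis are invisible
in this construction, so single-view errors provably never exceed the
corresponding two-view distances — a bound the test suite checks on
every simulated study.

**Motion categories.** Each frame gets a cardiac phase (percent of the
RR interval from the recorded ECG R-peaks) and a respiratory label from
a Savitzky-Golay-filtered diaphragm-surrogate trace, scaled to the
isocenter and gated with a 3 mm acceptance window. Frames are then
binned: c1 expiration/30-40 % RR (motion-synchronized with the
reference), c2 inspiration/30-40 %, c3 expiration/80-90 % (atrial
systole), c4 inspiration/80-90 %. Per category the package reports the
averaged Euclidean distance (AED) ± SD to the reference, Shapiro-Wilk
normality, and Welch's test against c1.

**Error budget.** The closed-form accuracy estimate chains half-diagonal
pixel/voxel identification errors:

    ε_2DXR,iso = ε_2DXR / M
    ε_3DXR     = sqrt(ε_2DXR,iso² + ε_XRgeo²)
    ε_2DXRproj = ε_3DXR · M
    ε_tot      = sqrt(ε_3DXR² + ε_CMR²)

with M = SID/SOD the isocenter magnification.

**Synthetic phantom.** `simulateStudy()` generates studies with known
ground truth: a marker with an additive atrial-systolic bump
(raised-cosine in cardiac phase) and a quasi-periodic respiratory
displacement with end-expiratory dwell, imaged at 15 fps under one or
two angulations with identification noise, RR variability, a larger
diaphragm surrogate, and a reference position offset by a known,
injected co-registration error. Every pipeline stage is testable against
this ground truth.

## Worked example

```r
library(fluoromotion)
geoms <- list(CArmGeometry(label = "AP"),
              CArmGeometry(label = "LAO60", primary_deg = 60))
study <- simulateStudy(motionParams(seed = 42), geometries = geoms,
                       duration_s = 60, registration_error = c(1.2, 0.8, 0.5))
report <- analyzeStudy(study)
report
```

```
pair analysis: 45 matched frame pairs
single-view categorization: c1=45, c2=26, c3=49, c4=22
Accuracy report (distances to the co-registered reference, mm)
  cat     n      AED       SD    p_vs_c1
  c1     45     1.27     0.08          -
  c2     26     2.13     0.16     0.0000     **
  c3     49     1.90     0.22     0.0000     **
  c4     22     3.97     0.29     0.0000     **
  pair block: 45 pairs, 3D AED 1.49 (0.11) mm, reprojection AED 0.15 (0.14) mm, separation 60.0 deg
```

The injected registration offset has a 1.30 mm component perpendicular
to the AP view axis, and the motion-synchronized category c1 recovers
essentially that value (single-view distances cannot see the along-axis
component); the off-phase categories are significantly worse — respiratory mismatch
(c2) mainly shifts the mean, cardiac mismatch (c3, c4) adds the
atrial-systolic displacement. The pair block shows the two-view
reconstruction agreeing with both detectors to ~0.15 mm in the image
plane.

The budget with default parameters (1.3 mm reference voxel, 0.2 mm 2D
identification error, 0.2 mm geometry error, magnification 1.5, rounded
intermediates):

```r
propagateBudget()
```

```
Error budget (mm):
  2D XR identification (half pixel diagonal)        0.2  (0.2000)
  3D reference identification (half voxel diagonal)  1.1  (1.1258)
  2D XR at isocenter scale                          0.1  (0.1333)
  intrinsic XR geometry                             0.2  (0.2000)
  two-view 3D localization                          0.2  (0.2404)
  3D error re-projected to image plane              0.3  (0.3606)
  total 3D (XR + reference)                         1.1  (1.1512)
```

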