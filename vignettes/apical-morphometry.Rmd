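---
title: "Computer-aided morphometry of the root-canal apex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-aided morphometry of the root-canal apex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexmetry)
```

## The measurement problem

Evaluating an electronic apex locator requires knowing where an endodontic
file tip actually ended up relative to two anatomical landmarks of the
root-canal apex: the **apical constriction** (AC), the narrowest
cross-section of the canal and the intended endpoint of instrumentation,
and the **apical foramen** (AF), the canal's terminal opening at the root
surface. Classically both landmarks are located by eye under magnification,
which is subjective and poorly reproducible. apexmetry implements an
objective alternative: starting from a calibrated cross-sectional image in
which the two canal walls and the file tip have been digitally marked, it
detects AC and AF automatically, measures their diameters and separation,
and computes signed distances from the file tip to each landmark.

## From marked walls to a width profile

The annotation is two ordered wall polylines plus a tip point, in pixel
coordinates (origin top-left, y downward, 0-based) with a single
micrometre-per-pixel calibration; all downstream quantities are in mm.
Annotations arrive either as explicit polylines or as a label image whose
strokes are vectorised by tracing each label's pixel set as the diameter of
its 8-connected adjacency graph (two breadth-first searches), which is
robust to the spurs and micro-loops of digitised strokes, followed by
Ramer–Douglas–Peucker simplification at 0.1 px. The tolerance is kept well
below one pixel deliberately: the stroke's subpixel position is recovered
later by averaging, and a coarser simplification would discard it again and
flatten shallow width minima into wide plateaus.

A **medial path** between the walls carries the axial coordinate. It is
seeded by pairing every wall-A vertex with its nearest point on wall B,
anchored at the apical terminus (the midpoint of the two apical wall
endpoints), then symmetrised by a short fixed-point iteration that
re-centres every resampled point onto the midpoint of its nearest points on
both walls, and finally relaxed with a short moving average so that
residual point noise does not inflate the arclength parameterisation. The
coronal tail, where the correspondence clamps at a wall's last vertex, is
trimmed as a boundary artefact. A raw merge-and-sort of midpoints from both
walls, the most obvious construction, is not used: nearest-point feet snap
to polyline corners across the (wide) canal lumen and the merged sequence
zigzags, inflating arclength severalfold.

The **width profile** assigns to each medial sample the length of the chord
joining its nearest points on either wall — the discrete version of the
smallest distance between the walls at that axial station. Chords that
cross a wall (possible at sharp bends) are dropped.

## Landmark detection

**AF** is the canal's opening: its chord joins the two apical terminal wall
endpoints, by construction at axial station $s = 0$. Its diameter is the
chord length.

**AC** is the narrowest cross-section within an apical search window
(default 3 mm, configurable; the constriction is an apical-region feature,
so the search is bounded away from coronal narrowings). The in-window profile minimum
seeds the search; the first in-window sample is excluded so the foramen is
never re-detected, and ties break toward the most apical sample. Around the
seed, the constriction *station* is localised by a continuous-breakpoint
two-limb ("hinge") least-squares fit of perpendicular-ray widths,

$$w(s) \approx b_0 + p\,(s_k - s)_+ + r\,(s - s_k)_+ ,$$

which is unbiased for a kinked profile with unequal limb slopes, where a
raw argmin drifts toward the shallow limb under digitisation noise.
Perpendicular-ray widths (the chord through the medial point normal to the
local path tangent) are used for the fit because nearest-point chords carry
a wall-tilt bias that bends the V's limbs. The final chord is cut against
the *unsmoothed* annotation — smoothing stabilises the fit but rounds the
constriction corner and would lift the measured diameter:

* shallow constrictions (fitted slopes $\le$ 1.5): the chord at the fitted
  station; its width is insensitive to small station errors there;
* steep constrictions: a dense local minimal-distance search, pinned to the
  corner; near-ties within half a pixel resolve toward the steep limb, and
  a disagreement of more than 3 µm with the fitted station triggers a tight
  re-search around the fit.

A canal that only tapers, with no re-flare toward the foramen, has no
interior V anywhere near the apical boundary; it is reported as the most
apical in-window chord with a "no distinct constriction" warning.

The AC–AF distance is the perpendicular distance from the AC chord midpoint
to the line through the AF chord — the same construction as the tip
distances, with the AC midpoint in the tip's role.

## Signed tip distances and position classes

The distance from the tip to a landmark is the perpendicular distance to
the infinite line through the landmark chord. This equals the
trigonometric construction $D = b \sin\alpha$, with $b$ the distance from
the tip to the nearer chord endpoint and $\alpha$ the angle there between
chord and tip segment; both diagnostics are returned and the identity holds
to $10^{-9}$ mm by construction. Arclength along a curved canal would be a
different quantity requiring a different formula; the perpendicular
distance is exactly what the triangle construction measures.

Signs follow the convention that **negative = beyond (apical to) the
landmark**. The apical side of a chord is identified by a reference point
known to lie apical of both chords; since the medial path *starts on* the
AF chord, the path's first point is extrapolated one step outward along the
terminal tangent to obtain it. Classification:

| $D_{AC}$ | $D_{AF}$ | class |
|---|---|---|
| $> 0$ | — | `SHORT_OF_AC` |
| $\le 0$ | $\ge 0$ | `BETWEEN_AC_AF` |
| — | $< 0$ | `BEYOND_AF` |

A tip exactly at a landmark counts as having reached but not passed it, so
both boundary cases classify `BETWEEN_AC_AF`; over-instrumentation requires
strictly passing the foramen. The pair $D_{AC} > 0$ with $D_{AF} < 0$ is
geometrically impossible when AC is coronal to AF and raises a validation
error.

## Statistics

* `icc_absolute_agreement()` — ICC(2,1): two-way random effects, absolute
  agreement, single measurement, with the F-based 95% confidence interval
  (Satterthwaite degrees of freedom) and p-value. This form is appropriate
  when different raters re-measure the same images and absolute distances
  matter; a consistency form would ignore systematic rater offsets.
* `oneway_anova()`, `ttest_independent()` — classical one-way ANOVA and the
  two-sided pooled-variance t-test (Welch by flag), delegating to the
  standard R implementations.
* `fisher_exact()` — two-sided exact p. For 2×2 tables the conditional
  hypergeometric distribution is evaluated directly and all tables no more
  probable than the observed one are summed; r×c tables use the network
  algorithm, with a Monte-Carlo option beyond a total of 200.
* `beyond_af_tests()` — the group comparison of over-instrumentation: all
  pairwise 2×2 exact tests on the beyond-AF dichotomy with Holm adjustment,
  plus the omnibus exact test. Pairwise-with-Holm is the primary analysis
  because the scientific conclusions are pairwise statements about which
  measurement mode over-instruments more often.
* `cohort_summary()` — per-group means and sample SDs (n − 1 denominator)
  of diameters and distances, plus the group × position-class count table.

## The synthetic apex generator

Because no annotated image corpus is distributable, every pipeline stage is
validated against a generator whose ground truth is known exactly. A
generated apex is an hourglass: canal width tapers linearly from the
coronal width to the AC diameter at the configured AC–AF distance from the
terminus, then re-flares linearly to the AF diameter at the terminus. Walls
are the centerline offset by half the local width along the normal; the
centerline is straight by default or a circular arc of configurable
curvature. The file tip sits on the terminal tangent at a signed offset
from the AF chord (negative = beyond). Hand-marking tremor is emulated by
smoothly correlated Gaussian vertex jitter (window-averaged white noise,
marginal SD 2 µm ≈ one pixel by default) — independent per-vertex noise is
both unrealistic for a hand-drawn stroke and occasionally self-intersecting.
Rendering rasterises the walls as 1-px chains and the tip as a single pixel
into a label PNG at 2 µm/px on a canvas auto-sized with a 10% margin,
alongside a JSON sidecar and a ground-truth JSON that the measurement
pipeline never reads.

Cohorts mirror a three-group study design (RPM, EPM, EPA; 40 specimens per
group by default): AC diameter 0.27 (0.11) mm, AF diameter 0.64 (0.22) mm
and AC–AF interval 0.36 (0.26) mm as truncated normals (lower bounds
0.05 mm, and AC + 0.05 for AF, keeping geometry physical), and per-group
signed tip offsets from the foramen as normals — RPM 0.301 (0.22), EPM
0.411 (0.28), EPA 0.238 (0.35) mm. Normality is an explicit modelling
choice; only moments are available to match. The truncated distributions
are parameterised by their **post-truncation** means (the underlying
location is solved by root-finding, sampling by inverse CDF): the point of
the default cohort is that measured cohort means recover the configured
values directly, which plain location-parameterised truncation would break
(the AC–AF interval would shift by +0.058 mm). When a conditional bound
makes a target mean unattainable — an extreme companion draw — the target
is used as the location instead, a negligible-bias fallback on rare draws.

What the generator does *not* emulate: dentin texture, stain or lighting
variation, accessory canals, non-planar (3-D) canal paths, marking errors
of anatomy rather than of stroke placement. Passing the synthetic suite
therefore demonstrates correctness of the geometry and statistics given a
faithful annotation, not robustness to annotation mistakes.

## Numerical choices

* Medial sampling step 0.01 mm; wall moving-average window 3 during path
  construction (final chords always measured against the raw annotation);
  hinge-fit window ±0.12 mm around the seed minimum.
* Steep/shallow branch threshold: fitted limb slope 1.5 (dimensionless,
  width per axial mm); near-tie band 0.5 px; station re-search trigger 3 µm.
* Chord admissibility during refinement tolerates grazing intersections
  within two pixels of the chord's own endpoints: digitised strokes are
  jagged at the pixel scale, and a chord anchored on a wall routinely clips
  an adjacent stair tooth without actually crossing the canal.
* The generator's profile places a vertex exactly at the constriction
  station so the true minimal chord is realisable by the polyline.
* Validation problem sizes: 200 rendered jitter-free apices for end-to-end
  recovery (every quantity within 2 px·scale = 4 µm), a 120-specimen
  rendered default cohort for summary-statistic recovery (within 3
  Monte-Carlo SE), 2000 EPA draws for the over-instrumentation frequency,
  50 coarse sections against a brute-force enumeration oracle, and the full
  set of ~132,000 2×2 tables with total ≤ 40 for the exact test.
* The brute-force oracle comparison runs on jitter-free sections: with
  jitter, the global vertex-pair minimum chases noise dips anywhere along
  the canal and measures a different quantity than the denoised
  constriction width that ground-truth recovery rewards.

## Known limitations

* The medial curve of the symmetric nearest-point construction carries a
  small lateral bias growing with curvature × taper²; at curvature
  0.1 mm⁻¹ it reaches ~1 µm in the steep foramen flare. Landmark
  measurements are unaffected at the micron scale, but centerline fidelity
  claims are only validated up to mild apical curvature.
* Two-dimensional sections of a three-dimensional anatomy: AC and AF are
  not planar entities, and a single section can misrepresent both. The
  package measures the section it is given.
* The AC search window and the smoothing/refinement constants are
  reconstructions; the original experimental software's search strategy is
  not documented, so recovery of known synthetic truth — not replication of
  a reference implementation — is the validation standard.
* Reliability statistics reproduce the study design (two raters, repeated
  measurement) but no attempt is made to reproduce a specific published
  ICC value, whose exact model is unspecified.
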