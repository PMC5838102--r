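---
title: "Measuring axon and myelin morphology along 3D label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axon and myelin morphology along 3D label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmorph)
```

## The measurement problem

Serial block-face scanning electron microscopy (SBF-SEM) produces aligned
stacks of block-face images — typically 5 nm pixels in-plane and 50 nm
cutting increments, so 2000 sections span 100 µm of tissue. After
segmentation, each myelinated axon is an instance-labelled tube winding
through the stack, wrapped by compact myelin and, in pathology, by patches
of *decompacted* myelin (lamellae that have separated and swollen). The
classical single-section approach measures many axons in one plane and
assumes each axon's shape is representative; 3D data lets one instead walk
along each axon and ask how much its calibre, sheath and nodal architecture
vary over its length.

`axonmorph` implements that walk. Its inputs are integer label volumes
(multi-page TIFF) in which semantic classes occupy label ranges declared by
a `channel_map`: axon instance *i* carries label *i*, its compact and
decompacted myelin carry *i* + 1000 and *i* + 2000, and mitochondria carry
their own instance labels above 3000. A voxel has exactly one label, so the
classes are disjoint by construction; the offset pairing makes the
axon–myelin association explicit rather than inferred.

All physical outputs are in µm (µm² for areas), converted once from the
nm-valued voxel spacing at measurement time. Stacks are stored `[y, x, z]`
with 1-based indices and the voxel-centre convention
`(i − 0.5) · spacing`.

## Per-slice measurements

Measurements are taken in the acquisition z-plane, not perpendicular to the
local axon axis. This is deliberate: it is how 2D EM morphometry is done,
and the chosen statistics are the ones that are robust to it.

* **Cross-sectional area** — voxel count × pixel area. Area is *not*
  obliquity-robust: a cylinder of radius r tilted by α meets the plane in
  an ellipse of area πr²/cos α. The tests assert this inflation rather
  than hide it.
* **Minimum axon diameter** — the minimum caliper (Feret) width of the
  axon mask: the smallest width over all orientations, computed by rotating
  calipers on the convex hull of the voxel *corner* points (a single voxel
  therefore reports `min(dx, dy)`). The minimum caliper width of an
  ellipse is its minor axis, so an obliquely sectioned cylinder still
  reports its true diameter — the testable content of the
  minimum-diameter convention.
* **Minimum myelin thickness** — 360 rays are cast from the axon centroid;
  each ray's thickness is the length of its intersection with myelin
  (compact ∪ decompacted), sampled at quarter-voxel steps; the reported
  value is the minimum over rays that meet myelin. If fewer than half the
  rays meet myelin the slice is classified as myelin-free (a nodal slice)
  and thickness is 0 — the 50%-ray rule separates nodes from segmentation
  dropouts.
* **Fiber diameter** — minimum caliper width of axon ∪ myelin; it equals
  the axon diameter exactly where myelin is absent. (An additive variant,
  axon diameter + 2 × thickness, is available via
  `fiber_diameter(additive = TRUE)` for comparison with studies that
  define it that way.)
* **G-ratio** — axon diameter / fiber diameter, in (0, 1].
* **Percent decompaction** — among rays that meet myelin, the percentage
  whose intersection contains at least one decompacted voxel. Scoring over
  the myelin-bearing rays (rather than all 360°) means a partial wrap next
  to a node is scored over its actual circumference, where "fraction of the
  total circumference" would be ill-defined.

## Tracing and longitudinal profiles

`trace_axon()` follows an axon id from its first section until it leaves
the stack, linking per-slice components by largest voxel overlap and
tolerating up to `max_gap = 2` consecutive slices without an overlapping
component before terminating with a warning. The centerline is the area
centroid per slice; arc length accumulates 3D centroid-to-centroid
distances, plus one dz for the two terminal half-slices, so a straight tube
spanning n slices measures exactly n · dz. "Length along the axon" means
this arc length, not the raw z-extent — for tilted axons the two differ by
1/cos α — and the sampling positions of `sample_positions()` (default
every 5 µm, the field's convention) are defined on it. Centroids are not
smoothed: smoothing changes phantom arc lengths by under 1% and would add a
tunable to the measurement chain.

Profile statistics follow directly: per-metric range (max − min over the
sampled slices), per-axon mean, and the **decompaction score** — one point
per sampled slice whose decompaction percentage *strictly* exceeds 40%,
divided by the measured length (points/µm; the strict inequality means a
slice at exactly 40.0% never scores). Axons shorter than two sampling
intervals are excluded from range statistics, since a range needs at least
two samples. Single-section comparators (`single_section_sample()`,
`random_axon_section_sample()`) measure isolated planes for the 3D-vs-2D
contrasts.

## Nodes of Ranvier and mitochondria

`detect_nodes()` applies the myelin-presence rule to *every* traced slice
(nodes rarely fall on the 5 µm grid). For speed the rule is evaluated in
its binned form — the fraction of 1° angular bins about the centroid that
contain myelin voxel centres — which for annular myelin is equivalent to
the ray form at the 1° scale but costs O(n voxels) per slice. A maximal
run of ≥ 3 consecutive myelin-free slices is one node (`min_run` suppresses
single-slice dropouts); the paranodal gap is the arc distance between the
flanking myelinated slices, i.e. between the two internode termini, and
runs touching the trace ends are discarded because their gaps cannot be
measured. Where the gap starts relative to the paranodal loops is not
resolvable at this feature scale; terminus-to-terminus is the recorded
assumption.

Mitochondrion length is the pure z-span, (last − first + 1) · dz, from the
slice where the organelle first appears to where it disappears — matching
how such lengths are measured in practice — rather than a 3D skeleton
length. Each mitochondrion projects its mid-span onto its axon's
centerline and is assigned to at most one node: the nearest node of the
same axon, and only within a 10 µm window.

## The statistical layer

`fit_diameter_thickness()` is ordinary least squares of thickness on
diameter with R² = 1 − SSres/SStot. Group comparisons use the classic
Levene test (one-way ANOVA on absolute deviations from group means —
the mean-centred original, not the Brown–Forsythe median variant) as a
gate at α = 0.05 between Student's and Welch's t-test; the output table
reports both the Levene F and the t statistic, since published tables often
print the two side by side. 3D-vs-2D comparisons use a one-way
repeated-measures ANOVA (subject-blocked two-way decomposition via `aov`)
with Tukey HSD on the error mean square. Degenerate inputs are defined,
not crashed: identical samples give t = 0, p = 1; identical conditions
give F = 0, p = 1. A Dunnett post-hoc is deliberately out of scope.

## The phantom generator

Because no machine-readable reference dataset exists for this kind of
study, the package ships a first-class generator whose defaults *are* the
study conditions, so every stage is testable against known truth.

Each synthetic axon is a true 3D tube: a centerline that wanders about a
home position (two sinusoids per axis with seeded phases, optionally plus a
constant tilt), a radius varying sinusoidally (±15% by default), and a
myelin annulus following the thickness rule **t = 0.20 · d + 0.13 µm**
with smooth seeded noise. Voxels are labelled by their distance to the
centerline *curve*, so a tilted tube has an elliptical in-plane footprint
(semi-minor r, semi-major r/cos α): area inflates with obliquity while the
minimum caliper stays 2r, which is exactly what the measurement conventions
are designed to survive. Decompaction patches replace the compact annulus
over an angular sector, widened radially ×1.5; nodes remove myelin over a
gap; mitochondria are intra-axonal ellipsoids with their own labels.
Axon overlap is an error, never silently clipped. Identical
(config, seed) pairs produce identical volumes.

The test-scale geometry is 20 × 20 × 100 nm voxels — preserving the 1:5
anisotropy of the acquisition — over 512 × 512 × 400 voxels
(10.24 × 10.24 × 40 µm) for cohort volumes, with 10 axons per volume
standing in for one animal's field of view. Problem sizes throughout
(single-axon 160² × 150 recovery phantoms, 3 animals × 10 axons per group,
2000 null replicates for calibration) were chosen once as desk-scale
renditions of the study design.

Preset contrasts (normal → injured): decompaction coverage 2% → 25% of
z-length at angular fractions drawn around 0.2 → 0.6; paranodal gap
1.5 ± 0.2 → 3.0 ± 0.3 µm; nodal mitochondrion length 1.4 ± 0.2 →
0.8 ± 0.15 µm; thickness-noise sd 0.025 → 0.039 µm. The noise sds were
derived analytically from the preset diameter distribution via
R² = Var(0.2 d) / (Var(0.2 d) + σ²) to put the *truth-table* R² near 0.45
(normal) and 0.25 (injured); the R² measured through the full chain comes
out somewhat lower than the truth value because voxel quantization adds
measurement noise to both variables — an attenuation the package reports
rather than corrects. Nodes occur on ~60% of axons (not every 40 µm
segment contains one), and mitochondria counts per node are Poisson(1.5),
so some nodes have none and others several.

## What passing tests do and do not show

The phantoms validate the *measurement chain*: geometry recovery (radius
RMSE within one voxel, gaps within 2 dz, mitochondrion lengths within dz,
decompaction within 2 percentage points), obliquity behaviour, determinism
and the direction pattern of the injury contrast. They do not emulate
segmentation error beyond slice dropouts, astrocytes or other glia, axon
branching, grayscale appearance, or the biological correlation structure of
real cohorts — so green tests certify the software on idealized tubes, not
the biology of any particular dataset.

## Numerical choices worth knowing

* Caliper widths are computed on voxel corners, which overestimates a
  continuous shape's width by up to ~1 voxel; diameters therefore carry a
  ±1-voxel convention, and sub-voxel agreement claims are never made.
* Ray marching uses quarter-voxel steps with nearest-voxel lookup; ray
  thickness resolution is ~1 voxel.
* Component fragments in a slice are resolved toward the traced centroid,
  others ignored with a message.
* The brute-force caliper oracle in the test suite sweeps a 0.5° angle grid
  and then refines by golden-section search on the projection width — a
  bare grid stops ~10⁻³ µm short of the minimum at flush-edge angles, so
  grid-only comparison at 10⁻⁶ µm would be meaningless.
* 16-bit TIFF pages round-trip labels exactly (all labels < 65536);
  measurement tables round-trip through RFC-4180 CSV with deterministic row
  order.

## A worked example

```{r example, eval = FALSE}
cfg <- phantom_preset("normal", seed = 1, n_axons = 10)
ph  <- generate_phantom(cfg)
res <- measure_volume(ph$volume, interval_um = 5, group = "normal", animal = 1)
head(res$summaries)
res$nodes          # paranodal gaps, um
res$mitos          # mitochondrion z-spans and nodal assignment
fit_diameter_thickness(res$points$axon_diameter_um,
                       res$points$myelin_thickness_um)
```

Cohort-level comparisons mirror the study design:

```{r cohort, eval = FALSE}
normal  <- simulate_cohort("normal",  seed = 1)
injured <- simulate_cohort("injured", seed = 2)
cohort_comparison(normal, injured)$stats
```

## Known limitations

* Fragmented or touching instance labels beyond simple dropouts are the
  segmenter's problem; the tracer follows overlap, it does not re-segment.
* Decompaction is a provided label class; detecting it from grayscale
  texture is out of scope.
* Mitochondrion length underestimates the true 3D length of strongly
  tilted organelles (z-span convention).
* Per-animal nesting is not modelled; axons are pooled within groups, as
  in the study design the package mirrors.
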