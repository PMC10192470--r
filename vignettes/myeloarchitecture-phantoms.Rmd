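---
title: "Surface-based myeloarchitecture mapping on synthetic cortical phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based myeloarchitecture mapping on synthetic cortical phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myeloparc)
```

## The measurement model

The package quantifies cortical myeloarchitecture from three ingredients:
a white surface, a pial surface with 1:1 vertex correspondence, and
T1w/T2w MR volumes. The per-vertex myelin value is the T1w/T2w intensity
ratio — higher where intracortical myelin is denser — sampled along each
white→pial segment with Gaussian weights centred at the mid-thickness
(the vertexwise average of white and pial), so that values near the
middle of the cortical ribbon dominate and partial-volume contamination
at the surfaces is down-weighted. The kernel is parameterized by its full
width at half maximum; the default 1.8 mm is the value tuned to the night
monkey's median cortical thickness, and `sampling_kernel()` exposes both
the FWHM and the (odd, ≥ 3) number of samples per segment, default 7.

Raw ratio maps carry a multiplicative, spatially smooth bias (dominated by
the B1 transmit field): if the true map is $m$ and the bias is $B$, the
measured ratio is $m\,B^2$. The correction subtracts the spatially
low-frequency difference between the individual map and a symmetrized
group template:

$$\mathrm{corrected} = \mathrm{ind} - G_\sigma(\mathrm{ind} - \mathrm{template}),\qquad \sigma = 5\ \mathrm{mm},$$

where $G_\sigma$ is on-surface Gaussian smoothing. The correction is
linear, removes constants exactly, and passes sharp areal transitions
through almost unchanged; the price is that it also flattens any genuine
individual deviation smoother than ~3σ, which is the accepted trade-off
of template-referenced correction.

Areal borders are delineated from the gradient of the corrected map (and
of thickness, for parcels like V1 whose lateral border follows a thickness
transition): per vertex, the 1-ring neighbours are projected into the
tangent plane (normal = area-weighted face normals) and a linear field is
least-squares fitted; the slope magnitude is the gradient. With 0.5 mm
pre-smoothing, ridge vertices above a threshold form the candidate
boundary network, and each parcel grows by flood fill from a seed vertex
until it hits ridge vertices. Per-parcel measurements are then taken in
each subject's native space: surface area as the sum of vertex-wise areas
on the mid-thickness surface (each triangle contributing one third to each
corner — exactly conservative), thickness as the unweighted vertex mean
(an area-weighted variant is available via a flag), and volume as the sum
of vertex-wise wedge volumes between the white and pial triangles.
Relative area and relative volume (parcel / whole-hemisphere total) are
the cross-species comparable quantities; interspecies effects are tested
with a two-way ANOVA (species × parcel) and Bonferroni-corrected post hoc
Welch t tests.

## The phantom generator and what it emulates

`species_spec()` + `make_hemisphere()` build closed hemisphere phantoms:
an icosphere (default 4 subdivisions in the desk profile, 2562 vertices;
5 gives 10242) radially perturbed by three low-order sinusoidal "sulcal"
indentations, with white and pial surfaces offset half a thickness inward
and outward along the radial direction. Parcels are geodesic patches grown
vertex-by-vertex (always the frontier vertex nearest the patch centre, so
the patch stays edge-connected) until the accumulated vertex area matches
the target fraction of total surface area; the realized fraction is exact
to half a vertex area, and the generator refuses targets finer than the
mesh can honour. The ground-truth myelin field is a background level
(default 1.4 ratio units) plus per-parcel contrasts (+0.60 MT+-like,
+0.45 auditory-like, −0.25 BA7-like, +0.55 V1-like), smoothed over roughly
one edge length so transitions span no more than about two edges. The
V1-like parcel is also thinner (factor 0.78), giving the thickness
gradient its role in delineation.

`rasterize_volumes()` inverts the contrast mechanism: within the ribbon,
$T1w = B\sqrt{m}$ and $T2w = B^{-1}/\sqrt{m}$, so the noiseless ratio at a
ribbon voxel equals the local field value exactly and the bias enters as
$B^2$. The bias is a sum of three random harmonic components whose spatial
scale (wavelength / 2π) is floored at 15 mm — comfortably smoother than
areal transitions, so the 5 mm correction can separate them. Noise is
independent additive Gaussian per voxel on T1w and T2w before the ratio
(a simplification of Rician noise; the low-SNR regime is out of scope).
Voxels are classified by dense splatting of the white/pial prisms at
sub-half-voxel spacing, which assumes the phantom's star-shaped geometry;
a guard band of about one voxel of cortex-valued samples beyond each
surface limits partial-volume contamination of trilinear samples taken at
segment endpoints, standing in for the ribbon-constrained partial-volume
handling that full pipelines apply to real data.

The default study conditions mirror the real comparison: hemisphere total
areas 2030 / 9894 / 1053 mm² (night / macaque / marmoset), thicknesses
1.91 / 2.1 / 1.7 mm, 9 / 32 / 20 subjects × 2 hemispheres, and parcel
fractions MT+ 2.4 / 0.9 / 1.2%, auditory 2.5 / 0.6 / 1.5%, BA7
2.3 / 3.2 / 2.0%, V1 18.8 / 11.7 / 20.4%. Between-subject variability —
not stated for the source populations beyond group standard deviations —
is set to the observed relative spreads: 3% linear scale jitter (~6% area),
3% parcel-fraction jitter, 2% thickness jitter. Right hemispheres are
exact mirror images of left ones, which supplies both the symmetry tests
and an identity left/right correspondence for template symmetrization.

What the phantoms do **not** emulate: realistic gyrification (folds are
gentle sinusoids, so curvature is exercised but not sulcal burying),
surface reconstruction error (white/pial correspondence is exactly radial,
so correspondence thickness equals true thickness), registration error
across subjects (all subjects of a species share mesh topology, standing
in for folding-based registration), dura/vessel artefacts, and Rician
noise statistics. Passing tests therefore demonstrate the correctness of
the measurement chain, not robustness to reconstruction or registration
failure on real data.

## Numerical choices

- **Smoothing.** Geodesic Gaussian smoothing is approximated by iterated
  1-ring averaging with Gaussian edge weights; the per-step kernel
  bandwidth is solved (per mesh and sigma) so the accumulated per-axis
  variance equals σ² exactly, and the iterate count follows. The kernel is
  row-normalized, so constants are preserved exactly, at the cost of exact
  mass preservation on non-uniform meshes. A delta on a flat grid matches
  the analytic planar Gaussian within ~1% RMS at σ = 2 edge lengths.
- **Wedge split.** Each white/pial prism is split into three tetrahedra by
  the staircase rule keyed to sorted global vertex indices, making shared
  quad-face diagonals agree between neighbouring prisms; interior faces
  then cancel and the wedge total telescopes to the divergence-theorem
  volume difference (machine-precision agreement in tests). Inverted
  wedges are accumulated signed and counted.
- **Gradient.** Tangent-plane least squares over the 1-ring, solved in an
  explicit 2-D tangent basis (exact for planar linear fields; ~1% accurate
  for smooth fields on icospheres at the default resolutions). Vertices
  with fewer than three neighbours, or any masked neighbour, are masked.
- **Ridge threshold.** `boundary_criteria()` defaults to 0.5 × the 98th
  percentile of the gradient, the single-ridge convention.
  `delineate_standard_parcels()` lowers its default to 0.25: it must trap
  the weakest areal border (the low-contrast BA7-like transition produces
  a ridge roughly half as strong as the MT+-like one) while staying above
  the gradient noise floor, and the 98th percentile is dominated by the
  strongest borders. Both are explicit knobs, not inferences about how
  borders "should" be drawn.
- **Ridge-band assignment.** Flood fill alone leaves the whole ridge band
  unlabelled, which biases every parcel small — ruinously so for
  sub-percent parcels at desk resolutions (for a 0.9%-of-cortex parcel at
  2562 vertices the band is nearly half the parcel). After growth, band
  vertices adjacent to exactly one parcel are therefore assigned to it
  when their myelin value is closer to the parcel's interior median than
  to the background median — the operational form of placing borders "by
  intensity and gradient" together. This brings area recovery to within
  ~0.1 percentage points and Dice to ~0.98 on phantoms.
- **Degenerate inputs.** Zero-sigma smoothing is the bitwise identity;
  empty ridge sets are legal (a fill then covers the mesh with a "leaky
  boundary" warning); empty parcels yield zero rows with a warning; a
  constant ANOVA response has zero residual variance and is flagged with
  NA F statistics rather than fabricated ones; ties in nearest-vertex
  resampling break to the lowest source index, and all component and
  label orderings are deterministic by vertex index.
- **Rounding.** Printed relative areas use round-half-up at one decimal
  (`relative_fraction()`), matching printed-arithmetic conventions rather
  than banker's rounding.

## Statistical design choices

Hemispheres enter the ANOVA as independent observations — this matches the
N accounting of the comparison being reproduced (64/18/40 hemispheres,
interaction df (6, 476)) but ignores within-subject correlation; a
mixed-effects treatment is deliberately out of scope. The design is
unbalanced across species, so Type III sums of squares with sum-to-zero
contrasts are the default (`ss = "II"` is available). Post hoc tests are
Welch (unequal-variance) t tests with a joint Bonferroni factor m =
(species pairs) × (parcels); with 3 species and 4 parcels, m = 12. The
interaction F test is calibrated: over 10,000 null simulations of a small
balanced design the empirical type-I rate at α = 0.05 falls in [0.04,
0.06] (this is asserted in the acceptance suite).

## Problem sizes

The test and acceptance runs use desk-scale instantiations chosen to keep
the full suite in the minutes range while preserving the quantities under
test: 2562-vertex hemispheres and 2 subjects per species for the 20
replicate end-to-end runs (group-mean recovery is bias-limited, not
n-limited, and the interaction effect sizes are enormous relative to the
phantom's residual variance); 10,242–40,962-vertex meshes where geometric
fidelity matters (cap areas, bias-vs-step separation — the latter on a
macaque-scale hemisphere, where a ≥ 15 mm bias is genuinely low-frequency
relative to the 5 mm kernel while the mesh stays fine enough for a sharp
step). The ANOVA design checks use the full 488-observation design, which
is cheap.

## Known limitations

- The rasterizer is specific to star-shaped phantom geometry and is not a
  general MRI simulator; there is no B0/distortion, dura, or Rician model.
- Thickness is correspondence distance, which coincides with the usual
  surface-based definitions only because the phantoms are built with
  near-normal correspondence.
- The low-frequency correction attenuates any real inter-individual myelin
  difference smoother than ~15 mm; on small hemispheres (night-monkey
  scale, radius ~13 mm) even the smoothest possible bias retains ~10–15%
  after a 5 mm correction, a geometric fact worth keeping in mind when
  interpreting corrected maps of small brains.
- Group-level delineation projected through shared topology stands in for
  cross-subject surface registration; per-subject delineation variability
  on real data is larger.
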