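# myeloparc

Surface-based T1w/T2w myeloarchitecture quantification for comparative
primate neuroanatomy, with a fully synthetic cortical phantom generator so
every stage is testable against known ground truth.

## The scientific problem

Cortical areas differ in intracortical myelin density, and the ratio of
T1-weighted to T2-weighted MR intensity (`T1w/T2w`) is a non-invasive proxy
for it: heavily myelinated areas such as the MT+ motion complex, auditory
cortex, and V1 stand out as high-ratio islands, and lightly myelinated
association cortex (e.g. a BA7-like parietal region) as low-ratio islands.
Because areal borders coincide with sharp myelin transitions, the magnitude
of the surface gradient of the myelin map marks candidate boundaries, and
parcels can be delineated by growing regions from seeds inside closed
gradient ridges. Measuring each parcel's surface area **relative to total
cortical area** makes the measurements comparable across species with very
different brain sizes — the kind of comparison used to ask whether a
nocturnal primate's MT+ complex and auditory cortex are disproportionately
large relative to diurnal monkeys.

The package implements that chain end to end:

1. **Surface geometry** — mid-thickness surface (vertexwise mean of white
   and pial), vertex-wise areas (one third of each incident triangle),
   vertex-wise wedge volumes (each white/pial prism split into three
   tetrahedra with a globally consistent diagonal rule, so the total equals
   the exact enclosed-volume difference), correspondence thickness, and
   iterative geodesic Gaussian smoothing.
2. **Myelin mapping** — voxelwise `T1w / max(T2w, eps)` ratio, sampled onto
   the surface at points along each white→pial segment with Gaussian
   weights centred at the mid-thickness (FWHM 1.8 mm by default;
   `sigma = FWHM / (2 sqrt(2 ln 2))`), then corrected by subtracting the
   spatially low-frequency (sigma = 5 mm) difference to a symmetrized
   group-average template.
3. **Gradient parcellation** — tangent-plane least-squares gradient
   magnitude with 0.5 mm pre-smoothing, ridge extraction at a fraction of
   the robust (98th-percentile) gradient maximum, seeded flood-fill growth
   bounded by ridges, intensity-guided assignment of the ridge band, and
   nearest-vertex label resampling across meshes.
4. **Areal statistics** — per-parcel area / mean thickness / wedge volume in
   native space, relative fractions, two-way ANOVA (species × parcel, Type
   III sums of squares with sum-to-zero contrasts, hemispheres as
   independent observations) and Bonferroni-corrected post hoc Welch t
   tests (m = species pairs × parcels = 12 for 3 species and 4 parcels).
5. **Synthetic phantoms** — folded white/pial icosphere pairs with myelin
   islands of configurable area fraction and contrast, rasterized into
   T1w/T2w volumes with multiplicative low-frequency bias and additive
   noise, for populations of subjects × 2 mirror-symmetric hemispheres per
   species.

## Worked example

The numbered drivers under `analysis/` run a desk-scale study (three
species × 3 subjects × 2 hemispheres, ~2.5k-vertex meshes) in a few
minutes:

```sh
Rscript analysis/01_simulate.R     # phantom population + ground truth
Rscript analysis/02_map_myelin.R   # volumes -> surface myelin maps
Rscript analysis/03_parcellate.R   # gradient-ridge parcellation vs truth
Rscript analysis/04_metrics.R      # native-space areal metrics
Rscript analysis/05_stats.R        # interspecies ANOVA + post hoc
```

Stage 4 prints the headline recovery (night-, macaque-, and marmoset-like
species with true MT+ fractions 2.4, 0.9, 1.2% of total cortical area):

```
recovered vs target MT+ relative areas (percent):
  macaque   recovered 0.86  target 0.90  (group Dice 0.979)
  marmoset  recovered 1.22  target 1.20  (group Dice 0.970)
  night     recovered 2.49  target 2.40  (group Dice 0.984)
```

i.e. the full simulate → rasterize → sample → bias-correct → parcellate →
measure chain recovers each species' group-mean relative MT+ area to within
a tenth of a percentage point, with per-parcel Dice overlap ≈ 0.98 against
the generator's ground-truth labels. Stage 5 then reports, per response,
the species × parcel ANOVA (for the full 64/18/40-hemisphere, 4-parcel
design the interaction degrees of freedom are (6, 476)) and the corrected
post hoc contrasts; with the phantom effect sizes every MT+ species pair is
significant at corrected p < 1e-9.

In code, the same one-liner convention used for printed relative areas:

```r
library(myeloparc)
relative_fraction(47.9, 2030)   # 2.4  (% of total cortical area)
relative_fraction(89.8, 9894)   # 0.9
relative_fraction(12.5, 1053)   # 1.2
```

## Notes

- Two published area figures conflict between the running text and the
  species table they summarize (marmoset MT+ 12.5 vs 16.1 mm²; auditory
  16.1 vs 12.2 mm²). The printed-arithmetic checks follow the running
  text's worked divisions; both values appear in the test fixtures only
  through those divisions.
- The phantom's rasterizer assumes star-shaped (centroid-visible)
  hemisphere geometry; it is phantom plumbing, not a general-purpose MRI
  simulator.
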