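---
title: "zonemig: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zonemig: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
assay being modeled, the statistic, the simulator and renderer, the
quantification pipeline, the parameter choices, and the limits of what the
synthetic data can demonstrate.

## The assay and its readout

In an exclusion-zone (barrier) migration assay, cells are seeded around a
silicon stopper that keeps a circular central region cell-free during
attachment. After stopper removal the population is labeled with a vital
lineage-tracing dye, imaged (t₀), allowed to migrate for 12–24 h, and
imaged again (t_f). Two circular ROIs are derived from the t₀ image: ROI-1
circumscribing the entire labeled field (which coincides with the inner
well wall) and ROI-2 delineating the cell-free zone. The pair is pasted
rigidly onto t_f, centered on the well, and the readout is

relative migration (%) = 100 · I(ROI-2) / I(ROI-1),

with I the summed pixel intensity in an ROI. The lineage dye partitions
essentially evenly between daughter cells, so each division halves per-cell
intensity while the *summed* intensity of a clone is unchanged. The ratio
therefore measures how much of the parental fluorescence mass moved into
the zone, whatever the division history — this is the proliferation
insensitivity the package exists to demonstrate. The conventional readout
(nuclear-stain signal or nucleus counts in the zone) lacks this property.

## The agent-based simulator (`run_assay()`)

Cells are points in a circular well of radius 3200 µm with a concentric
(optionally offset) exclusion zone of radius 1000 µm — the proportions of a
96-well barrier insert. Seeding is uniform over the annulus outside the
zone (uniform over the whole disk for plain cultures, `seed_exclusion =
FALSE`).

**Motility** is a persistent random walk: each step of `dt` hours perturbs
the heading by a Gaussian increment of variance `2·dt/P` and advances the
position by `speed·dt`. With this scaling the velocity autocorrelation
decays as `exp(-t/P)`, so `persistence_time` P is the velocity correlation
time and the mean squared displacement follows the Fürth form
`2·v²·P·(t − P·(1 − e^(−t/P)))`, which the test suite checks against a
free-space simulation. Cells meeting the well wall are reflected
specularly (heading mirrored about the tangent, radial overshoot folded
back).

**Division** is sampled per cell per step with probability
`division_rate·dt` (at most one division per cell per step; the default
`dt = 0.1` h keeps `division_rate·dt ≪ 1`, so the discretization error of
this Bernoulli scheme is negligible). A division replaces the parent by two
daughters carrying `dye·split` and `dye − dye·split` — the second daughter
takes the floating-point remainder, so the sum is *exactly* the parental
content and, at the symmetric default `split = 0.5`, per-cell dye is
exactly `2^-generation` (halving by 0.5 is exact in binary floating point).
Daughters sit ±5 µm from the parent along a random axis (≈ one cell
radius, preventing exact overlap) and inherit the parent's heading:
division does not reorient motion, which keeps the spatial law of a
lineage's descendants identical to that of an undivided walker — the
property that makes paired division-on/off comparisons clean.

**Dye kinetics**: per channel, first-order decay `exp(-decay_rate·dt)`;
then, for every pair of cells closer than `transfer_radius`, a symmetric
exchange of a fraction `transfer_rate·dt` of each cell's dye (an error is
raised if that fraction reaches 1). The exchange conserves total dye
exactly; with zero decay the simulator asserts total dye constant to
machine precision through any run — the mass-conservation backbone of the
dye statistic.

**Treatments** are pure multipliers on speed and division rate, applied
before the run: an actin depolymerizer as `speed × 0.1`, a cell-cycle
antagonist as `division × 0`, serum/ECM stimulation as `speed × 1.5`. No
dose–response modeling is attempted; the presets only need the qualitative
directions of the corresponding wet-lab treatments.

**Paired randomness.** `run_assay()` maintains two RNG streams (saved and
restored `.Random.seed` states). Stream A, seeded from `rng_seed`, drives
seeding and the motility increments of the initial cohort; stream B,
derived from `rng_seed`, drives division timing, daughter placement and
the motility of cells born during the run. Two runs with the same seed
that differ only in `division_rate` therefore share the exact trajectories
of their initial cells, which removes most between-arm variance from
paired comparisons. Identical seed and configuration give bitwise-identical
results.

## Default study conditions

- `n_cells = 30000`: within the 3–6 × 10⁴ cells/well seeding range of the
  assay; also the density at which the labeled field renders as a
  contiguous annulus, which the ROI detector (like the real analyst)
  requires.
- `speed = 120` µm/h, `persistence_time = 2` h, `duration = 24` h. These
  are *effective* dispersal parameters, deliberately faster than typical
  single-cell speeds: a dilute point-cell model has no pushing,
  proliferation-driven fronts or contact-mediated sheet invasion, so the
  agent speed is set such that zone occupancy at t_f lands near 6.5% of the
  total signal — well above the t₀ background, far from complete fill.
  This mirrors how migration windows are tuned per cell type in practice
  (fastest cells must not fill the zone; slowest must be detectable above
  background) and was fixed from a diffusive-influx estimate at design
  time. At these conditions the fully mixed (infinite-time) ceiling is the
  zone/well area ratio, ≈ 9.8%.
- Dye units are arbitrary with initial content 1.0 per cell: every
  statistic the package computes is a ratio.
- `division_rate` defaults to 0; the division arm of the insensitivity
  scenario uses `log(2)/24` h⁻¹ — one population doubling over the assay.

## Rendering (`render()`)

Each cell contributes an isotropic Gaussian spot of σ = 15 µm (cell-scale
optics of a 4×/0.13 NA lens; sub-cellular structure is not resolvable and
not modeled) whose integral is `gain · dye` (`gain · 1` per cell on the
nuclear channel, making it the counting channel). Spots are splatted with
bilinear sub-pixel weights and convolved with the point-spread kernel by
FFT on a padded grid: rendering is exactly linear in dye content and
conserves total flux up to field-of-view truncation, properties the
statistic inherits. The default gain puts a generation-0 peak near 20% of
the 16-bit range, leaving five dye halvings above the noise floor
(background 100 counts, Poisson shot noise, 5-count read noise). Pixels
outside the well circle are zeroed. Spectral bleed-through, vignetting,
stitching and focus artifacts are not modeled.

## Quantification (`detect_roi_pair()`, `relative_migration()`)

Detection operates on a lightly smoothed image (σ = 1 px Gaussian; a 3×3
median filter gives indistinguishable results on these fields at ~30× the
cost). ROI-1: Otsu threshold, largest connected foreground component,
circle fit to its outermost per-angle pixels (Kåsa algebraic fit refined by
Gauss–Newton), then sub-pixel refinement: the image is resampled on polar
sectors about the current center, profiles are averaged within each sector
to suppress the granularity of the discrete cell field, and each sector
contributes the radius where its profile crosses the midpoint between the
global inside and outside levels; the circle is re-fit to these crossings
over two passes. ROI-2: the same machinery on the inverted threshold
inside ROI-1 (Otsu computed on the square inscribed in ROI-1, so
outside-well zeros cannot skew it), with a heavier σ = 5 px blur plus
morphological opening for the component step only — inter-cell gaps must
not connect the zone to chance voids in the field. A confluent well (no
central cell-free component) is a detection error, flagged as "migration
complete or t0/tf swapped". On rendered fixtures the well circle is
recovered to ≲1 px / 1% and the zone circle to ≲0.5 px at full scale.

Alignment is translation-only: the well circle is re-detected on t_f and
the pair is moved rigidly (a circular well offers no rotation cue; radii
and the ROI-1→ROI-2 offset are preserved exactly).

A pixel belongs to an ROI when its center lies at distance ≤ radius
(boundary ties count as inside) — a deterministic, documented tie-break.
By default each pixel is background-corrected by the median intensity
outside ROI-1, clipped at zero, before summation; `background = "none"`
reproduces the bare ratio formula. Whether the original analysis
background-corrected its sums is not documented, so both paths exist; on
paired contrasts the choice cancels. The statistic is exactly invariant
under rescaling all intensities.

**Single-image mode** applies one standard ROI pair (from a reference t₀
or from the declared geometry, storable as geometry-relative JSON) to every
t_f image after centering on the detected well. It saves half the imaging
at the cost of ignoring per-well zone placement; on centered synthetic
wells it agrees with dual-image analysis to well under one percentage
point, and a two-way ANOVA across motility arms finds no method effect.
With a deliberately mis-centered zone the two modes diverge — partially
offsetting errors (missed rim signal on one side, captured field signal on
the other) keep the net bias moderate, and the package reports both modes
rather than hiding the difference.

**Count-based mode** is the proliferation-confounded baseline: the same
ratio on the nuclear channel, or nucleus counts within the ROIs. Its
denominator defaults to the t_f image (the literal zone-over-well ratio).
A subtlety the simulator makes explicit: when division is spatially
homogeneous — as in this model, which deliberately omits contact
inhibition and density-dependent growth — the t_f-normalized count ratio
is *also* proliferation-insensitive in expectation, because numerator and
denominator scale together (each descendant's position law equals the
single-walker law). The confound the assay literature describes operates
through absolute zone counts ("colony expansion") and through
density-dependent growth in crowded regions. Demonstrations of
proliferation sensitivity therefore reference the zone signal to the
*parental* population (`t0_nuclear`): that readout doubles under one
doubling of the population, while the dye statistic — whose denominator is
conserved by construction — is unchanged. This is the comparison the
insensitivity scenario and the acceptance checks run.

## Cytometry controls

`segment_cells()`: Otsu threshold (computed inside the well), connected
components, removal of objects below `π·(σ_psf/pixel)²/4` px² (a quarter
of the nominal spot area — noise speckles scale below it, cells above),
then a distance-transform watershed to split touching cells. Two Gaussian
spots become separable at center distances ≳3σ; below that the summed
image is unimodal (an oval level set with no neck), so no segmenter can
split it — counting contracts therefore hold on sparse fields (overlap
probability < 5%), where counts are within 2% of truth and strictly
monotone in the true density. Per-object statistics (centroid, area,
background-corrected mean and integrated intensity per channel) are
recomputable exactly from the label raster.

`dye_retention()`: background-corrected whole-well sums over a timepoint
series, as a percentage of the first timepoint. With zero decay the series
sits at 100% within rendering noise; a decay rate of `ln(100/97)/24` h⁻¹
reads out 97% at 24 h.

`dye_transfer()` reconstructs the mixed-culture transfer measurement: both
populations are segmented on their on-channel image; objects bright in
both channels after per-channel normalization are gated out as unresolved
violet/far-red doublets (genuine transfer never approaches channel
parity); then

percent transfer = 100 · (mean off-channel per-cell intensity in mixed −
same in the single-labeled culture) / (mean on-channel per-cell intensity
of the donor in its single-labeled culture),

with per-cell intensity integrated over the object mask (robust to
segmentation area jitter; capture-fraction biases cancel between numerator
and denominator). The detailed protocol of the original measurement lives
in supplementary material that is not part of the main text, so this
formula is a reconstruction of the two quoted definitions. Against the
simulator's ground-truth ledger (dye mass residing in the other lineage at
t_f) the estimate tracks transfer rates spanning 0–5% within ±1.5 points;
the residual positive offset (~0.5 points) is point-spread spill from
neighboring donors into recipient masks, which the single-culture
reference cannot contain — present in real imaging too. Transfer fixtures
use a 20×-scale field (1100 µm radius, 2 µm/px, 300 cells, σ = 5 µm),
matching the per-cell imaging regime of such measurements.

## Statistics (`compare_groups()`)

Arms are compared by one- or two-way ANOVA (`stats::aov`) with Tukey
all-pairs (`stats::TukeyHSD`) or Dunnett many-to-one (`multcomp::glht`)
adjusted comparisons, significance at α = 0.05 and SEM error bars — the
conventional treatment of multi-arm migration panels. Nothing bespoke is
claimed for this layer.

## Problem sizes and determinism

The test suite runs full-scale wells (512² rasters, 3 × 10⁴ cells) for the
end-to-end properties — 30 paired replicates for the insensitivity
contrast, 4 arms × 6 replicates for the dual-vs-single comparison, 4
arms × 8 for the treatment ordering — and compact wells (256² rasters) for
unit-level fixtures; these sizes give stable statistics while keeping the
whole suite in the ten-minute range on one CPU. All randomness flows from
explicit seeds; scenario tables, CSV reports and simulation results are
reproducible bit for bit given the same seed.

## Known limitations

- Point cells: no volume exclusion, contact inhibition, front-driven sheet
  invasion, chemotaxis or cell–ECM mechanics; treatment arms are parameter
  multipliers, not mechanisms. Absolute migration percentages are
  therefore smaller than wet-lab values (which reach the zone ceiling by
  active front invasion), and effect sizes of real cell lines are out of
  scope.
- Spatially homogeneous division, hence the t₀-referenced count baseline
  discussed above.
- Optics: no bleed-through between the violet and far-red channels, no
  stitching or vignetting; retention wells are rendered at full-well scale
  rather than as stitched 20× tiles.
- Death is representable only as an `alive` flag; no apoptosis model.
- Whether a cell-cycle antagonist also suppresses motility in a given cell
  line (as observed for some lines, not others) is biology the simulator
  does not decide: both knobs are exposed and the preset blocks division
  only.
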