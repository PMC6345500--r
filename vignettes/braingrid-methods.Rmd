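---
title: "The Brain-Grid classification system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Brain-Grid classification system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braingrid)
```

## The model

Standard lobar classification of gliomas ("a left frontal glioma") ignores
both the subcortical extent of the lesion and the white-matter scaffolding
along which these tumors infiltrate. The Brain-Grid replaces the lobar
vocabulary with a fixed partition of the whole brain into 48 comparable
regions ("grid voxels", here *cells*), generated by eight planes through
landmarks that are recognizable on any morphological MRI:

* three sagittal-axis (y) planes — the anterior insular point, the
  posterior insular point, and the junction of the calcarine fissure with
  the parieto-occipital sulcus;
* two axial-axis (z) planes — the cistern between the cingulate gyrus and
  the callosal body, and the inferior insular point at the level of the
  mammillary bodies;
* three lateral (x) planes — the right and left middle frontal sulcus and
  the interhemispheric midline.

In MNI space the default plane coordinates are x = (33, 0, −33),
y = (28, −23, −68), z = (33, −13) mm; the Talairach constants
x = (32, 0, −32), y = (25, −24, −66), z = (31, −7) are shipped alongside
(both sets are data; no conversion between the spaces is computed). Cells
are coded A1–A4 right→left (radiological convention: A1 is the patient's
right, the largest x), C1–C3 cranio-caudal and S1–S4 anterior–posterior, so
`A3C2S2` is the left sub-insular/basal-ganglia region. The partition is a
pure function of the world coordinate: a tumor mask is classified by
assigning each foreground voxel center to a cell and accumulating volumes.

```{r grid}
g <- brain_grid("MNI")
g
label_point(c(-10, 0, 0), g)
```

## Conventions and tie-breaks

* **World space is RAS+** (right = +x, anterior = +y, superior = +z).
  Files in other orientations are reoriented to canonical RAS on load;
  reorientation permutes/flips the array only, never the world coordinates
  of voxel centers.
* **Points exactly on a plane** belong to the lower-index
  (right/cranial/anterior) slab. This makes the partition exhaustive and
  deterministic; boundary voxels are not discussed in radiological practice
  and any fixed rule is equally defensible. A consequence worth knowing:
  mirror equivariance (`label(mirror(p)) == mirror(label(p))`) holds
  everywhere except for points lying exactly *on* a lateral or midline
  plane, where the lower-index rule picks the medial slab on one side and
  the lateral slab on the other. Voxel-center grids in practice never place
  centers exactly on a plane unless the spacing divides the plane
  coordinate.
* **Cell IDs** follow the fixed bijection `id = (a−1)·12 + (c−1)·4 + s`,
  so exported labelmaps are bit-stable across runs and versions.
* **Subject-specific grids**: the landmark planes are drawn on each
  patient's own anatomy in routine use; `grid_planes()` (or a JSON override
  via `read_planes_json()`) builds the same machinery over any strictly
  decreasing plane triples. When a tumor infiltrates or dislocates a
  landmark, the contralateral landmark is used; `mirror_label()` encodes
  the corresponding A1↔A4 / A2↔A3 mapping.

## Classification parameters

`classify_mask()` has one tunable, `min_overlap_mm3` (default 0 mm³): a
cell counts as infiltrated when its overlap volume strictly exceeds it. The
default follows visual practice, where any visible hyperintensity in a cell
counts; a positive threshold is available to suppress single-voxel
segmentation noise. Volume bookkeeping is by voxel-center membership —
voxels are not split across cells and masks are never resampled, so the sum
of per-cell volumes equals the total foreground volume (exactly when the
voxel volume is exactly representable, e.g. unit voxels; to within float
summation order otherwise). Plane distances are minima of unsigned
voxel-center distances (0 when the foreground spans a plane); no sub-voxel
surface interpolation is attempted, so distances carry an uncertainty of
about one voxel pitch.

Laterality is derived from the infiltrated cells (A1/A2 right, A3/A4 left,
both sides → bilateral), independently of any radiologist-annotated side
column in cohort files.

## The tract table

The white-matter atlas is summarized per cell as a table: each of 34 major
structures (commissural, projection, associative) carries the set of grid
cells it traverses, so "which structures are at risk" is a set
intersection (`tracts_in_cells()`), ranked by shared-cell count with
alphabetical tie-break. The 34-structure inventory is decomposed as 5
midline entries (genu, body and splenium of the corpus callosum, anterior
commissure, fornix) + 14 bilateral pairs (IC, ExC, CST, OR, ATR, Ci, ILF,
MLF, IFOF, UF, FAT, SLF-h, AF, VOF) + the vertical SLF component counted
once; the published count and enumeration do not uniquely reconcile, and
this decomposition is recorded in the table itself rather than hard-coded.
Entries whose cell sets are directly recoverable from the published text
are tagged `main-text` in the `provenance` column; the remaining entries
carry anatomically inferred cell sets tagged `inferred` and are intended to
be replaced by a transcription of the full published appendix tables when
available. `build_table_from_masks()` rebuilds the table from any set of
per-tract NIfTI masks, so a site can regenerate it from its own atlas.

## Longitudinal comparison

`compare_reports()` reduces two serial studies to gained/lost/stable cell
sets plus volume change. `progression_routes()` then pairs every gained
cell with each face-adjacent baseline cell and lists the structures whose
cell sets contain both — a *proposal* of the white-matter pathway along
which the cell was reached (e.g. a gain of `A3C2S1` from a baseline
`A2C2S1` via the callosal genu). Adjacency is 6-connectivity on the 4×3×4
lattice, including the midline A2↔A3 face; diagonal (26-)connectivity was
rejected because it multiplies spurious routes without a corresponding
anatomical claim. Gained cells with no infiltrated neighbor are flagged as
non-contiguous appearances rather than forced onto a route. Multi-scan
series are handled pairwise; no smoothing across more than two time points
is attempted.

## Cohort analysis

`load_cohort_table()` validates the per-patient schema (histology A/O, WHO
grade 2/3, side R/L/B, margins bulky/diffuse, volume, infiltrated-cell
count 1–48, optional explicit cell sets). The shipped table transcribes the
39-patient WHO grade II–III cohort; where the source text and its table
disagree (they do in several summary statistics — e.g. printed mean cell
count 7.4 vs the column mean 7.33, printed volume range lower bound 5.5 vs
column minimum 5.1), all computation follows the table, and summaries are
reported unrounded with display rounding only in the print method.

`frequency_map()` computes per-cell infiltration frequencies over a stratum
(typically one hemisphere). Display binning uses the published anchors
(0–5% white, ≥50% high-frequency, >80% dark red), completed to the
monotone edges [0,5], (5,25], (25,50), [50,80], (80,100] percent. The
per-patient cell sets behind the published frequency figure are not
available, so frequency-map correctness is established by properties: the
counting identity (sum of frequencies × stratum size = total cell
mentions) and recovery of known generative probabilities on synthetic
cohorts (maximum absolute error < 0.05 at n = 500).

## The synthetic generator

`make_ellipsoid_lesion()` emulates the *bulky* phenotype (well-defined
margins) as a voxelized ellipsoid; `make_diffuse_lesion()` adds
finger-like digitations as capsules (cylinder + hemispherical caps) along
chosen directions, a deliberately simple stand-in for growth along deep
white-matter fibers. Boundary jitter toggles a seeded fraction of surface
voxels off, so identical specs are bit-identical and different seeds differ
only on the surface shell. `make_growth_series()` dilates and translates
the lesion per step and accumulates the union, guaranteeing the nesting a
treatment-naive growth series should show (translation alone would not).
The default test geometry is 2 mm isotropic, 91×109×91, world origin at
the volume center — the common template footprint at a resolution that
keeps rasterization fast.

What the generator does **not** emulate: MRI intensities, edema vs tumor
signal, mass effect and landmark dislocation, reaction–diffusion growth
kinetics, or anatomically realistic digitation paths. Passing tests on
these phantoms therefore validates the *geometry pipeline* (labeling,
counting, distances, deltas), not segmentation or biological fidelity.

## Numerical choices and degenerate inputs

* Masks with non-binary values are thresholded at > 0.5 on load
  (configurable), `NA`s are background.
* Empty masks classify to an empty report (laterality "indeterminate");
  plane distances on an empty mask are an error, since a minimum over an
  empty set is undefined.
* Affines must be invertible; negative-determinant (e.g. LAS) files are
  reoriented on load. Files with neither sform nor qform are taken as
  already RAS.
* Labelmap export writes integer datatypes; exporting twice on the same
  geometry is bit-identical.
* Problem sizes in the test suite: labeling oracle agreement on 10⁴ random
  points, dense-lattice partition checks at 8 mm pitch, whole-head
  rasterizations at 2–4 mm, unit-voxel conservation checks at 1 mm over an
  80×90×80 mm field, and a 500-record synthetic cohort for frequency
  recovery — sizes chosen to exercise every code path while keeping the
  full suite around a minute on a single core.

## Limitations

The grid is only as good as the spatial normalization or landmark placement
feeding it; no landmark detection or registration is performed here. The
shipped tract table's `inferred` entries are editorial placeholders, and
patient-level imaging results from the source cohort (per-patient cell
sets, the left/right split of infiltrated cells) are not publicly
available, so they are not reproduced — cohort-level checks are limited to
the published per-patient table and property-based validation. The system
deliberately carries radiologist judgments (bulky/diffuse margins, lobar
annotation) as input annotations and never computes them.
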