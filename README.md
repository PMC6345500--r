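# braingrid

Brain-Grid radiological classification of cerebral gliomas in R.

Lobar nomenclature ("left frontal glioma") describes neither the true
subcortical extent of a diffuse glioma nor the white-matter architecture
along which it infiltrates. The Brain-Grid addresses both with a fixed
partition of the whole brain into **48 comparable cells**, generated by
eight planes through landmarks visible on any morphological MRI: three
sagittal-axis planes (anterior insular point, posterior insular point,
parieto-occipital sulcus), two axial-axis planes (callosal–cingulate
space, inferior insular point) and three lateral planes (right/left middle
frontal sulcus, midline). In MNI space (RAS+, mm) the default planes are

    x = (33, 0, −33)    y = (28, −23, −68)    z = (33, −13)

with the Talairach constants shipped alongside. Cells are coded
`A{1–4}C{1–3}S{1–4}` — A right→left (A1 = patient's right), C
cranio-caudal, S anterior→posterior — so `A3C2S2` is the left
sub-insular/basal-ganglia region. A point `(x, y, z)` falls in the cell
whose half-open slab intervals contain it (ties to the lower index), and a
tumor segmentation mask is classified by assigning every foreground voxel
center to its cell.

The package provides:

* the grid itself: point→cell labeling, nomenclature parsing, mirroring,
  adjacency, and NIfTI labelmap export aligned to any reference image;
* tumor-mask classification into an infiltration report (cells, per-cell
  volumes, total volume, distances to each grid plane, laterality);
* a 34-structure white-matter tract ↔ cell association table for
  "structures at risk" queries, rebuildable from any set of tract masks;
* longitudinal comparison of serial studies with proposed white-matter
  spread routes for newly infiltrated cells;
* cohort tables, summaries, and per-cell infiltration frequency maps;
* a synthetic lesion generator (bulky/diffuse phenotypes, nested growth
  series) so the whole pipeline is testable without patient data.

## Worked example

A synthetic diffuse left-insular lesion with one anterior digitation,
classified against the MNI grid:

```r
library(braingrid)

g    <- brain_grid("MNI")
geo  <- make_reference_geometry(c(91, 109, 91), 2)   # 2 mm template FOV
sp   <- lesion_spec(c(-32, -2, 2), c(14, 12, 10),
                    digitations = list(digitation(c(0.3, 1, 0), 32, 5)))
mask <- make_diffuse_lesion(sp, geo)

rep <- classify_mask(mask, g, study_id = "pt01-2014")
summary(rep)
#> Brain-Grid infiltration report [pt01-2014] (MNI space)
#>   infiltrated cells: 3 / 48 (A3C2S1, A3C2S2, A4C2S2)
#>   total volume: 8.92 cm^3
#>   laterality: left
#>   per-cell volumes (mm^3):
#>   label id volume_mm3
#>  A3C2S1 29        392
#>  A3C2S2 30       5384
#>  A4C2S2 42       3144
#>   plane distances (mm):
#>              x_right            x_midline               x_left
#>                   51                   18                    0
#>   y_anterior_insular  y_posterior_insular  y_parieto_occipital
#>                    0                    9                   54
#> z_callosal_cingulate   z_inferior_insular
#>                   21                    5
```

The lesion occupies three cells for 8.92 cm³; its digitation has already
crossed the anterior-insular plane (distance 0 to `y_anterior_insular`)
while still 18 mm from the midline. The structures at risk, ranked by the
number of infiltrated cells they traverse:

```r
head(tracts_in_cells(rep$cells$label), 6)
#>   name hemisphere    category n_shared_cells  shared_cells
#> 1  ATR          L  projection              2 A3C2S1;A3C2S2
#> 2   Ci          L associative              2 A3C2S1;A3C2S2
#> 3 IFOF          L associative              2 A3C2S1;A3C2S2
#> 4   UF          L associative              2 A3C2S1;A3C2S2
#> 5   AC    midline commissural              1        A3C2S2
#> 6   AF          L associative              1        A4C2S2
```

i.e. the left anterior thalamic radiation, cingulum, IFOF and uncinate
each traverse two of the infiltrated cells. Serial studies are compared
with `compare_reports()` and `progression_routes()`, which pair each newly
infiltrated cell with adjacent baseline cells through the structures they
share (e.g. a gain of `A3C2S1` from `A2C2S1` via the callosal genu).

A thin command-line front end wrapping these functions is installed at
`system.file("cli", "braingrid", package = "braingrid")`, with subcommands
`grid-export`, `classify`, `tracts`, `compare`, `cohort`, `simulate` and
`build-atlas`.

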