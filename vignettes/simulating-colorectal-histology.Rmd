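---
title: "Simulating colorectal histology with cryptsim: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating colorectal histology with cryptsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cryptsim` generates synthetic haematoxylin-and-eosin (H&E) visual fields of
colonic tissue together with complete sub-cellular ground truth. This
vignette is the package's account of the underlying model: what is simulated,
which parameters matter, where the design was genuinely open and what was
decided, and what the synthetic data can and cannot stand in for.

## The tissue model

Healthy colonic mucosa is organised around crypts: tubular glands whose
cross-sections appear as rings of columnar epithelial cells around a mucin
lumen, with goblet cells forming a honeycomb inside, and stroma (fibroblasts,
lymphocytes) filling the space between glands. Colorectal adenocarcinoma
progressively destroys this architecture; the TNM differentiation grade
`S` (0 healthy, 1 well, 2 moderately, 3 poorly differentiated) is driven by
the fraction of tissue that still forms glands. The simulator takes `S` as
its master knob and derives architecture, cell population and texture from
it.

### Architecture

The number of crypts in an `i_h x i_w` field is
`N_c = round(f_c * floor(i_h / 2 mu_b) * floor(i_w / 2 mu_b))`, where `mu_b`
is the mean crypt semi-minor axis in pixels and `f_c` the glandular coverage
fraction: 1 for grades 0-1, `U(0.5, 0.95)` for grade 2 and `U(0, 0.5)` for
grade 3, mirroring the grading guidelines. Each crypt samples a semi-minor
axis `b ~ Gamma(alpha_b, beta_b)` and an axis ratio
`e = b/a ~ Gamma(alpha_e, beta_e)` (redrawn until `0.2 < e <= 1`), takes a
uniform rotation, and turns the rotated-ellipse polar radius into an outline
by adding per-vertex offsets `u = (S^2 + 1) U(-0.06, 0.1) b` at 72 evenly
spaced angles (5 degree steps), closed by a periodic cubic spline on the
radius. Because the radius is a single-valued function of angle the outline
is star-shaped, hence simple by construction, with no need for
self-intersection repair.

Two deliberately settled ambiguities:

* **Per-vertex deformation, scaled by the crypt size.** A single scalar `u`
  would only re-scale the radius and could not twist the outline, so the
  offset is drawn independently per vertex; scaling by `b` keeps the
  deformation proportionate across crypt sizes (an absolute offset of at
  most 1 is invisible at crypt scale).
* **Counting cells on the nominal gland boundary.** The epithelial cell
  number divides the summed crypt perimeters by an overlap-dependent
  spacing. We evaluate that formula on the ellipse perimeter
  (Ramanujan's approximation), not on the deformed polyline: the
  grade-dependent deformation lengthens the polyline several-fold at grade 3
  and would make the cell count an artefact of boundary roughness, whereas
  the published typical counts are essentially flat across grades.

Crypt centres are drawn from a randomly offset grid with spacing `0.6 b`.
Grades 0-1 admit no outline intersections (an exact geometric predicate:
point-in-polygon plus segment-crossing tests on the dense outlines); at
grades 2-3 a crypt may intersect at most one partner, the pairwise overlap
area is capped at half the smaller crypt, and partners share a `gland_group`
("gland within gland"). A visual field may cut glands at its border, but a
candidate centre is rejected when more than 40% of the outline falls outside
the image, which keeps fields framed on mostly-visible glands. Placement is
sequential with a budget of 400 grid candidates per crypt; a crypt that
cannot be placed is dropped and the shortfall logged.

### Cell population

Cell numbers follow from the placed architecture: stromal cells fill the
area outside the crypts at one cell per
`A = pi ((1.7 - 0.7 L_max) r)^2` pixels, and epithelial cells are strung
along the gland boundaries at spacing `2 (1.25 - L_max) r`, both scaled by
the user cellularities `nu_s`, `nu_e`. `r` is the nominal cell radius
(default 6 um). `L_max` caps the pairwise overlap ratio
`L_ij = |R_i ∩ R_j| / |R_i|` on the configured mask domain (nuclei by
default); placement is by rejection, re-drawing coordinates until the cap
holds in both directions or a 100-attempt budget skips the cell (skips are
logged and reconciled in the ground truth).

Epithelial cells sit on a random outline point, displaced per coordinate by
`r S U(-0.25, 0.08)` — exactly on the boundary when healthy, increasingly
scattered (mostly inward) with grade — and are oriented towards the crypt
centre; below grade 2 their nuclei are displaced outward along the cell
axis by a quarter of the cytoplasm length to mimic basal orientation (the
magnitude is our choice; the literature states the orientation, not a
number). Stromal cells are uniform over the stromal pixels and share a
dominant direction `phi + U(-pi/6, pi/6)`, with `phi` the circular mean of
the crypt rotations. In cancer grades a stromal cell is an infiltrating
tumour cell with probability `min(0.2 S, 1)` (the printed formula is
typographically corrupted; the monotone-increasing reading is implemented
and the slope is configurable); at grade 3 each tumour cell joins a cluster
region — a `10r x 10r` square with local overlap cap `min(2 L_max, 0.8)` —
with probability 0.5. Other stromal cells split 50/50 into fibroblasts and
lymphocytes.

### Cell geometry

Nuclei (and stromal cytoplasm) are randomized decagons: vertices at equal
angles on the unit circle, jittered radially by `U(-alpha, alpha)` per
coordinate and angularly by `U(-beta, beta)`, with `alpha = 0.1 (S + 1)` and
`beta = 0.05`, closed by periodic cubic splines. Irregularity therefore
grows with grade, which the tests verify as a monotone increase in mean
boundary roughness. Nuclear semi-axes are phenotype-specific normals
truncated below at 0.3 of the mean; cytoplasm axes multiply the nuclear axes
by independent `U(1.5, 2.2)` factors (whether the two factors are shared is
unstated in the source; independent draws are implemented and configurable).
Fibroblasts are rescaled to thin nuclei with long thin cytoplasm (nucleus
minor x0.8, cytoplasm major x1.8/minor x0.5) and lymphocytes shrink
uniformly (nucleus x0.8, cytoplasm x0.7). Epithelial cytoplasm starts from a
fixed columnar decagon template with exactly 2:1 extents (the published
template figure has no printed coordinates, so the template is defined in
code). Nucleus masks are clipped to their cytoplasm for epithelial,
lymphocyte and tumour cells, which makes the containment invariant exact.

### Texture, goblet cells and rendering

Chromatin and lumen textures are grown by non-parametric exemplar-based
synthesis (Efros–Leung): each frontier pixel takes the centre value of an
exemplar patch drawn uniformly among all patches whose Gaussian-weighted,
masked SSD is within `(1 + 0.1)` of the best match, window radius 5 — the
method's conventional settings, since the source names none. Output values
are therefore a subset of exemplar values, which the tests assert exactly.
The package ships a synthetic exemplar generator (posterised speckle fields
at class-specific granularity) so the pipeline runs with no downloads; users
can substitute real grayscale exemplars per class. One healthy-lumen class
and seven cancer-lumen classes are synthesized; a healthy run always uses
the healthy class while cancer runs draw a class per crypt. Canvases
(256x256 by default) are built once, cached, and randomly cropped with
replacement; whole-crypt lumen fills may exceed the canvas, in which case
the renderer mirror-tiles the canvas (plain crops larger than the canvas are
an error, as synthesis cost is the pipeline bottleneck). Cytoplasm and
goblet-wall texture use procedural value noise (octaves at persistence 0.5).

Goblet honeycombs appear only in healthy crypts: a ring of
`gamma = round(a/r)` Voronoi seeds one cell radius inside the boundary, plus
`2 kappa (kappa - 1)` seeds (with `kappa = round(1/e)`) in rows one cell
diameter apart along the `2 kappa` angles nearest the major axis — the row
spacing unit is unstated in the source; one cell diameter `2r` per row is
implemented — plus a centre seed, all jittered by `U(-0.2r, 0.2r)`. The
tessellation is computed as an exact nearest-seed labelling on the crypt
pixels; walls are the inter-label boundary pixels, dilated, corner-rounded,
textured and blurred. Goblet chambers are tessellation geometry, not
`CellSpec` cells.

Rendering composes two ideal channels (nuclei = haematoxylin proxy,
cytoplasm/lumen/walls = eosin proxy) with per-pixel maximum blending — the
source does not define a blending rule; maximum keeps channel values in
`[0, 1]` before staining, unlike additive alternatives. Acquisition
degradation is `I * G + N_G`: a unit-sum Gaussian PSF truncated at 4 sigma,
then zero-mean Gaussian noise of variance `sigma_G` (default 0.00025),
clipped to `[0, 1]`. H&E colour is Beer–Lambert:
`RGB = exp(-(I_n M_1 + I_c M_2))` with a user stain matrix (two built-ins:
a stain-separation estimate and the classical Ruifrok–Johnston vectors).
Treating the ideal channels directly as stain concentrations is the
implemented contract; the stain round-trip through the pseudo-inverse then
recovers the channels to machine precision on noise-free renders. A
scalebar, when requested, is burnt in as pure black, 4 px high with a 10 px
margin.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `grade` | 0 | — | master knob: coverage, deformation, shapes, phenotypes |
| `max_overlap` | 0.6 | fraction | pairwise overlap cap; also enters both count formulas |
| `cellularity_epithelial/stromal` | 1 | fraction | linear scaling of cell numbers |
| `cell_radius` | 6 | um | spacing unit of both count formulas and goblet rings |
| `magnification`, `ccd_pixel_size` | 40, 11 | —, um | specimen pixel size `ccd/mag` (0.275 um/px at 40x) |
| `psf_sigma`, `noise_variance` | 1 px, 2.5e-4 | px, intensity^2 | acquisition degradation |
| `stain_matrix` | separation estimate | OD | H&E colour composition |
| `seed` | 1 | — | master seed; stages and batch images use derived streams |

All lengths live in micrometres in the configuration and parameter tables
and are converted once at simulation start.

### Default morphometry and phenotype tables

The source publication presents its measured crypt-size distributions and
17 nuclear phenotype profiles only graphically, so this package cannot ship
those numbers. The defaults are therefore the package's own choices, made
once: crypt semi-minor axes `Gamma(25, 2.28)` um (mean 57 um) with axis ratio
`Gamma(20, 0.034)` (mean 0.68) for healthy tissue, and `Gamma(12, 65/12)`
um (mean 65 um, wider spread) with ratio mean 0.70 for cancerous tissue —
within histological plausibility, and calibrated so that the default
1000x1000 field at 40x with `L_max = 0.6` and unit cellularities reproduces
the published typical ranges for that exact condition (N_e in [110, 200],
N_s in [150, 260], N in [340, 380], batch mean near 360). The 17 phenotype
profiles group into regular columnar (1-6), enlarged atypical (7-10), small
round stromal (11-14) and spindle (15-17) classes, with frequency tables
that shift mass from regular to atypical with grade; both tables are
editable YAML and replaceable by fits from real annotations via
`learn_parameters()`.

## Numerical choices and degenerate inputs

* Rasterization uses even-odd membership of pixel centres (`mgcv::in.out`);
  its boundary-pixel convention is the package's tie-break. A position
  exactly on a crypt outline classifies as stromal (outside).
* `N_c` rounds to nearest; `gamma` rounds to nearest with a minimum ring of
  3 (smaller crypts render lumen-only, logged).
* Normal axis draws are truncated at `0.3 * mean` by redraw (100 tries, then
  the floor), preventing non-positive axes; degenerate `sigma = 0` returns
  the mean exactly.
* The axis-ratio rejection loop errors after 1000 draws (degenerate Gamma
  parameters); constant samples make `fit_gamma` fail loudly rather than
  return a divergent shape.
* Affinity propagation uses damping 0.9, at most 1000 iterations,
  median-similarity preference, and a tiny deterministic jitter to break
  exact ties; non-convergence returns labels with a warning.
* GLCM features quantize to 32 levels and average offsets
  {(0,1),(1,0),(1,1),(1,-1)}; entropies use log2. A constant patch returns
  the documented degenerate vector (energy 1, entropy 0, correlation 0 with
  a warning).
* Both-empty masks have Dice 1 by convention. The textbook claim that
  object-level Dice never exceeds pixel-level Dice is *not* asserted as an
  invariant — `validate_run()` probes it on random sub-segmentations and
  reports the violation count instead of suppressing counterexamples.
* Seeds: `derive_seed(master, k)` is an exact affine hash modulo `2^31 - 1`;
  architecture, cells, textures and noise consume independent streams, so
  e.g. adding texture classes does not perturb the placed cells.

## Problem sizes used by the shipped checks

The test suite runs layout-mode fields between 200 and 420 px plus a batch
of 1000x1000 layout fields for the count study; texture tests use 16-24 px
exemplars with window radius 2 and canvases up to 48 px, and full renders
up to 300 px. These sizes were chosen as the smallest at which every
statistical check has adequate power. `scripts/acceptance.R` regenerates
the published-condition quantities at full 1000x1000 size: 20 fields for
the batch count and grade-3 fields until 2000 stromal tumour cells are
accumulated. Ground-truth-only (`render = "layout"`) mode is used wherever
the measured quantity is a placement/count statistic, since texture
synthesis and staining do not alter the placed population.

## What the synthetic data does and does not show

The generator emulates gland architecture, cell crowding and overlap,
phenotype mixture shifts, chromatin/lumen texture statistics, and
acquisition blur/noise, with exact instance-level ground truth — the
setting needed to benchmark cell/crypt segmentation, counting, restoration
and grading pipelines. It deliberately omits: extracellular matrix texture
between stromal cells, membranes as a separate compartment, muscularis and
submucosa layers, necrosis, 3-D structure and whole-slide context; stromal
cell subtypes are rendered generically, tumour budding and mucin loss are
not modelled beyond the coverage and phenotype shifts. Passing tests
therefore certify internal consistency with the stated model and published
summary statistics — not biological fidelity beyond those features, and
results on synthetic fields should be read as upper bounds on algorithm
behaviour rather than replacements for hand-marked tissue.

## Known limitations

* Sequential placement can fall short of `N_c` for large deformed crypts in
  small fields; the shortfall is logged and all counts are derived from the
  actually-placed architecture.
* Synthetic exemplars are statistical stand-ins; chromatin classes are
  distinguishable but not histologically calibrated.
* The non-parametric synthesis is exhaustive-search (with early pruning)
  by design; canvas size is the cost knob, and canvases are cached.
* Grade 1 renders like grade 0 apart from deformation/phenotype shifts;
  partial goblet loss in grade 1 is not modelled (the source describes
  goblet construction for healthy samples only).
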