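---
title: "Models and methods behind hexpack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexpack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions, numerical choices and known
limitations of `hexpack`. It is the place where every genuinely open design
decision is recorded with its rationale.

## Coordinate frame and edge classes

All meshes live in a fixed micrometre frame with `x` the equatorial (Eq)
axis and `y` the anterior–posterior (AP) axis, mathematical orientation
(y up). Rasters are converted at load time (row 1 is the top of the image;
pixel `(r, c)` has centre `((c − 0.5)·ps, (nrow − r + 0.5)·ps)`). Edge
angles are reported in degrees in `[0, 180)` from `+x`; for a polyline edge
the angle (and every force calculation) uses the chord between its
endpoints, matching the straight-edge force model.

An edge is **Eq** when its acute angle to the Eq axis is at most the
threshold, otherwise **AP**; ties classify as Eq. The default threshold of
45° is the only value under which an ideal flat-top hexagon — edges at 0°,
60° and 120° — receives its canonical 2 Eq + 4 AP edges; it is exposed as
`threshold_deg` everywhere it matters.

## The tissue mesh

`build_mesh_from_polygons` assembles a shared-vertex, shared-edge mesh from
one ring per cell, merging vertices within `snap_tol` (default `1e-6` µm
for analytically generated polygons; raster meshes use pixel-scale
tolerances). An edge claimed by more than two cells is a topology error;
zero-area rings are rejected with their index. A cell is *boundary* when
any of its edges has a single adjacent cell or touches the raster border;
interior cells are the default population for every tissue statistic,
because boundary cells have truncated neighborhoods and inflate apparent
defect counts. For Voronoi tissues the boundary definition is strengthened:
any cell clipped by the tessellation window *or adjacent to a clipped cell*
is boundary, since a closed tile at the ragged margin of the point set
still has a truncated Voronoi neighborhood. For a defect-free `n × m`
lattice this leaves the `(n−2) × (m−2)` interior block (a 10 × 10 lattice
has 64 interior cells; a 3 × 3 lattice has one — its centre cell genuinely
has all six neighbors).

`extract_mesh_from_labels` consumes an integer-labelled segmentation. The
boundary mask (background pixels near labels, plus carved midlines where
two labels touch) is thinned to a one-pixel skeleton (Zhang–Suen). Skeleton
pixels seeing three or more distinct labels, skeleton branch points
(crossing number ≥ 3), and pixels where two cells meet the image border or
the tissue hull are junctions; junction pixels within two pixels of each
other cluster into one vertex. The remaining skeleton decomposes into arcs,
each traced as the shortest path through its pixel-adjacency graph (robust
to residual two-pixel-thick staircases) and attached to its end junctions;
stray fragmented junctions are fused by a final vertex merge at 3.5 px and
degree-two vertices between collinear arcs are dissolved. Cells take their
pixel-count area and pixel centroid. The procedure is fully deterministic.
Labels under `min_px = 9` pixels are excluded with a warning, a
disconnected label is an error, and marginal slivers whose boundaries
cannot be resolved are dropped with a warning. Edges below roughly two
pixels cannot be resolved and fuse into higher-valence junctions — the
resolution limit that also affects microscopy segmentations; round-trip
tests therefore use tissues whose edges are several pixels long (≥ 5 px/µm
on lattices with micrometre-scale edges).

## Synthetic tissues and their ground truth

`generate_hex_lattice` builds flat-top honeycombs. `eq_stretch` elongates
the two equatorial edges so that the Eq:AP mean edge-length *ratio equals
the parameter* (the natural control-like preset is `7.9/4.4 ≈ 1.8`,
mirroring reported mean Eq and AP edge lengths); this is deliberate —
stretching all x-coordinates by a factor does *not* produce that
edge-length ratio, because oblique edges only partially project onto x.

`generate_voronoi_tissue` jitters a triangular point lattice (vertical
bonds, so tiles are flat-top hexagons) with isotropic Gaussian noise of
standard deviation `jitter` lattice spacings, optionally Lloyd-relaxes, and
tessellates with `deldir`. Zero jitter reproduces the hexagonal lattice;
jitter progressively melts the packing. The default spacing is 4 µm so
that cell areas (~14 µm²) and edge lengths are microscopy-like.

`insert_defect_pair` performs defect surgery on the generating points. A
**dislocation** applies the continuum displacement field of an edge
dislocation (isotropic elasticity, Poisson ratio 1/3, Burgers vector one
vertical lattice vector) and merges point pairs driven closer than half a
spacing; the tessellation then carries exactly one bound 5/7 pair at the
core. A **disclination** cannot be inserted locally — it is a global
topological charge, and any local surgery creates a compensating defect —
so the point set is rebuilt as a cone lattice: 5 (or 7) matched sectors of
triangular lattice whose apex cell has coordination 5 (or 7), all other
interior cells 6. Defect-recovery experiments insert into gently jittered
tissues (jitter 0.05, 300 cells) and count a defect as recovered when a
cluster of the requested classification lies within two lattice spacings
of the insertion site; stray jitter-induced clusters elsewhere do not
negate recovery of the inserted defect.

`assign_tensions` prescribes ground-truth tensions: `class_based` assigns
`t_ap`/`t_eq` by orientation class with optional multiplicative lognormal
noise (coefficient of variation `noise_cv`; multiplicative noise keeps
tensions positive), `sinusoidal` interpolates
`T(θ) = t_eq + (t_ap − t_eq)·sin²θ`. Tensions are normalised to mean one
and pressures start at zero, matching the inference gauge.

`relax_to_force_balance` moves free (interior) vertices until the net
force `F_v = Σ_e T_e û_{v→w} + Σ_c P_c ∂A_c/∂r_v` vanishes
(`∂A_c/∂r_v = ½(y_b − y_a, x_a − x_b)`, the outward area gradient). That
force is minus the gradient of `E = Σ T_e L_e − Σ P_c A_c`, so relaxation
is a deterministic L-BFGS minimisation with analytic gradient; convergence
requires the largest free-vertex force below `tol` (default `1e-6` in
mean-tension units; presets use `1e-5`). Two physical complications are
handled explicitly:

* *Edge collapse (T1 events).* With heterogeneous tensions the tension-only
  energy is unstable to edge collapse — verified numerically: edges shrink
  to ~1e-13 of their length and the minimisation stalls at finite residual.
  When an inner minimisation stalls with edges shorter than 5% of the
  median starting length, those edges are contracted into higher-valence
  junctions (which the inference handles), their tension entries dropped,
  tensions renormalised to mean one, and relaxation continues on the new
  topology.
* *Area elasticity.* For noisy or strongly anisotropic prescriptions an
  area-elastic term `(K/2) Σ (A_c − A0_c)²` (default preset `K = 10`)
  replaces fixed pressures; at the minimum the pressures are
  `P_c = −K(A_c − A0_c)` and are written back into the ground truth
  (shifted to mean zero, which leaves interior-vertex balance unchanged),
  so the relaxed geometry and the `(T*, P*)` pair satisfy exactly the
  balance equations the inference assembles. `area_stiffness = 0`
  reproduces the pure fixed-pressure prescription, used for the noise-free
  lattice conditions.

Boundary vertices are pinned throughout, mimicking a patch embedded in a
larger sheet.

Rendering: `render_label_image` scanline-fills each cell with a unique
label and carves one-pixel 0-valued boundaries along the pixel grid
(deterministic, avoids dashed lines from rounding exactly half-integer
coordinates); `render_edge_intensity_image` strokes each edge at its
class's intensity level (brighter value wins where strokes overlap at
vertices), then adds Gaussian noise clipped at zero.

## Orientational order and shape

`psi_n(j) = (1/z_j) Σ_k exp(i n θ_jk)` over all mesh neighbors of cell `j`
(boundary cells count as neighbors), with `θ_jk` the angle of the
centroid-to-centroid vector; area centroids of the polygons are used, not
vertex means, for robustness to unequal edge sampling. Cells without
neighbors report a missing value, never zero. The global parameter `Psi_n`
is the **modulus of the complex mean** over interior cells — not the mean
of moduli — because tissue-wide order requires phase coherence across
cells, which a mean of moduli cannot detect. Boundary cells' per-cell
values are computed but excluded from global averages. The annotation
thresholds 0.65 (crystal) and 0.35 (hexatic) are reported as flags only.

The shape tensor uses chord-length weighting,
`s_j = (1/A_j) Σ_e L_e (û_e ⊗ û_e)`, which makes `trace(s_j)` the
perimeter-to-area ratio and reproduces the reading that `s_yy` captures AP
alignment; squared-length and unweighted alternatives are available behind
the `weighting` switch since the exact weighting is a genuinely open
choice. The anisotropy ratio is `s_yy/s_xx`, 1 for any regular polygon,
`h/w` for an axis-aligned rectangle; it is undefined (missing) only when
all edges are exactly vertical.

## Bayesian force inference

Force balance at each interior vertex gives two linear equations in the
unknowns `x = (T_1..T_E, P_1..P_C)`: unit chord vectors on tensions,
outward area gradients (`½ R90(b − a)` over each incident cell's cycle) on
pressures. Vertices of valence ≥ 4 contribute rows with all incident terms.
Boundary vertices are excluded (unknown external forces); edges with no
interior endpoint are determined by the prior alone and flagged
`prior_dominated`.

Because only force ratios are observable, the system is solved as
`min ‖Ax‖² + µ‖T − 1‖² + ε₀‖P‖²`: a proper Gaussian mean-one prior on
tensions with weight `µ`, and a *flat* prior on pressures with a fixed
infinitesimal ridge `ε₀` (`1e-8` of the mean pressure-block diagonal of
`AᵀA`, hence scale-free) that only pins the pressure gauge. `µ` is selected
by minimising `ABIC(µ) = N log(S/N) − E log µ + log det(AᵀA + µB_T + ε₀I_P)`
over `µ ∈ 10^{−4..4}` (17 points) with golden-section refinement; `S` is
the attained penalised objective and `N` the number of equations. The
pressure ridge is deliberately excluded from the µ-scaled prior
bookkeeping: folding it in (e.g. as `ε = 10⁻⁶µ`) makes the marginal
likelihood decrease without bound in µ and collapses the tension amplitude
onto the prior. With the flat-pressure treatment, noise-free synthetic
tissues drive µ to the small end of the grid and the inferred tension field
recovers the full ground-truth amplitude.

The solver is a sparse Cholesky solve of the normal equations — no random
initialisation, bit-reproducible. The solution is renormalised to mean
tension one over the informative (non-`prior_dominated`) edges — the
normalisation is applied after excluding boundary edges, the convention
adopted for the open question of when "mean one per image" is enforced —
and mean pressure zero (a pure gauge shift for interior rows). Negative
inferred tensions are counted and reported, not errors. "High tension"
means `T ≥ 1` (within 1e-12), used for the polar distribution of
above-mean-tension edge orientations (18 bins of 20°, edges mirrored into
both half-planes since they are apolar).

## Intensity measurements

Edge masks are the polyline (or chord) dilated to `line_width_px` (default
3 px), trimmed along the edge axis by half-width + 1 px at both ends: the
junction zone lies under the strokes of several edges and would
contaminate the per-edge signal (very short edges retain at least their
central third). `mean_gray` is the exact pixel mean over the mask. The
per-micrometre normalised intensity is `mean_gray × line_width_px` — the
mean-times-nominal-width estimator — rather than the raw pixel sum divided
by length, because the discrete pixel area of a stroke depends on its
orientation (a horizontal 3-px stroke rasterises to ~4 px per column, an
oblique one to ~3), which would bias AP:Eq ratios by ~20%. With this
estimator the renderer oracle is recovered exactly: a 2:1 AP:Eq rendering
yields a tissue ratio of 2.0, a uniform rendering 1.0, and the 1.19-fold
preset 1.19 under noise. Cells lacking either edge class, or with zero Eq
signal, are excluded and counted. Cell density follows the stated ROI
procedure verbatim — nuclei count divided by ROI area (µm²), times 1000 —
and is labelled *per 1000 µm²* here; the bundled 9109.6 µm² ROI matches the
meridional-row preset.

## Problem sizes and determinism

Default study sizes were chosen so the full test suite and the analysis
scripts complete in a few minutes on one core while keeping every estimate
stable: 10–12 row lattices (64–100 interior cells) for analytic identities
and recovery, 200–400-cell Voronoi tissues for disorder sweeps (10–20 seeds
per condition), 300-cell tissues for the 50-seed defect-recovery study, and
8 px/µm rendering for round-trip extraction. Every stochastic step takes an
explicit integer seed, and identical seeds give bit-identical meshes,
tensions, rasters and summaries.

## What the generator does and does not emulate

The synthetic tissues reproduce the *geometry and mechanics* being
measured: confluent polygonal packing, controllable coordination-number
disorder and topological defects, orientation-dependent junctional tension
with force-balanced geometry, and junctional-marker rasters with Gaussian
noise. They do not model microscopy point-spread functions, uneven
illumination, segmentation errors other than resolution-limited edge
fusion, curved cell boundaries (edges are straight after relaxation),
cell division, or any temporal dynamics (T1 contraction here is a
numerical device for reaching static equilibrium, not a kinetic model).
Passing recovery tests on these tissues therefore validates the estimators
under their stated assumptions — planarity, mechanical equilibrium,
straight-edge force balance — not robustness to every imaging artefact of
real data.

## Known limitations

* Tensions and pressures are relative; between-image comparisons rely on
  the mean-one normalisation, as in the underlying inference framework.
* Four-way junctions are retained (not split) and resolved by the prior;
  heavily degenerate meshes will lean correspondingly harder on it.
* The extraction's resolution limit fuses sub-pixel edges into
  higher-valence junctions, slightly deflating defect counts of strongly
  disordered tissues at low magnification.
* Defect classification near the analysis boundary is flagged `truncated`
  (the cluster may continue into excluded cells) and reported separately;
  small fields of view overestimate defect burdens.
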