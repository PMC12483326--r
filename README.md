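# hexpack

Quantitative analysis of hexagonal cell packing and junctional mechanics in
confluent epithelial monolayers — the geometry found, for example, in the
meridional-row (MR) cells of the vertebrate lens, where nearly every cell is
a hexagon with two edges along the equatorial (Eq) axis and four along the
anterior–posterior (AP) axis.

The package is aimed at quantitative cell biologists and tissue biophysicists
who have segmented microscopy images of a monolayer (or want a synthetic
stand-in with known ground truth) and need the standard packing readouts:

- **Tissue meshes** — a polygonal representation of the monolayer (vertices,
  edges, cells, adjacency), built either from generator polygons or from an
  integer-labelled segmentation raster via boundary skeletonisation and
  region-adjacency analysis (`build_mesh_from_polygons`,
  `extract_mesh_from_labels`), with JSON and TIFF/PNG I/O.
- **Packing topology** — neighbor-number distributions and classification of
  topological defects: a *dislocation* is a bound 5/7-neighbor pair (mean
  coordination six, nonzero Burgers vector, estimated from the 7→5 centroid
  displacement); a *disclination* is an isolated cell whose cluster's mean
  coordination differs from six; balanced 5-7-7-5 chains are neutral
  (`neighbor_distribution`, `find_defect_clusters`, `defect_frequencies`).
- **Orientational order and shape** — per-cell and global hexatic and
  nematic bond-orientational order,
  `psi_n(j) = (1/z_j) * sum_k exp(i n theta_jk)` with `Psi_n` the modulus of
  the complex mean over interior cells; the edge-based cell shape tensor
  `s_j = (1/A_j) * sum_e L_e (u_e ⊗ u_e)` whose diagonal ratio
  `s_AP/s_Eq = s_yy/s_xx` measures elongation; AP/Eq edge classification
  (45° threshold) with count and length statistics (`psi_n_cell`,
  `global_psi_n`, `shape_tensor`, `ap_eq_counts`, `edge_length_stats`).
- **Bayesian force inference** — relative edge tensions and cell pressures
  from geometry alone, assuming force balance at every interior vertex:
  `min ||A x||^2 + mu ||T − 1||^2` with a Gaussian mean-one tension prior,
  the weight `mu` selected by ABIC, tensions renormalised to mean one per
  tissue (`assemble_balance_system`, `infer_forces`,
  `tension_orientation_stats`).
- **Junctional intensity and morphometrics** — per-edge integrated density
  and mean gray value of a marker image, the AP:Eq normalised-intensity
  ratio (1 = unpolarised marker), and ROI-based cell area / density
  (`edge_intensity_ratio`, `edge_mfi`, `cell_area_from_roi`).
- **Synthetic tissues with ground truth** — hexagonal lattices with
  controllable Eq elongation, jittered Voronoi tissues, surgical insertion
  of single dislocations/disclinations, orientation-dependent ground-truth
  tensions, relaxation to force balance (with T1 handling), and rendering
  of label and edge-intensity rasters, so every analysis stage has an
  oracle (`generate_hex_lattice`, `generate_voronoi_tissue`,
  `insert_defect_pair`, `assign_tensions`, `relax_to_force_balance`,
  `render_label_image`, `render_edge_intensity_image`).

## Worked example

Simulate an anisotropic-tension “control” tissue, infer tensions back from
its relaxed geometry, and read off the headline statistics:

```r
library(hexpack)

cfg <- preset_config("control", seed = 20260922, out_dir = "results/control")
s <- run_pipeline(cfg)

s$six_neighbor_fraction   # 0.953  - fraction of interior cells with 6 neighbors
s$Psi6                    # 0.873  - global hexatic order (crystal regime, > 0.65)
s$mean_nAP_nEq            # 2.00   - 4 AP + 2 Eq edges per cell
s$edge_length_ratio       # 0.70   - AP edges shorter than Eq edges
s$mean_T_AP; s$mean_T_Eq  # 1.18 / 0.67 - inferred tension is AP-polarised
s$tension_recovery_r      # 0.992  - inferred vs ground-truth tension correlation
s$tension_length_correlation  # -0.62 - shorter edges bear higher tension
s$intensity_ratio         # 1.190  - AP:Eq junctional marker polarity
```

The same pipeline with `preset_config("mutant")` (isotropic noisy tensions,
stronger positional disorder, an inserted dislocation) gives the disordered
phenotype: six-neighbor fraction 0.46, `Psi6` 0.12 (liquid regime),
`mean_T_AP/mean_T_Eq` ≈ 1.00, intensity ratio 1.00.

The numbered scripts under `analysis/` run the full study —
`01_simulate_tissues.R` through `05_intensity_morphometrics.R` — writing
per-stage tables under `results/` (topology census, jitter melting sweep,
order parameters, force-inference summaries, intensity ratios).

## Scope notes

Inferred tensions and pressures are *relative* (mean tension one, mean
pressure zero per tissue); absolute calibration, stress-tensor
coarse-graining, and time-resolved inference are out of scope, as are
learned segmentation (the pipeline consumes label images) and dynamic
vertex-model simulation (only static force-balanced configurations are
generated). See the methods vignette (`vignettes/hexpack-methods.Rmd`) for
the model, parameter choices, and limitations.
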