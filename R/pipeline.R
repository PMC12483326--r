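# End-to-end pipeline: simulate -> extract -> topology -> order -> forces ->
# intensity, with a serialisable configuration, per-stage logging, and a
# single machine-readable summary.

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Unknown keys are
#' rejected; all defaults are explicit in the returned object, and the
#' effective configuration is written alongside the outputs of every run.
#'
#' @param ... configuration overrides (see Details).
#' @details Keys: `tissue` ("voronoi" or "lattice"), `n_cells`, `n_rows`,
#'   `n_cols`, `spacing` (µm), `eq_stretch`, `jitter`, `lloyd_iters`,
#'   `defects` (list of `list(kind=, charge=)`), `t_ap`, `t_eq`, `noise_cv`,
#'   `tension_model`, `area_stiffness`, `relax_tol`, `relax`,
#'   `intensity_levels` (named AP/Eq), `image_noise_sd`, `px_per_um`,
#'   `line_width_px`, `ap_eq_threshold_deg`, `mu` (NULL = ABIC), `seed`,
#'   `out_dir`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    tissue = "voronoi", n_cells = 220, n_rows = 12, n_cols = 12,
    spacing = 4, eq_stretch = 1, jitter = 0.12, lloyd_iters = 1,
    defects = NULL, t_ap = 1, t_eq = 1, noise_cv = 0,
    tension_model = "class_based", area_stiffness = 10,
    relax_tol = 1e-5, relax = TRUE,
    intensity_levels = c(AP = 100, Eq = 100), image_noise_sd = 2,
    px_per_um = 5, line_width_px = 3, ap_eq_threshold_deg = 45,
    mu = NULL, seed = 1, out_dir = "hexpack_out"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  if (!cfg$tissue %in% c("voronoi", "lattice"))
    stop("tissue must be 'voronoi' or 'lattice'")
  structure(cfg, class = "pipeline_config")
}

#' Built-in pipeline presets
#'
#' `control`: anisotropic junctional tensions (AP > Eq), Eq-elongated
#' low-disorder tissue, AP-enriched junctional marker - the ordered,
#' anisotropic phenotype. `mutant`: isotropic tensions with tension noise,
#' stronger positional disorder plus an inserted dislocation, and an
#' unpolarised marker - the disordered phenotype.
#'
#' @param name `"control"` or `"mutant"`.
#' @param ... further overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
preset_config <- function(name = c("control", "mutant"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(
      tissue = "voronoi", n_cells = 220, jitter = 0.12, lloyd_iters = 1,
      t_ap = 1.3, t_eq = 0.7, noise_cv = 0,
      intensity_levels = c(AP = 119, Eq = 100)
    ),
    mutant = list(
      tissue = "voronoi", n_cells = 220, jitter = 0.3, lloyd_iters = 0,
      defects = list(list(kind = "dislocation")),
      t_ap = 1, t_eq = 1, noise_cv = 0.1,
      intensity_levels = c(AP = 100, Eq = 100)
    )
  )
  do.call(pipeline_config, utils::modifyList(base, list(...), keep.null = TRUE))
}

#' Run the analysis pipeline
#'
#' Simulates a tissue from the configuration, renders label and intensity
#' images, re-extracts the mesh from the label raster, computes packing
#' topology, orientational order, force inference and intensity statistics,
#' and writes all outputs (mesh JSON, ground truth JSON, TIFF rasters, CSV
#' tables, `summary.json`, `config.json`, `log.csv`) under
#' `config$out_dir`. Deterministic: identical configurations and seeds give
#' identical summaries.
#'
#' @param config a `pipeline_config`.
#' @return the summary list, invisibly; all artefacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- list()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- fun()
    logf[[length(logf) + 1]] <<- data.frame(
      stage = name, seconds = round(as.numeric(Sys.time() - t0), 3),
      seed = config$seed
    )
    out
  }
  out <- list()

  sim <- stage("simulate", function() {
    if (config$tissue == "lattice") {
      mesh <- generate_hex_lattice(config$n_rows, config$n_cols,
                                   edge_len = config$spacing / 2,
                                   eq_stretch = config$eq_stretch)
    } else {
      tp <- voronoi_tissue_points(config$n_cells, jitter = config$jitter,
                                  seed = config$seed, spacing = config$spacing)
      for (d in config$defects) {
        tp <- insert_defect_pair(
          tp, kind = d$kind,
          charge = if (is.null(d$charge)) 5L else d$charge,
          jitter = config$jitter, seed = config$seed
        )
      }
      mesh <- voronoi_mesh(tp, lloyd_iters = config$lloyd_iters)
    }
    gt <- assign_tensions(
      mesh, t_ap = config$t_ap, t_eq = config$t_eq,
      noise_cv = config$noise_cv, seed = config$seed,
      model = config$tension_model,
      intensity_levels = config$intensity_levels,
      threshold_deg = config$ap_eq_threshold_deg
    )
    if (config$relax) {
      mesh <- relax_to_force_balance(mesh, gt, tol = config$relax_tol,
                                     area_stiffness = config$area_stiffness)
      gt <- attr(mesh, "ground_truth")
    }
    write_mesh_json(mesh, file.path(config$out_dir, "mesh.json"))
    jsonlite::write_json(
      list(tension = gt$tension, pressure = gt$pressure,
           intensity_levels = as.list(gt$intensity_levels),
           tension_model = gt$tension_model, seed = gt$seed,
           noise_cv = gt$noise_cv,
           relaxation_residual = gt$relaxation_residual),
      file.path(config$out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = I(17)
    )
    label <- render_label_image(mesh, px_per_um = config$px_per_um)
    intens <- render_edge_intensity_image(
      mesh, gt, px_per_um = config$px_per_um,
      line_width_px = config$line_width_px,
      noise_sd = config$image_noise_sd, seed = config$seed
    )
    write_label_image(label, file.path(config$out_dir, "labels.tif"))
    write_intensity_image(intens, file.path(config$out_dir, "intensity.tif"))
    list(mesh = mesh, gt = gt, label = label, intens = intens)
  })

  extr <- stage("extract", function() {
    mx <- extract_mesh_from_labels(sim$label,
                                   pixel_size = attr(sim$label, "pixel_size"))
    write_mesh_json(mx, file.path(config$out_dir, "extracted_mesh.json"))
    # neighbor-count agreement for interior cells of the generating mesh
    ps <- attr(sim$label, "pixel_size")
    offx <- attr(sim$label, "xmin")
    offy <- attr(sim$label, "ymax") - nrow(sim$label) * ps
    ic <- interior_cells(sim$mesh)
    agree <- vapply(ic, function(j) {
      d2 <- (mx$cells$x + offx - sim$mesh$cells$x[j])^2 +
        (mx$cells$y + offy - sim$mesh$cells$y[j])^2
      mx$cells$z[which.min(d2)] == sim$mesh$cells$z[j]
    }, logical(1))
    list(mesh = mx, z_agreement = mean(agree))
  })

  topo <- stage("topology", function() {
    clusters <- find_defect_clusters(sim$mesh)
    utils::write.csv(defect_cluster_table(clusters),
                     file.path(config$out_dir, "defect_clusters.csv"),
                     row.names = FALSE)
    list(
      neighbor_distribution = neighbor_distribution(sim$mesh),
      frequencies = defect_frequencies(sim$mesh)
    )
  })

  ord <- stage("order", function() {
    os <- order_summary(sim$mesh, threshold_deg = config$ap_eq_threshold_deg)
    utils::write.csv(os$cells, file.path(config$out_dir, "order_cells.csv"),
                     row.names = FALSE)
    os
  })

  fi <- stage("forces", function() {
    sol <- infer_forces(sim$mesh, mu = config$mu)
    st <- tension_orientation_stats(sol, sim$mesh,
                                    threshold_deg = config$ap_eq_threshold_deg)
    utils::write.csv(st$edges, file.path(config$out_dir, "edge_tensions.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(cell = sim$mesh$cells$id, pressure = sol$pressure),
      file.path(config$out_dir, "cell_pressures.csv"), row.names = FALSE
    )
    utils::write.csv(st$polar_high$histogram,
                     file.path(config$out_dir, "polar_high_tension.csv"),
                     row.names = FALSE)
    use <- !sol$prior_dominated
    list(
      solution = sol, stats = st,
      recovery_r = stats::cor(sol$tension[use], sim$gt$tension[use])
    )
  })

  inten <- stage("intensity", function() {
    rec <- edge_intensity_records(sim$intens, sim$mesh,
                                  line_width_px = config$line_width_px,
                                  threshold_deg = config$ap_eq_threshold_deg)
    utils::write.csv(rec, file.path(config$out_dir, "edge_intensity.csv"),
                     row.names = FALSE)
    ratio <- edge_intensity_ratio(sim$intens, sim$mesh, records = rec)
    mfi <- edge_mfi(sim$intens, sim$mesh, records = rec)
    list(ratio = ratio, mfi = mfi)
  })

  summary <- list(
    n_cells = nrow(sim$mesh$cells),
    n_interior_cells = length(interior_cells(sim$mesh)),
    n_edges = nrow(sim$mesh$edges),
    neighbor_distribution = as.list(topo$neighbor_distribution),
    six_neighbor_fraction = unname(topo$neighbor_distribution[["6"]]),
    dislocation_fraction = topo$frequencies$dislocation_fraction,
    disclination_fraction = topo$frequencies$disclination_fraction,
    Psi6 = ord$tissue$Psi6, Psi2 = ord$tissue$Psi2,
    mean_anisotropy = ord$tissue$mean_anisotropy,
    mean_nAP_nEq = ord$tissue$mean_nAP_nEq,
    mean_L_AP = ord$tissue$mean_L_AP, mean_L_Eq = ord$tissue$mean_L_Eq,
    edge_length_ratio = ord$tissue$length_ratio,
    mean_T_AP = fi$stats$mean_T_AP, mean_T_Eq = fi$stats$mean_T_Eq,
    tension_length_correlation = fi$stats$r_TL,
    tension_recovery_r = fi$recovery_r,
    inference_mu = fi$solution$mu,
    inference_residual = fi$solution$residual,
    intensity_ratio = inten$ratio$tissue_ratio,
    image_mfi = inten$mfi$image_mfi,
    extraction_z_agreement = extr$z_agreement,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = I(17))
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  log_df <- do.call(rbind, logf)
  log_df$config_md5 <- unname(tools::md5sum(cfg_path))
  utils::write.csv(log_df, file.path(config$out_dir, "log.csv"),
                   row.names = FALSE)
  invisible(summary)
}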