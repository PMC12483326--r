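# Orientational order and cell-shape anisotropy.
#
# The n-fold bond-orientational order parameter of cell j is
#   psi_n(j) = (1/z_j) * sum_k exp(i n theta_jk),
# where theta_jk is the angle of the centroid-to-centroid vector from cell j
# to neighbor k, measured from the +x (Eq) axis. n = 6 probes hexagonal
# packing regularity (hexatic order), n = 2 nematic alignment. The global
# parameter Psi_n is the modulus of the complex mean of psi_n over interior
# cells: it is high only when the per-cell phases are coherent across the
# tissue, not merely when each cell is locally regular.
#
# Cell shape anisotropy uses the edge-based shape tensor
#   s_j = (1/A_j) * sum_edges L_e * (u_e x u_e),
# with u_e the unit chord vector of each edge; the ratio s_yy / s_xx
# (AP over Eq diagonal) is 1 for unelongated polygons, > 1 for cells
# elongated along the AP axis.

#' Per-cell n-fold bond-orientational order parameter
#'
#' Uses all mesh neighbors of the cell (including boundary cells as
#' neighbors). Cells without neighbors yield `NA` (missing, not zero).
#'
#' @param mesh a `tissue_mesh`.
#' @param cell cell id (may be a vector; default all cells).
#' @param n symmetry order, 2 (nematic) or 6 (hexatic).
#' @return complex vector of psi_n values, `NA` where undefined.
#' @export
psi_n_cell <- function(mesh, cell = mesh$cells$id, n = 6) {
  stopifnot(inherits(mesh, "tissue_mesh"), n >= 1)
  vapply(cell, function(j) {
    nb <- mesh$neighbors[[j]]
    if (!length(nb)) return(NA_complex_)
    th <- atan2(
      mesh$cells$y[nb] - mesh$cells$y[j],
      mesh$cells$x[nb] - mesh$cells$x[j]
    )
    mean(exp(1i * n * th))
  }, complex(1))
}

#' Global bond-orientational order parameter
#'
#' Modulus of the complex mean of per-cell psi_n over interior cells with a
#' defined value.
#'
#' @inheritParams psi_n_cell
#' @return a real number in `[0, 1]`.
#' @export
global_psi_n <- function(mesh, n = 6) {
  ic <- interior_cells(mesh)
  psi <- psi_n_cell(mesh, ic, n)
  psi <- psi[!is.na(psi)]
  if (!length(psi)) stop("no interior cell has a defined psi_n")
  Mod(mean(psi))
}

#' Cell shape tensor and anisotropy ratio
#'
#' `shape_tensor` returns the symmetric 2-by-2 edge-based shape tensor of a
#' cell; `anisotropy_ratio` returns its AP/Eq diagonal ratio `s_yy / s_xx`
#' (`NA` when `s_xx` is zero, i.e. all edges exactly vertical).
#'
#' @param mesh a `tissue_mesh`.
#' @param cell a single cell id for `shape_tensor`, a vector (default all
#'   cells) for `anisotropy_ratio`.
#' @param weighting edge weight in the tensor sum: chord length (`"length"`,
#'   the default, giving trace = perimeter/area), squared length
#'   (`"length2"`), or unweighted (`"none"`).
#' @return `shape_tensor`: a 2-by-2 matrix; `anisotropy_ratio`: numeric
#'   vector.
#' @export
shape_tensor <- function(mesh, cell, weighting = c("length", "length2", "none")) {
  stopifnot(inherits(mesh, "tissue_mesh"), length(cell) == 1)
  weighting <- match.arg(weighting)
  eids <- mesh$cell_edges[[cell]]
  e <- mesh$edges[eids, ]
  dx <- mesh$vertices$x[e$v2] - mesh$vertices$x[e$v1]
  dy <- mesh$vertices$y[e$v2] - mesh$vertices$y[e$v1]
  L <- sqrt(dx^2 + dy^2)
  ux <- dx / L; uy <- dy / L
  wgt <- switch(weighting, length = L, length2 = L^2, none = rep(1, length(L)))
  s <- matrix(c(
    sum(wgt * ux * ux), sum(wgt * ux * uy),
    sum(wgt * ux * uy), sum(wgt * uy * uy)
  ), 2, 2)
  s / mesh$cells$area[cell]
}

#' @rdname shape_tensor
#' @export
anisotropy_ratio <- function(mesh, cell = mesh$cells$id,
                             weighting = c("length", "length2", "none")) {
  weighting <- match.arg(weighting)
  vapply(cell, function(j) {
    s <- shape_tensor(mesh, j, weighting)
    if (s[1, 1] == 0) return(NA_real_)
    s[2, 2] / s[1, 1]
  }, numeric(1))
}

#' Classify edge orientation as AP or Eq
#'
#' An edge whose acute angle to the Eq (x) axis is at most `threshold_deg`
#' is equatorial, otherwise anterior-posterior. Ties (angle exactly at the
#' threshold) classify as Eq. The 45-degree default is the only threshold
#' that assigns an ideal flat-top hexagon (edges at 0 and +/-60 degrees) its
#' canonical 2 Eq + 4 AP edges.
#'
#' @param angle edge angle(s) in degrees in `[0, 180)`; typically
#'   `mesh$edges$angle`.
#' @param threshold_deg classification threshold in degrees.
#' @return character vector, `"AP"` or `"Eq"`.
#' @export
classify_edge_orientation <- function(angle, threshold_deg = 45) {
  if (any(!is.finite(angle))) stop("undefined edge angle (zero-length edge?)")
  ifelse(pmin(angle, 180 - angle) <= threshold_deg, "Eq", "AP")
}

#' Per-cell AP/Eq edge counts
#'
#' @param mesh a `tissue_mesh`.
#' @param cell cell id(s); default all cells.
#' @param threshold_deg orientation threshold, see
#'   [classify_edge_orientation()].
#' @return data frame with columns `cell`, `nAP`, `nEq`, `ratio`
#'   (`NA` when `nEq` is 0).
#' @export
ap_eq_counts <- function(mesh, cell = mesh$cells$id, threshold_deg = 45) {
  cls <- classify_edge_orientation(mesh$edges$angle, threshold_deg)
  out <- lapply(cell, function(j) {
    k <- cls[mesh$cell_edges[[j]]]
    nAP <- sum(k == "AP"); nEq <- sum(k == "Eq")
    c(nAP, nEq)
  })
  out <- do.call(rbind, out)
  data.frame(
    cell = cell, nAP = out[, 1], nEq = out[, 2],
    ratio = ifelse(out[, 2] > 0, out[, 1] / out[, 2], NA_real_)
  )
}

#' Edge-length statistics by orientation class
#'
#' Mean edge length of interior AP and Eq edges, their ratio, and the mean
#' per-cell AP/Eq length ratio over interior cells (cells lacking edges of
#' either class are excluded; the number excluded is reported).
#'
#' @param mesh a `tissue_mesh`.
#' @param threshold_deg orientation threshold.
#' @return named list: `mean_L_AP`, `mean_L_Eq`, `length_ratio`
#'   (`mean_L_AP / mean_L_Eq`), `mean_cell_ratio`, `n_cells_excluded`.
#' @export
edge_length_stats <- function(mesh, threshold_deg = 45) {
  cls <- classify_edge_orientation(mesh$edges$angle, threshold_deg)
  int_e <- !mesh$edges$boundary
  mAP <- mean(mesh$edges$length[int_e & cls == "AP"])
  mEq <- mean(mesh$edges$length[int_e & cls == "Eq"])
  ic <- interior_cells(mesh)
  per_cell <- vapply(ic, function(j) {
    eids <- mesh$cell_edges[[j]]
    k <- cls[eids]
    if (!any(k == "AP") || !any(k == "Eq")) return(NA_real_)
    mean(mesh$edges$length[eids[k == "AP"]]) /
      mean(mesh$edges$length[eids[k == "Eq"]])
  }, numeric(1))
  list(
    mean_L_AP = mAP, mean_L_Eq = mEq, length_ratio = mAP / mEq,
    mean_cell_ratio = mean(per_cell, na.rm = TRUE),
    n_cells_excluded = sum(is.na(per_cell))
  )
}

#' Order summary for a tissue
#'
#' Per-cell order parameters, shape tensors and AP/Eq counts plus global
#' summaries. Per-cell values are computed for every cell; global values
#' average interior cells only. The crystal (`Psi6 > 0.65`) and hexatic
#' (`Psi6 > 0.35`) flags are annotations following the phase thresholds
#' conventionally applied to these tissues.
#'
#' @param mesh a `tissue_mesh`.
#' @param threshold_deg AP/Eq orientation threshold.
#' @param weighting shape-tensor edge weighting, see [shape_tensor()].
#' @return list with elements `cells` (data frame, one row per cell) and
#'   `tissue` (named list of global statistics).
#' @export
order_summary <- function(mesh, threshold_deg = 45,
                          weighting = c("length", "length2", "none")) {
  weighting <- match.arg(weighting)
  psi6 <- psi_n_cell(mesh, n = 6)
  psi2 <- psi_n_cell(mesh, n = 2)
  ratio <- anisotropy_ratio(mesh, weighting = weighting)
  sxx <- syy <- sxy <- numeric(nrow(mesh$cells))
  for (j in mesh$cells$id) {
    s <- shape_tensor(mesh, j, weighting)
    sxx[j] <- s[1, 1]; syy[j] <- s[2, 2]; sxy[j] <- s[1, 2]
  }
  counts <- ap_eq_counts(mesh, threshold_deg = threshold_deg)
  cells <- data.frame(
    cell = mesh$cells$id,
    interior = !mesh$cells$boundary,
    psi6_re = Re(psi6), psi6_im = Im(psi6), psi6_abs = Mod(psi6),
    psi2_re = Re(psi2), psi2_im = Im(psi2), psi2_abs = Mod(psi2),
    s_xx = sxx, s_yy = syy, s_xy = sxy, anisotropy = ratio,
    nAP = counts$nAP, nEq = counts$nEq, nAP_nEq = counts$ratio
  )
  els <- edge_length_stats(mesh, threshold_deg)
  ic <- interior_cells(mesh)
  Psi6 <- global_psi_n(mesh, 6)
  Psi2 <- global_psi_n(mesh, 2)
  tissue <- list(
    Psi6 = Psi6, Psi2 = Psi2,
    crystal = Psi6 > 0.65, hexatic = Psi6 > 0.35,
    mean_anisotropy = mean(ratio[ic], na.rm = TRUE),
    mean_nAP_nEq = mean(counts$ratio[ic], na.rm = TRUE),
    mean_L_AP = els$mean_L_AP, mean_L_Eq = els$mean_L_Eq,
    length_ratio = els$length_ratio,
    mean_cell_length_ratio = els$mean_cell_ratio,
    n_interior = length(ic)
  )
  list(cells = cells, tissue = tissue)
}
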