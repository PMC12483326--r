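# Junctional-marker intensity along classified edges, and ROI-based cell
# area / density morphometrics.
#
# Edge masks are the edge polyline (or chord) dilated to a stroke of
# line_width_px pixels; overlapping masks near vertices contribute to both
# edges, as they would with manual line tracing. Integrated density is the
# pixel sum over the mask; dividing by the edge length in micrometres gives
# the per-micrometre normalised intensity whose AP/Eq ratio quantifies
# junctional polarity (ratio > 1: marker concentrated on AP edges).

# Pixel mask (r, c rows) of an edge's stroke on an image raster. The mask
# is trimmed near the edge's end vertices (by `trim_px`, default stroke
# half-width + 1): pixels at a junction lie under the strokes of several
# edges and would contaminate the per-edge signal. Very short edges reduce
# the trim to keep at least the central third of the stroke.
#' @keywords internal
edge_pixel_mask <- function(img, mesh, e, line_width_px, xmin, ymax,
                            trim_px = NULL) {
  ps <- mesh$pixel_size
  if (is.null(ps)) ps <- attr(img, "pixel_size")
  if (is.null(ps)) stop("no pixel size available for the image/mesh pair")
  pl <- if (!is.null(mesh$edge_polylines) && !is.null(mesh$edge_polylines[[e]])) {
    mesh$edge_polylines[[e]]
  } else {
    rbind(
      c(mesh$vertices$x[mesh$edges$v1[e]], mesh$vertices$y[mesh$edges$v1[e]]),
      c(mesh$vertices$x[mesh$edges$v2[e]], mesh$vertices$y[mesh$edges$v2[e]])
    )
  }
  nr <- nrow(img); nc <- ncol(img)
  # to pixel coordinates (r, c continuous)
  rr <- (ymax - pl[, 2]) / ps + 0.5
  cc <- (pl[, 1] - xmin) / ps + 0.5
  half_w <- line_width_px / 2
  hit <- matrix(FALSE, 0, 2)
  for (k in seq_len(nrow(pl) - 1)) {
    rlo <- max(1L, floor(min(rr[k], rr[k + 1]) - half_w - 1))
    rhi <- min(nr, ceiling(max(rr[k], rr[k + 1]) + half_w + 1))
    clo <- max(1L, floor(min(cc[k], cc[k + 1]) - half_w - 1))
    chi <- min(nc, ceiling(max(cc[k], cc[k + 1]) + half_w + 1))
    if (rlo > rhi || clo > chi) next
    Rg <- rlo:rhi; Cg <- clo:chi
    Rm <- matrix(Rg, length(Rg), length(Cg))
    Cm <- matrix(Cg, length(Rg), length(Cg), byrow = TRUE)
    vx <- rr[k + 1] - rr[k]; vy <- cc[k + 1] - cc[k]
    L2 <- max(vx^2 + vy^2, 1e-12)
    t <- pmin(1, pmax(0, ((Rm - rr[k]) * vx + (Cm - cc[k]) * vy) / L2))
    d <- sqrt((Rm - rr[k] - t * vx)^2 + (Cm - cc[k] - t * vy)^2)
    sel <- which(d <= half_w, arr.ind = TRUE)
    if (nrow(sel)) hit <- rbind(hit, cbind(Rg[sel[, 1]], Cg[sel[, 2]]))
  }
  hit <- unique(hit)
  L_um <- mesh$edges$length[e]
  if (nrow(hit) == 0) return(list(mask = hit, measured_len = L_um))
  L_px <- L_um / ps
  if (is.null(trim_px)) trim_px <- half_w + 1
  trim_px <- max(0, min(trim_px, L_px / 3))
  measured_len <- L_um - 2 * trim_px * ps
  if (trim_px > 0) {
    # trim along the chord axis so the retained stroke is a clean band
    ur <- rr[length(rr)] - rr[1]; uc <- cc[length(cc)] - cc[1]
    Lc <- sqrt(ur^2 + uc^2)
    ur <- ur / Lc; uc <- uc / Lc
    t <- (hit[, 1] - rr[1]) * ur + (hit[, 2] - cc[1]) * uc
    keep <- t >= trim_px & t <= Lc - trim_px
    if (any(keep)) hit <- hit[keep, , drop = FALSE] else measured_len <- L_um
  }
  list(mask = hit, measured_len = measured_len)
}

#' Per-edge intensity records
#'
#' Integrated density, mean gray value and length-normalised intensity of
#' every edge of the mesh measured on an intensity image.
#'
#' @param img numeric intensity matrix (row 1 = top). If the image carries
#'   `xmin`/`ymax` attributes (as rendered images do) they define the
#'   mesh-to-image frame; otherwise the mesh is assumed to live in the
#'   image's own frame (origin at the bottom-left pixel corner, as for
#'   extracted meshes).
#' @param mesh a `tissue_mesh` in the same coordinate frame.
#' @param line_width_px stroke width of the measurement mask in pixels.
#' @param threshold_deg AP/Eq classification threshold.
#' @return data frame with one row per edge: `id`, `class`,
#'   `integrated_density`, `n_px`, `mean_gray`, `length`,
#'   `normalized_intensity`.
#' @export
edge_intensity_records <- function(img, mesh, line_width_px = 3,
                                   threshold_deg = 45) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (line_width_px < 1) stop("line_width_px must be >= 1")
  xmin <- attr(img, "xmin"); ymax <- attr(img, "ymax")
  ps <- mesh$pixel_size
  if (is.null(ps)) ps <- attr(img, "pixel_size")
  if (is.null(ps)) stop("no pixel size available for the image/mesh pair")
  if (is.null(xmin)) xmin <- 0
  if (is.null(ymax)) ymax <- nrow(img) * ps
  # frame check: every vertex must fall inside the image
  rr <- (ymax - mesh$vertices$y) / ps + 0.5
  cc <- (mesh$vertices$x - xmin) / ps + 0.5
  if (any(rr < 0 | rr > nrow(img) + 1 | cc < 0 | cc > ncol(img) + 1))
    stop("mesh extends outside the image bounds")
  cls <- classify_edge_orientation(mesh$edges$angle, threshold_deg)
  out <- lapply(seq_len(nrow(mesh$edges)), function(e) {
    em <- edge_pixel_mask(img, mesh, e, line_width_px, xmin, ymax)
    mask <- em$mask
    if (nrow(mask) == 0) {
      warning(sprintf("edge %d has an empty mask; skipped", e))
      return(data.frame(
        id = e, class = cls[e], integrated_density = NA_real_, n_px = 0L,
        mean_gray = NA_real_, length = mesh$edges$length[e],
        normalized_intensity = NA_real_
      ))
    }
    id <- sum(img[mask])
    mg <- id / nrow(mask)
    # per-micrometre intensity: mean gray times the nominal stroke width.
    # Using the raw pixel count instead would make the estimate depend on
    # the stroke orientation (a horizontal 3-px stroke rasterises to a
    # different pixel area per unit length than an oblique one).
    data.frame(
      id = e, class = cls[e], integrated_density = id, n_px = nrow(mask),
      mean_gray = mg, length = mesh$edges$length[e],
      normalized_intensity = mg * line_width_px
    )
  })
  do.call(rbind, out)
}

#' AP/Eq edge-intensity ratio
#'
#' Per cell, the mean length-normalised intensity of its AP edges divided by
#' that of its Eq edges; the tissue value is the mean over cells that have
#' both classes. Cells lacking a class, or with zero Eq intensity, are
#' excluded and counted.
#'
#' @inheritParams edge_intensity_records
#' @param records optionally, a precomputed result of
#'   [edge_intensity_records()].
#' @return list with `cells` (data frame: cell, ratio, nAP, nEq, excluded,
#'   reason), `tissue_ratio`, `n_excluded`.
#' @export
edge_intensity_ratio <- function(img, mesh, line_width_px = 3,
                                 threshold_deg = 45, records = NULL) {
  if (is.null(records))
    records <- edge_intensity_records(img, mesh, line_width_px, threshold_deg)
  rows <- lapply(mesh$cells$id, function(ci) {
    eids <- mesh$cell_edges[[ci]]
    rec <- records[eids, ]
    ap <- rec$normalized_intensity[rec$class == "AP"]
    eq <- rec$normalized_intensity[rec$class == "Eq"]
    ap <- ap[!is.na(ap)]; eq <- eq[!is.na(eq)]
    if (!length(ap) || !length(eq)) {
      return(data.frame(cell = ci, ratio = NA_real_, nAP = length(ap),
                        nEq = length(eq), excluded = TRUE,
                        reason = "missing class"))
    }
    if (mean(eq) == 0) {
      return(data.frame(cell = ci, ratio = NA_real_, nAP = length(ap),
                        nEq = length(eq), excluded = TRUE,
                        reason = "division by zero"))
    }
    data.frame(cell = ci, ratio = mean(ap) / mean(eq), nAP = length(ap),
               nEq = length(eq), excluded = FALSE, reason = "")
  })
  cells <- do.call(rbind, rows)
  list(
    cells = cells,
    tissue_ratio = mean(cells$ratio[!cells$excluded]),
    n_excluded = sum(cells$excluded)
  )
}

#' Mean fluorescence intensity of edges
#'
#' Mean gray value per edge mask plus the unweighted mean over edges
#' (the per-image MFI summary).
#'
#' @inheritParams edge_intensity_ratio
#' @return list with `edges` (data frame) and `image_mfi`.
#' @export
edge_mfi <- function(img, mesh, line_width_px = 3, threshold_deg = 45,
                     records = NULL) {
  if (is.null(records))
    records <- edge_intensity_records(img, mesh, line_width_px, threshold_deg)
  list(
    edges = records[, c("id", "class", "mean_gray", "n_px")],
    image_mfi = mean(records$mean_gray, na.rm = TRUE)
  )
}

#' ROI cell-area and cell-density morphometrics
#'
#' `cell_area_from_roi` divides the ROI area by the number of nuclei counted
#' in it (mean cross-sectional area per cell). `cell_density_from_roi`
#' divides the count by the area and multiplies by 1000; the resulting unit
#' is cells per 1000 µm² (reported in the source procedure under the label
#' cells/mm², which this package reproduces verbatim rather than converting
#' by the literal µm²-to-mm² factor).
#'
#' @param roi_area_um2 ROI area in µm² (> 0). The bundled preset
#'   `9109.6` µm² corresponds to the meridional-row ROI.
#' @param nuclei_count number of nuclei in the ROI (>= 1).
#' @return a single number.
#' @export
cell_area_from_roi <- function(roi_area_um2, nuclei_count) {
  if (roi_area_um2 <= 0) stop("roi_area_um2 must be positive")
  if (nuclei_count < 1) stop("nuclei_count must be >= 1")
  roi_area_um2 / nuclei_count
}

#' @rdname cell_area_from_roi
#' @export
cell_density_from_roi <- function(nuclei_count, roi_area_um2) {
  if (roi_area_um2 <= 0) stop("roi_area_um2 must be positive")
  if (nuclei_count < 1) stop("nuclei_count must be >= 1")
  nuclei_count / roi_area_um2 * 1000
}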