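# Voronoi tissue generator: confluent monolayers built as the Voronoi
# tessellation of a (jittered) triangular point lattice. With zero jitter the
# tessellation is the flat-top hexagonal lattice; jitter progressively melts
# the packing, lowering the fraction of six-neighbor cells.

#' Triangular generating points for a Voronoi tissue
#'
#' Produces the point set whose Voronoi tessellation is the tissue, prior to
#' any defect surgery. Points sit on a triangular lattice (vertical bonds, so
#' the dual cells are flat-top hexagons) displaced by isotropic Gaussian
#' jitter.
#'
#' @param n_cells number of generating points (>= 16).
#' @param jitter displacement standard deviation as a fraction of the lattice
#'   spacing.
#' @param seed integer RNG seed; identical seeds give identical tissues.
#' @param spacing lattice spacing in micrometres (default 1).
#' @return an object of class `tissue_points`: list with `points` (n-by-2
#'   matrix), `spacing`, and `window` (xmin, xmax, ymin, ymax).
#' @export
voronoi_tissue_points <- function(n_cells, jitter = 0, seed = 1, spacing = 1) {
  if (n_cells < 16) stop("n_cells must be >= 16")
  if (jitter < 0) stop("jitter must be >= 0")
  s <- spacing
  colsp <- sqrt(3) / 2 * s
  nr <- max(4L, round(sqrt(n_cells * sqrt(3) / 2)))
  nc <- ceiling(n_cells / nr)
  pts <- matrix(0, nr * nc, 2)
  k <- 0L
  for (j in seq_len(nc) - 1L) {
    for (i in seq_len(nr) - 1L) {
      k <- k + 1L
      pts[k, ] <- c(j * colsp, i * s + (j %% 2L) * s / 2)
    }
  }
  pts <- pts[seq_len(n_cells), , drop = FALSE]
  if (jitter > 0) {
    set.seed(seed)
    pts <- pts + matrix(stats::rnorm(2 * n_cells, sd = jitter * s), ncol = 2)
  }
  win <- c(min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2])) +
    0.55 * s * c(-1, 1, -1, 1)
  structure(list(points = pts, spacing = s, window = win),
            class = "tissue_points")
}

#' Voronoi tessellation of a tissue point set
#'
#' Tessellates the points within their rectangular window (via `deldir`) and
#' assembles the clipped tiles into a `tissue_mesh`. Optional Lloyd
#' iterations replace each point by its tile centroid and re-tessellate,
#' evening out cell sizes.
#'
#' @param tp a `tissue_points` object (or n-by-2 matrix, in which case the
#'   window is the bounding box plus half a mean-spacing margin).
#' @param lloyd_iters number of Lloyd relaxation sweeps (default 0).
#' @return a `tissue_mesh`.
#' @export
voronoi_mesh <- function(tp, lloyd_iters = 0) {
  if (is.matrix(tp)) {
    s <- sqrt(diff(range(tp[, 1])) * diff(range(tp[, 2])) / nrow(tp))
    tp <- structure(list(
      points = tp, spacing = s,
      window = c(min(tp[, 1]), max(tp[, 1]), min(tp[, 2]), max(tp[, 2])) +
        0.55 * s * c(-1, 1, -1, 1)
    ), class = "tissue_points")
  }
  stopifnot(inherits(tp, "tissue_points"))
  pts <- tp$points
  for (it in seq_len(lloyd_iters)) {
    tiles <- voronoi_tiles(pts, tp$window)
    pts <- do.call(rbind, lapply(tiles, polygon_centroid))
  }
  tiles <- voronoi_tiles(pts, tp$window)
  mesh <- build_mesh_from_polygons(tiles, snap_tol = 1e-6 * tp$spacing)
  mesh$provenance <- "synthetic"
  # A cell at the tissue margin can have a closed (unclipped) tile, e.g. at
  # the ragged edge of the point lattice, and would otherwise pass as interior
  # despite a truncated Voronoi neighborhood. Flag as boundary every cell that
  # is clipped by the window or adjacent to a clipped cell.
  clipped <- mesh$cells$boundary
  near <- vapply(seq_len(nrow(mesh$cells)),
                 function(i) any(clipped[mesh$neighbors[[i]]]), logical(1))
  mesh$cells$boundary <- clipped | near
  attr(mesh, "points") <- pts
  mesh
}

#' @keywords internal
voronoi_tiles <- function(pts, win) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = win, suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  if (length(tl) != nrow(pts))
    stop("degenerate point set: coincident generating points")
  lapply(tl, function(t) cbind(t$x, t$y))
}

#' Generate a Voronoi tissue
#'
#' Convenience wrapper: jittered triangular points, optional defect surgery,
#' optional Lloyd relaxation, Voronoi tessellation. `jitter = 0` reproduces
#' the defect-free hexagonal lattice; increasing jitter lowers the fraction
#' of six-neighbor interior cells (on average over seeds).
#'
#' @inheritParams voronoi_tissue_points
#' @param lloyd_iters Lloyd relaxation sweeps after jittering.
#' @param defects optional list of defect requests, each a list with `kind`
#'   (`"dislocation"` or `"disclination"`) and optional `site` (x, y) and
#'   `charge` (for disclinations: 5 or 7); applied with [insert_defect_pair()].
#' @return a `tissue_mesh` (generating points in `attr(, "points")`).
#' @export
generate_voronoi_tissue <- function(n_cells, jitter = 0, lloyd_iters = 0,
                                    seed = 1, spacing = 1, defects = NULL) {
  tp <- voronoi_tissue_points(n_cells, jitter, seed, spacing)
  for (d in defects) {
    tp <- insert_defect_pair(
      tp, kind = d$kind,
      site = d$site, charge = if (is.null(d$charge)) 5L else d$charge
    )
  }
  voronoi_mesh(tp, lloyd_iters = lloyd_iters)
}
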