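# Polygonal tissue mesh: vertices, edges, cells, adjacency.
#
# Coordinate frame: x is the equatorial (Eq) axis, y the anterior-posterior
# (AP) axis, units micrometres, mathematical orientation (y up). Edge angles
# are reported in degrees in [0, 180) measured from +x.

#' @keywords internal
polygon_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @keywords internal
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' @keywords internal
edge_angle_deg <- function(dx, dy) {
  ang <- atan2(dy, dx) * 180 / pi
  ang <- ang %% 180
  ang[abs(ang - 180) < 1e-12] <- 0
  ang
}

# Merge points closer than tol into single vertices (union-find over a
# spatial hash so exact grid placement cannot split a close pair).
#' @keywords internal
snap_points <- function(pts, tol) {
  n <- nrow(pts)
  if (tol <= 0) {
    key <- paste(sprintf("%.17g", pts[, 1]), sprintf("%.17g", pts[, 2]))
    ids <- match(key, unique(key))
    uniq <- pts[!duplicated(key), , drop = FALSE]
    return(list(id = ids, xy = uniq))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gx <- floor(pts[, 1] / tol); gy <- floor(pts[, 2] / tol)
  cellkey <- paste(gx, gy)
  buckets <- split(seq_len(n), cellkey)
  bucket_of <- function(cx, cy) buckets[[paste(cx, cy)]]
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      js <- bucket_of(gx[i] + dx, gy[i] + dy)
      if (is.null(js)) next
      js <- js[js > i]
      if (!length(js)) next
      d2 <- (pts[js, 1] - pts[i, 1])^2 + (pts[js, 2] - pts[i, 2])^2
      for (j in js[d2 <= tol^2]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  uroot <- unique(root)
  ids <- match(root, uroot)
  xy <- matrix(0, length(uroot), 2)
  for (k in seq_along(uroot)) {
    m <- root == uroot[k]
    xy[k, ] <- c(mean(pts[m, 1]), mean(pts[m, 2]))
  }
  list(id = ids, xy = xy)
}

#' @keywords internal
new_tissue_mesh <- function(vertices, edges, cells, cell_vertices, cell_edges,
                            neighbors, edge_polylines = NULL,
                            pixel_size = NULL, provenance = "synthetic") {
  structure(
    list(
      vertices = vertices, edges = edges, cells = cells,
      cell_vertices = cell_vertices, cell_edges = cell_edges,
      neighbors = neighbors, edge_polylines = edge_polylines,
      pixel_size = pixel_size, provenance = provenance
    ),
    class = "tissue_mesh"
  )
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf(
    "tissue_mesh (%s): %d cells (%d interior), %d edges, %d vertices\n",
    x$provenance, nrow(x$cells), sum(!x$cells$boundary),
    nrow(x$edges), nrow(x$vertices)
  ))
  invisible(x)
}

#' Build a tissue mesh from polygon rings
#'
#' Assembles a shared-vertex, shared-edge polygonal mesh from one closed ring
#' per cell. Vertices of adjacent cells closer than `snap_tol` are merged so
#' that a border shared by two cells becomes a single edge with two adjacent
#' cells. Cells, edges and vertices touching the outer hull of the tissue are
#' flagged as boundary.
#'
#' @param polygons list of numeric n-by-2 matrices, one ring per cell in
#'   micrometre coordinates (first point not repeated at the end). Ring
#'   orientation is normalised to counter-clockwise.
#' @param snap_tol vertex merge tolerance in micrometres (default `1e-6`,
#'   appropriate for analytically generated polygons).
#' @return a `tissue_mesh` object.
#' @export
build_mesh_from_polygons <- function(polygons, snap_tol = 1e-6) {
  if (!is.list(polygons) || length(polygons) < 1)
    stop("need at least one polygon")
  if (snap_tol < 0) stop("snap_tol must be >= 0")
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3 || !all(is.finite(p)))
      stop(sprintf("polygon %d is not a finite n-by-2 ring with n >= 3", i))
    a <- polygon_signed_area(p)
    if (abs(a) <= snap_tol^2)
      stop(sprintf("degenerate (zero-area) polygon at index %d", i))
    if (a < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    p
  })

  allpts <- do.call(rbind, polygons)
  counts <- vapply(polygons, nrow, integer(1))
  snap <- snap_points(allpts, snap_tol)
  offsets <- c(0L, cumsum(counts))
  n_cells <- length(polygons)

  cell_vertices <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    ids <- snap$id[(offsets[ci] + 1L):offsets[ci + 1L]]
    # collapse consecutive duplicates including the wrap-around
    ids <- rle(ids)$values
    if (length(ids) > 1 && ids[1] == ids[length(ids)]) ids <- ids[-length(ids)]
    if (length(ids) < 3)
      stop(sprintf("polygon %d collapses under snapping (snap_tol too large?)", ci))
    if (anyDuplicated(ids))
      stop(sprintf("polygon %d is not simple after vertex snapping", ci))
    cell_vertices[[ci]] <- ids
  }

  # edge table keyed by unordered vertex pair
  ekey_all <- character(0)
  e_v1 <- integer(0); e_v2 <- integer(0)
  edge_of_key <- new.env(hash = TRUE, parent = emptyenv())
  edge_cells <- list()
  cell_edges <- vector("list", n_cells)
  n_edges <- 0L
  for (ci in seq_len(n_cells)) {
    vs <- cell_vertices[[ci]]
    nxt <- c(vs[-1], vs[1])
    eids <- integer(length(vs))
    for (k in seq_along(vs)) {
      a <- min(vs[k], nxt[k]); b <- max(vs[k], nxt[k])
      key <- paste0(a, "_", b)
      eid <- edge_of_key[[key]]
      if (is.null(eid)) {
        n_edges <- n_edges + 1L
        eid <- n_edges
        assign(key, eid, envir = edge_of_key)
        e_v1[eid] <- a; e_v2[eid] <- b
        edge_cells[[eid]] <- ci
      } else {
        cs <- edge_cells[[eid]]
        if (ci %in% cs)
          stop(sprintf("polygon %d traverses an edge twice (not simple)", ci))
        if (length(cs) >= 2)
          stop(sprintf(
            "topology error: edge shared by >2 cells (%s); polygons overlap beyond snap_tol",
            paste(c(cs, ci), collapse = ", ")
          ))
        edge_cells[[eid]] <- c(cs, ci)
      }
      eids[k] <- eid
    }
    cell_edges[[ci]] <- eids
  }

  vx <- snap$xy[, 1]; vy <- snap$xy[, 2]
  c1 <- vapply(edge_cells, function(z) z[1], integer(1))
  c2 <- vapply(edge_cells, function(z) if (length(z) > 1) z[2] else NA_integer_, integer(1))
  dx <- vx[e_v2] - vx[e_v1]; dy <- vy[e_v2] - vy[e_v1]
  len <- sqrt(dx^2 + dy^2)
  edges <- data.frame(
    id = seq_len(n_edges), v1 = e_v1, v2 = e_v2,
    cell1 = c1, cell2 = c2,
    length = len, angle = edge_angle_deg(dx, dy),
    boundary = is.na(c2)
  )

  finalize_mesh(
    vertices_xy = snap$xy, edges = edges,
    cell_vertices = cell_vertices, cell_edges = cell_edges,
    edge_polylines = NULL, pixel_size = NULL, provenance = "synthetic"
  )
}

# Compute cell table, neighbor lists, z and boundary flags from topology.
#' @keywords internal
finalize_mesh <- function(vertices_xy, edges, cell_vertices, cell_edges,
                          edge_polylines = NULL, pixel_size = NULL,
                          provenance = "synthetic",
                          cell_geom = NULL, vertex_boundary_extra = NULL) {
  n_cells <- length(cell_vertices)
  n_vert <- nrow(vertices_xy)

  neighbors <- vector("list", n_cells)
  for (i in seq_len(n_cells)) neighbors[[i]] <- integer(0)
  int_e <- which(!is.na(edges$cell2))
  for (e in int_e) {
    a <- edges$cell1[e]; b <- edges$cell2[e]
    neighbors[[a]] <- c(neighbors[[a]], b)
    neighbors[[b]] <- c(neighbors[[b]], a)
  }
  neighbors <- lapply(neighbors, function(z) sort(unique(z)))
  z <- vapply(neighbors, length, integer(1))

  if (is.null(cell_geom)) {
    cent <- matrix(0, n_cells, 2)
    area <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      ring <- vertices_xy[cell_vertices[[i]], , drop = FALSE]
      area[i] <- polygon_signed_area(ring)
      cent[i, ] <- polygon_centroid(ring)
    }
    if (any(area <= 0))
      stop("internal error: non-CCW or degenerate cell after assembly")
  } else {
    cent <- cell_geom$centroid
    area <- cell_geom$area
  }

  edge_boundary <- is.na(edges$cell2)
  if (!is.null(edges$border_flag)) edge_boundary <- edge_boundary | edges$border_flag
  vert_boundary <- rep(FALSE, n_vert)
  vert_boundary[c(edges$v1[edge_boundary], edges$v2[edge_boundary])] <- TRUE
  if (!is.null(vertex_boundary_extra)) vert_boundary[vertex_boundary_extra] <- TRUE
  cell_boundary <- rep(FALSE, n_cells)
  for (i in seq_len(n_cells)) {
    cell_boundary[i] <- any(edge_boundary[cell_edges[[i]]])
  }

  edges$boundary <- edge_boundary
  edges$border_flag <- NULL
  vertices <- data.frame(
    id = seq_len(n_vert), x = vertices_xy[, 1], y = vertices_xy[, 2],
    boundary = vert_boundary
  )
  cells <- data.frame(
    id = seq_len(n_cells), x = cent[, 1], y = cent[, 2],
    area = area, z = z, boundary = cell_boundary
  )
  new_tissue_mesh(vertices, edges, cells, cell_vertices, cell_edges,
                  neighbors, edge_polylines, pixel_size, provenance)
}

#' Interior cells of a tissue mesh
#'
#' Cells whose boundary flag is `FALSE`; all per-tissue statistics in this
#' package default to this set, since boundary cells have truncated neighbor
#' information and inflate apparent defect counts.
#'
#' @param mesh a `tissue_mesh`.
#' @return integer vector of cell ids.
#' @export
interior_cells <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  mesh$cells$id[!mesh$cells$boundary]
}

#' Validate tissue mesh invariants
#'
#' Checks referential integrity, positive areas and lengths, neighbor
#' symmetry, and agreement between the neighbor lists and edge-sharing
#' adjacency. Stops with a descriptive error on the first violation.
#'
#' @param mesh a `tissue_mesh`.
#' @return `TRUE`, invisibly.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  v <- mesh$vertices; e <- mesh$edges; cl <- mesh$cells
  if (!all(is.finite(v$x)) || !all(is.finite(v$y))) stop("non-finite vertex positions")
  if (!all(e$v1 %in% v$id) || !all(e$v2 %in% v$id)) stop("edge references missing vertex")
  if (!all(e$cell1 %in% cl$id)) stop("edge references missing cell")
  if (!all(stats::na.omit(e$cell2) %in% cl$id)) stop("edge references missing cell")
  if (any(e$length <= 0)) stop("non-positive edge length")
  if (any(cl$area <= 0)) stop("non-positive cell area")
  for (i in cl$id) {
    if (!all(mesh$cell_edges[[i]] %in% e$id)) stop("cell references missing edge")
    for (j in mesh$neighbors[[i]]) {
      if (!(i %in% mesh$neighbors[[j]])) stop("asymmetric neighbor relation")
    }
    if (cl$z[i] != length(mesh$neighbors[[i]])) stop("z inconsistent with neighbors")
  }
  # every interior vertex has >= 3 incident edges
  deg <- tabulate(c(e$v1, e$v2), nbins = nrow(v))
  if (any(deg[!v$boundary] < 3)) stop("interior vertex with < 3 incident edges")
  invisible(TRUE)
}

# Apply a rigid (or affine) transform to all mesh coordinates and recompute
# derived geometry. Used by property tests (rotation covariance).
#' @keywords internal
transform_mesh <- function(mesh, A = diag(2), b = c(0, 0)) {
  xy <- as.matrix(mesh$vertices[, c("x", "y")]) %*% t(A)
  xy[, 1] <- xy[, 1] + b[1]; xy[, 2] <- xy[, 2] + b[2]
  mesh$vertices$x <- xy[, 1]; mesh$vertices$y <- xy[, 2]
  refresh_mesh_geometry(mesh)
}

# Recompute lengths, angles, centroids and areas from vertex positions.
#' @keywords internal
refresh_mesh_geometry <- function(mesh) {
  vx <- mesh$vertices$x; vy <- mesh$vertices$y
  dx <- vx[mesh$edges$v2] - vx[mesh$edges$v1]
  dy <- vy[mesh$edges$v2] - vy[mesh$edges$v1]
  mesh$edges$length <- sqrt(dx^2 + dy^2)
  mesh$edges$angle <- edge_angle_deg(dx, dy)
  mesh$edge_polylines <- NULL
  for (i in mesh$cells$id) {
    ring <- cbind(vx[mesh$cell_vertices[[i]]], vy[mesh$cell_vertices[[i]]])
    a <- polygon_signed_area(ring)
    mesh$cells$area[i] <- abs(a)
    cc <- polygon_centroid(ring)
    mesh$cells$x[i] <- cc[1]; mesh$cells$y[i] <- cc[2]
  }
  mesh
}

#' Per-cell and per-edge tables
#'
#' Flat data frames (one row per cell / per edge) suitable for CSV export.
#'
#' @param mesh a `tissue_mesh`.
#' @return a data frame.
#' @export
mesh_cell_table <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  mesh$cells
}

#' @rdname mesh_cell_table
#' @export
mesh_edge_table <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  mesh$edges
}
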