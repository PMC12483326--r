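# Mesh serialization: a small JSON schema with vertices, edges (vertex pair,
# adjacent cells, optional pixel polyline) and cell vertex cycles. The writer
# stores enough state (flags, cell geometry) that a re-read mesh is identical
# whatever its provenance.

#' Write a tissue mesh to JSON
#'
#' @param mesh a `tissue_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_json <- function(mesh, path) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  obj <- list(
    vertices = lapply(seq_len(nrow(mesh$vertices)), function(i) {
      c(mesh$vertices$x[i], mesh$vertices$y[i])
    }),
    vertex_boundary = mesh$vertices$boundary,
    edges = lapply(seq_len(nrow(mesh$edges)), function(i) {
      e <- list(
        v = c(mesh$edges$v1[i], mesh$edges$v2[i]),
        cells = if (is.na(mesh$edges$cell2[i])) list(mesh$edges$cell1[i])
                else list(mesh$edges$cell1[i], mesh$edges$cell2[i]),
        boundary = mesh$edges$boundary[i]
      )
      if (!is.null(mesh$edge_polylines) && !is.null(mesh$edge_polylines[[i]])) {
        pl <- mesh$edge_polylines[[i]]
        e$polyline <- lapply(seq_len(nrow(pl)), function(k) c(pl[k, 1], pl[k, 2]))
      }
      e
    }),
    cells = lapply(seq_len(nrow(mesh$cells)), function(i) {
      list(
        vertices = mesh$cell_vertices[[i]],
        edges = mesh$cell_edges[[i]],
        centroid = c(mesh$cells$x[i], mesh$cells$y[i]),
        area = mesh$cells$area[i],
        boundary = mesh$cells$boundary[i]
      )
    }),
    pixel_size = mesh$pixel_size,
    provenance = mesh$provenance
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a tissue mesh from JSON
#'
#' @param path path to a file written by [write_mesh_json()].
#' @return a `tissue_mesh`.
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vxy <- do.call(rbind, lapply(obj$vertices, function(p) c(p[[1]], p[[2]])))
  n_edges <- length(obj$edges)
  e_v1 <- integer(n_edges); e_v2 <- integer(n_edges)
  c1 <- integer(n_edges); c2 <- rep(NA_integer_, n_edges)
  bflag <- logical(n_edges)
  polylines <- vector("list", n_edges)
  has_poly <- FALSE
  for (i in seq_len(n_edges)) {
    e <- obj$edges[[i]]
    e_v1[i] <- e$v[[1]]; e_v2[i] <- e$v[[2]]
    c1[i] <- e$cells[[1]]
    if (length(e$cells) > 1) c2[i] <- e$cells[[2]]
    bflag[i] <- isTRUE(e$boundary)
    if (!is.null(e$polyline)) {
      polylines[[i]] <- do.call(rbind, lapply(e$polyline, function(p) c(p[[1]], p[[2]])))
      has_poly <- TRUE
    }
  }
  dx <- vxy[e_v2, 1] - vxy[e_v1, 1]
  dy <- vxy[e_v2, 2] - vxy[e_v1, 2]
  len <- sqrt(dx^2 + dy^2)
  for (i in seq_len(n_edges)) {
    if (!is.null(polylines[[i]])) {
      pl <- polylines[[i]]
      len[i] <- sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
    }
  }
  edges <- data.frame(
    id = seq_len(n_edges), v1 = e_v1, v2 = e_v2, cell1 = c1, cell2 = c2,
    length = len, angle = edge_angle_deg(dx, dy),
    boundary = bflag, border_flag = bflag
  )
  n_cells <- length(obj$cells)
  cell_vertices <- lapply(obj$cells, function(cl) as.integer(unlist(cl$vertices)))
  cent <- do.call(rbind, lapply(obj$cells, function(cl) c(cl$centroid[[1]], cl$centroid[[2]])))
  area <- vapply(obj$cells, function(cl) as.numeric(cl$area), numeric(1))
  cell_edges <- lapply(obj$cells, function(cl) as.integer(unlist(cl$edges)))
  if (any(vapply(cell_edges, length, 0L) == 0))
    stop("mesh JSON: cell without an edge cycle")
  vb <- as.logical(unlist(obj$vertex_boundary))
  mesh <- finalize_mesh(
    vertices_xy = vxy, edges = edges,
    cell_vertices = cell_vertices, cell_edges = cell_edges,
    edge_polylines = if (has_poly) polylines else NULL,
    pixel_size = if (is.null(obj$pixel_size)) NULL else as.numeric(obj$pixel_size),
    provenance = obj$provenance,
    cell_geom = list(centroid = cent, area = area),
    vertex_boundary_extra = which(vb)
  )
  # cell boundary flags may be augmented beyond the edge-derived default
  # (e.g. Voronoi margin policy, raster hull detection): restore as stored
  mesh$cells$boundary <- vapply(obj$cells, function(cl) isTRUE(cl$boundary),
                                logical(1))
  mesh
}
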