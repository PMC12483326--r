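# Mesh extraction from segmented label images.
#
# Pipeline: (1) build the boundary mask (background pixels plus carved
# midlines where two labels touch directly), restricted to a band around the
# labelled tissue; (2) thin it to a one-pixel skeleton (Zhang-Suen);
# (3) classify skeleton pixels by the distinct cell labels adjacent to them -
# pixels seeing three or more labels (or lying where boundary arcs meet the
# image border) are junctions, clusters of junction pixels become vertices;
# (4) the remaining skeleton decomposes into arcs, each traced into an
# ordered pixel polyline and attached to its end junctions, giving edges
# with the two adjacent cells read off the region adjacency; (5) cells take
# their pixel-count area and pixel centroid, with vertex/edge cycles ordered
# by angle around the centroid. The whole procedure is deterministic.

# 3x3-neighborhood shift helper: returns a list of 8 shifted copies.
#' @keywords internal
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning of a logical matrix, vectorised over the image.
#' @keywords internal
zhang_suen_thin <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      # neighbors in order p2..p9 clockwise from north (row-1 = up)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Distinct positive labels in the 8-neighborhood (optionally radius 2) of
# each pixel in `which_px` (2-column r,c matrix).
#' @keywords internal
adjacent_labels <- function(labels, px, radius = 1) {
  nr <- nrow(labels); nc <- ncol(labels)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lapply(seq_len(nrow(px)), function(i) {
    r <- px[i, 1]; c <- px[i, 2]
    rs <- r + offs$dr; cs <- c + offs$dc
    ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
    sort(unique(labels[cbind(rs[ok], cs[ok])][labels[cbind(rs[ok], cs[ok])] > 0]))
  })
}

# Connected components (8-connectivity) over a set of pixels given as an
# r,c matrix; returns an integer component id per pixel. If `group` is
# given, pixels additionally connect only within the same group (used to
# keep arcs with different adjacent-cell pairs apart where they brush past
# each other at junctions).
#' @keywords internal
pixel_components <- function(px, group = NULL, radius = 1) {
  if (nrow(px) == 0) return(integer(0))
  key <- paste(px[, 1], px[, 2])
  id_of <- stats::setNames(seq_len(nrow(px)), key)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nk <- paste(px[, 1] + offs$dr[k], px[, 2] + offs$dc[k])
    to <- unname(id_of[nk])
    hit <- !is.na(to)
    if (!is.null(group)) hit <- hit & !is.na(to) &
        group[seq_len(nrow(px))] == group[ifelse(is.na(to), 1L, to)]
    if (any(hit))
      edges <- rbind(edges, cbind(which(hit), to[hit]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_len(nrow(px)), seq_len(nrow(px)))),
    directed = FALSE
  )
  igraph::components(g)$membership[seq_len(nrow(px))]
}

#' Extract a tissue mesh from a segmented label image
#'
#' Consumes an integer-labelled segmentation (one positive label per cell,
#' background 0; labels may either be separated by background boundaries or
#' touch directly, in which case a one-pixel boundary is carved), and builds
#' a polygonal `tissue_mesh` via skeletonisation of the cell boundaries and
#' region-adjacency analysis. Cells touching the image border are flagged
#' boundary; labels smaller than `min_px` pixels are excluded with a
#' warning; a label whose pixels are not connected is an error.
#'
#' @param labels integer matrix (row 1 = top of image), positive labels on
#'   background 0.
#' @param pixel_size micrometres per pixel.
#' @param min_px minimum label size in pixels (smaller labels are dropped).
#' @return a `tissue_mesh` with `provenance = "raster"`, polyline edges, and
#'   pixel-derived cell areas/centroids.
#' @export
extract_mesh_from_labels <- function(labels, pixel_size = 1, min_px = 9) {
  labels <- as.matrix(labels)
  if (!all(labels == round(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  ulab <- sort(unique(labels[labels > 0]))
  if (!length(ulab)) stop("label image is all background")
  nr <- nrow(labels); nc <- ncol(labels)

  # drop labels too small to be cells
  sizes <- tabulate(labels, nbins = max(ulab))[ulab]
  small <- ulab[sizes < min_px]
  if (length(small)) {
    warning(sprintf("excluding %d label(s) with fewer than %d pixels: %s",
                    length(small), min_px, paste(small, collapse = ", ")))
    labels[labels %in% small] <- 0L
    ulab <- setdiff(ulab, small)
    if (!length(ulab)) stop("label image is all background")
  }

  # connectivity check per label (8-connectivity, bbox-restricted spreading)
  for (L in ulab) {
    pos <- which(labels == L, arr.ind = TRUE)
    rs <- range(pos[, 1]); cs <- range(pos[, 2])
    sub <- labels[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE] == L
    reach <- matrix(FALSE, nrow(sub), ncol(sub))
    reach[which(sub)[1]] <- TRUE
    repeat {
      grown <- reach
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        grown <- grown | shift_mat(reach, dr, dc, FALSE)
      }
      grown <- grown & sub
      if (identical(grown, reach)) break
      reach <- grown
    }
    if (sum(reach) != sum(sub))
      stop(sprintf("label %d is not a single connected component", L))
  }

  # carve a boundary where two labels touch directly
  carve <- matrix(FALSE, nr, nc)
  for (sh in list(c(0, 1), c(1, 0))) {
    nb <- shift_mat(labels, sh[1], sh[2])
    diff2 <- labels > 0 & nb > 0 & labels != nb
    carve <- carve | diff2 | shift_mat(diff2, -sh[1], -sh[2], FALSE)
  }
  labels[carve] <- 0L

  # boundary band: background pixels within one pixel of any label
  bg <- labels == 0L
  near_lab <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    near_lab <- near_lab | shift_mat(labels, dr, dc) > 0
  }
  band <- bg & near_lab
  skel <- zhang_suen_thin(band)
  # cells bordering the exterior (outside the tissue or the image): dilate
  # the pure-exterior region and flag overlapping labels
  exterior <- bg & !band
  exterior[c(1, nr), ] <- TRUE
  exterior[, c(1, nc)] <- TRUE
  exterior0 <- exterior
  for (k in 1:3) {
    grown <- exterior
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mat(exterior, dr, dc, FALSE)
    }
    exterior <- grown
  }
  hull_labels <- sort(unique(labels[exterior & labels > 0]))

  spx <- which(skel, arr.ind = TRUE)
  if (nrow(spx) == 0) stop("no boundary skeleton found")
  adj <- adjacent_labels(labels, spx, radius = 1)
  need2 <- lengths(adj) < 2
  if (any(need2))
    adj[need2] <- adjacent_labels(labels, spx[need2, , drop = FALSE], radius = 2)
  on_border <- spx[, 1] <= 1 | spx[, 1] >= nr | spx[, 2] <= 1 | spx[, 2] >= nc

  # branch points of the skeleton: crossing number >= 3 (number of 0->1
  # transitions around the 8-neighborhood)
  s <- skel * 1L
  p2 <- shift_mat(s, 1, 0);  p3 <- shift_mat(s, 1, -1)
  p4 <- shift_mat(s, 0, -1); p5 <- shift_mat(s, -1, -1)
  p6 <- shift_mat(s, -1, 0); p7 <- shift_mat(s, -1, 1)
  p8 <- shift_mat(s, 0, 1);  p9 <- shift_mat(s, 1, 1)
  crossings <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  branch <- crossings[spx] >= 3

  # a skeleton pixel adjacent to the exterior where two cells meet is a
  # tissue-hull junction (the generalisation of the image-border rule)
  near_ext <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    near_ext <- near_ext | shift_mat(exterior0, dr, dc, FALSE)
  }
  at_hull <- near_ext[spx]

  is_junction <- lengths(adj) >= 3 | branch |
    ((on_border | at_hull) & lengths(adj) >= 2)
  jpx <- spx[is_junction, , drop = FALSE]
  if (nrow(jpx) == 0) {
    # a mesh needs at least one vertex; degenerate single-cell images get
    # one junction at the first skeleton pixel
    is_junction[1] <- TRUE
    jpx <- spx[is_junction, , drop = FALSE]
  }
  # junction pixels within two pixels of each other are one junction; this
  # keeps a fragmented meeting point (pixels separated by an arc pixel) from
  # splitting into several low-degree vertices
  jcomp <- pixel_components(jpx, radius = 2)
  n_vert <- as.integer(max(jcomp))
  # vertex positions: cluster centroids in micrometre coordinates (y-up)
  vx <- as.numeric(tapply((jpx[, 2] - 0.5) * pixel_size, jcomp, mean))
  vy <- as.numeric(tapply((nr - jpx[, 1] + 0.5) * pixel_size, jcomp, mean))
  # map from junction pixel key to vertex id
  jkey <- paste(jpx[, 1], jpx[, 2])
  vert_of_jpx <- stats::setNames(jcomp, jkey)

  # arcs: skeleton minus junctions
  apx <- spx[!is_junction, , drop = FALSE]
  aadj <- adj[!is_junction]
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]

  edges_list <- list()
  polylines <- list()
  if (nrow(apx) > 0) {
    acomp <- pixel_components(
      apx, group = vapply(aadj, paste, "", collapse = "_")
    )
    akey <- paste(apx[, 1], apx[, 2])
    arc_id_of <- stats::setNames(seq_len(nrow(apx)), akey)
    for (comp in seq_len(max(acomp))) {
      ix <- which(acomp == comp)
      cpx <- apx[ix, , drop = FALSE]
      n_cpx <- nrow(cpx)
      # junction vertex adjacent to each component pixel (NA if none)
      near_vert <- vapply(seq_len(n_cpx), function(i) {
        nk <- paste(rep(cpx[i, 1], 8) + offs$dr, rep(cpx[i, 2], 8) + offs$dc)
        vs <- vert_of_jpx[nk]
        vs <- vs[!is.na(vs)]
        if (length(vs)) as.integer(vs[1]) else NA_integer_
      }, integer(1))
      # intra-component 8-adjacency graph
      el <- NULL
      for (i in seq_len(n_cpx)) {
        nk <- paste(rep(cpx[i, 1], 8) + offs$dr, rep(cpx[i, 2], 8) + offs$dc)
        hits <- arc_id_of[nk]
        hits <- hits[!is.na(hits)]
        loc <- match(hits, ix)
        loc <- loc[!is.na(loc)]
        if (length(loc)) el <- rbind(el, cbind(i, loc))
      }
      g <- igraph::graph_from_edgelist(
        rbind(el, cbind(seq_len(n_cpx), seq_len(n_cpx))), directed = FALSE
      )
      # choose the two path ends: prefer pixels touching two different
      # junctions, else the most distant pixel pair (graph diameter)
      touching <- which(!is.na(near_vert))
      endA <- endB <- NA_integer_
      if (length(touching) >= 1) {
        endA <- touching[1]
        other <- touching[near_vert[touching] != near_vert[endA]]
        if (length(other)) {
          d <- igraph::distances(g, v = endA)[1, ]
          endB <- other[which.max(d[other])]
        }
      }
      if (is.na(endA)) {
        ecc <- igraph::eccentricity(g)
        endA <- which.max(ecc)
      }
      if (is.na(endB)) {
        d <- igraph::distances(g, v = endA)[1, ]
        endB <- which.max(d)
      }
      path <- as.integer(igraph::shortest_paths(g, endA, endB)$vpath[[1]])
      opx <- cpx[path, , drop = FALSE]
      vA <- near_vert[endA]
      vB <- near_vert[endB]
      # adjacent cells: the two most frequent labels along the arc
      labs <- sort(table(unlist(aadj[ix])), decreasing = TRUE)
      labs <- as.integer(names(labs))
      arc_border <- any(opx[, 1] <= 1 | opx[, 1] >= nr |
                          opx[, 2] <= 1 | opx[, 2] >= nc)
      edges_list[[length(edges_list) + 1]] <- list(
        vA = vA, vB = vB,
        pA = opx[1, ], pB = opx[nrow(opx), ],
        cells = labs[seq_len(min(2, length(labs)))],
        border = arc_border
      )
      # polyline in micrometre coordinates
      pl <- cbind((opx[, 2] - 0.5) * pixel_size,
                  (nr - opx[, 1] + 0.5) * pixel_size)
      polylines[[length(edges_list)]] <- pl
    }
  }

  # resolve arc ends that found no junction pixel: cluster nearby orphan
  # ends into new vertices (two arcs meeting without an explicit junction
  # pixel between them), attaching to an existing junction cluster when one
  # lies within two pixels
  orphan <- do.call(rbind, lapply(seq_along(edges_list), function(i) {
    e <- edges_list[[i]]
    rbind(
      if (is.na(e$vA)) c(i, 1L, e$pA) else NULL,
      if (is.na(e$vB)) c(i, 2L, e$pB) else NULL
    )
  }))
  if (!is.null(orphan) && nrow(orphan) > 0) {
    ocomp <- pixel_components(orphan[, 3:4, drop = FALSE], radius = 2)
    for (oc in seq_len(max(ocomp))) {
      rows <- which(ocomp == oc)
      opix <- orphan[rows, 3:4, drop = FALSE]
      # nearest junction pixel within Chebyshev distance 3 of the cluster
      vid <- NA_integer_
      if (nrow(jpx) > 0) {
        best <- Inf; best_k <- NA_integer_
        for (k in seq_len(nrow(opix))) {
          cheb <- pmax(abs(jpx[, 1] - opix[k, 1]), abs(jpx[, 2] - opix[k, 2]))
          if (min(cheb) < best) {
            best <- min(cheb)
            best_k <- which.min(cheb)
          }
        }
        if (best <= 3) vid <- as.integer(vert_of_jpx[best_k])
      }
      if (is.na(vid)) {
        n_vert <- n_vert + 1L
        vx <- c(vx, mean((opix[, 2] - 0.5) * pixel_size))
        vy <- c(vy, mean((nr - opix[, 1] + 0.5) * pixel_size))
        vid <- n_vert
      }
      for (k in rows) {
        i <- orphan[k, 1]
        if (orphan[k, 2] == 1L) edges_list[[i]]$vA <- vid
        else edges_list[[i]]$vB <- vid
      }
    }
  }

  tryCatch(
    assemble_raster_mesh(
      labels = labels, ulab = ulab, pixel_size = pixel_size,
      vx = vx, vy = vy, n_vert = n_vert,
      edges_list = edges_list, polylines = polylines, nr = nr, nc = nc,
      hull_labels = hull_labels
    ),
    hexpack_empty_cells = function(e) {
      # typically minuscule clipped cells at the tissue margin whose
      # boundary arcs are thinner than the skeleton can resolve
      warning(sprintf(
        "excluding %d cell(s) whose boundaries could not be resolved: label %s",
        length(e$labels), paste(e$labels, collapse = ", ")
      ))
      labels[labels %in% e$labels] <- 0L
      extract_mesh_from_labels(labels, pixel_size, min_px)
    }
  )
}

# Build the tissue_mesh object from extraction intermediates.
#' @keywords internal
assemble_raster_mesh <- function(labels, ulab, pixel_size, vx, vy, n_vert,
                                 edges_list, polylines, nr, nc,
                                 hull_labels = integer(0)) {
  cell_of_label <- stats::setNames(seq_along(ulab), ulab)
  n_cells <- length(ulab)
  # per-cell pixel geometry
  area <- numeric(n_cells)
  cx <- numeric(n_cells); cy <- numeric(n_cells)
  for (i in seq_along(ulab)) {
    pos <- which(labels == ulab[i], arr.ind = TRUE)
    area[i] <- nrow(pos) * pixel_size^2
    cx[i] <- mean((pos[, 2] - 0.5) * pixel_size)
    cy[i] <- mean((nr - pos[, 1] + 0.5) * pixel_size)
  }
  border_cell <- ulab %in% hull_labels

  # edge table; drop arcs with no usable junction attachment or no cells
  keep <- vapply(edges_list, function(e) {
    !is.na(e$vA) && !is.na(e$vB) && length(e$cells) >= 1
  }, logical(1))
  edges_list <- edges_list[keep]
  polylines <- polylines[keep]
  if (!length(edges_list)) stop("no edges extracted from label image")
  n_edges <- length(edges_list)
  e_v1 <- vapply(edges_list, function(e) e$vA, integer(1))
  e_v2 <- vapply(edges_list, function(e) e$vB, integer(1))
  c1 <- vapply(edges_list, function(e) {
    unname(cell_of_label[as.character(e$cells[1])])
  }, integer(1))
  c2 <- vapply(edges_list, function(e) {
    if (length(e$cells) > 1) unname(cell_of_label[as.character(e$cells[2])])
    else NA_integer_
  }, integer(1))
  border_e <- vapply(edges_list, function(e) e$border, logical(1))

  # polyline with the junction vertices prepended/appended; arc length
  len <- numeric(n_edges); ang <- numeric(n_edges)
  for (i in seq_len(n_edges)) {
    pl <- rbind(c(vx[e_v1[i]], vy[e_v1[i]]),
                polylines[[i]],
                c(vx[e_v2[i]], vy[e_v2[i]]))
    polylines[[i]] <- pl
    len[i] <- sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
    ang[i] <- edge_angle_deg(pl[nrow(pl), 1] - pl[1, 1],
                             pl[nrow(pl), 2] - pl[1, 2])
  }
  ok_len <- len > 0
  if (any(e_v1 == e_v2 & vapply(polylines, nrow, 0L) < 4)) {
    # degenerate self-loop stubs from skeleton noise: drop
    drop <- e_v1 == e_v2 & vapply(polylines, nrow, 0L) < 4
    keep <- ok_len & !drop
  } else keep <- ok_len
  e_v1 <- e_v1[keep]; e_v2 <- e_v2[keep]; c1 <- c1[keep]; c2 <- c2[keep]
  border_e <- border_e[keep]; len <- len[keep]; ang <- ang[keep]
  polylines <- polylines[keep]

  # dissolve spurious degree-2 vertices (skeleton corner artefacts): merge
  # their two incident arcs into one polyline edge
  dissolve_deg2 <- function() {
    repeat {
      deg <- tabulate(c(e_v1, e_v2), nbins = n_vert)
      cand <- which(deg == 2)
      merged <- FALSE
      for (v in cand) {
        inc <- which(e_v1 == v | e_v2 == v)
        if (length(inc) != 2 || inc[1] == inc[2]) next
        a <- inc[1]; b <- inc[2]
        same_cells <- setequal(stats::na.omit(c(c1[a], c2[a])),
                               stats::na.omit(c(c1[b], c2[b])))
        if (!same_cells) next
        pla <- polylines[[a]]; plb <- polylines[[b]]
        if (e_v1[a] == v) pla <- pla[rev(seq_len(nrow(pla))), , drop = FALSE]
        if (e_v2[b] == v) plb <- plb[rev(seq_len(nrow(plb))), , drop = FALSE]
        new_v1 <- if (e_v1[a] == v) e_v2[a] else e_v1[a]
        new_v2 <- if (e_v2[b] == v) e_v1[b] else e_v2[b]
        if (new_v1 == new_v2) next  # would create a self-loop; leave as is
        polylines[[a]] <<- rbind(pla, plb[-1, , drop = FALSE])
        e_v1[a] <<- new_v1; e_v2[a] <<- new_v2
        border_e[a] <<- border_e[a] || border_e[b]
        pl <- polylines[[a]]
        len[a] <<- sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
        ang[a] <<- edge_angle_deg(pl[nrow(pl), 1] - pl[1, 1],
                                  pl[nrow(pl), 2] - pl[1, 2])
        e_v1 <<- e_v1[-b]; e_v2 <<- e_v2[-b]; c1 <<- c1[-b]; c2 <<- c2[-b]
        border_e <<- border_e[-b]; len <<- len[-b]; ang <<- ang[-b]
        polylines <<- polylines[-b]
        merged <- TRUE
        break
      }
      if (!merged) break
    }
  }
  dissolve_deg2()

  # merge vertices closer than ~3.5 px: junctions that fragmented into
  # nearby clusters during skeleton analysis are fused back into one vertex
  # (true junctions of a resolvable tissue are several pixels apart)
  snap <- snap_points(cbind(vx, vy), 3.5 * pixel_size)
  if (nrow(snap$xy) < n_vert) {
    e_v1 <- snap$id[e_v1]; e_v2 <- snap$id[e_v2]
    vx <- snap$xy[, 1]; vy <- snap$xy[, 2]
    n_vert <- nrow(snap$xy)
    loop <- e_v1 == e_v2
    if (any(loop)) {
      e_v1 <- e_v1[!loop]; e_v2 <- e_v2[!loop]
      c1 <- c1[!loop]; c2 <- c2[!loop]
      border_e <- border_e[!loop]; len <- len[!loop]; ang <- ang[!loop]
      polylines <- polylines[!loop]
    }
    # refresh polyline endpoints and derived geometry
    for (i in seq_along(polylines)) {
      pl <- polylines[[i]]
      pl[1, ] <- c(vx[e_v1[i]], vy[e_v1[i]])
      pl[nrow(pl), ] <- c(vx[e_v2[i]], vy[e_v2[i]])
      polylines[[i]] <- pl
      len[i] <- sum(sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2))
      ang[i] <- edge_angle_deg(pl[nrow(pl), 1] - pl[1, 1],
                               pl[nrow(pl), 2] - pl[1, 2])
    }
    dissolve_deg2()
  }

  # drop vertices that no longer appear; re-index
  used_v <- sort(unique(c(e_v1, e_v2)))
  remap <- match(seq_len(n_vert), used_v)
  e_v1 <- remap[e_v1]; e_v2 <- remap[e_v2]
  vx <- vx[used_v]; vy <- vy[used_v]
  n_vert <- length(used_v)
  n_edges <- length(e_v1)

  edges <- data.frame(
    id = seq_len(n_edges), v1 = e_v1, v2 = e_v2,
    cell1 = c1, cell2 = c2, length = len, angle = ang,
    boundary = is.na(c2) | border_e, border_flag = border_e
  )

  # cell cycles: edges of each cell ordered by angle of edge midpoint
  cell_edges <- vector("list", n_cells)
  cell_vertices <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    eids <- which(c1 == i | (!is.na(c2) & c2 == i))
    if (!length(eids)) next
    mid <- t(vapply(eids, function(e) {
      pl <- polylines[[e]]
      pl[ceiling(nrow(pl) / 2), ]
    }, numeric(2)))
    o <- order(atan2(mid[, 2] - cy[i], mid[, 1] - cx[i]))
    cell_edges[[i]] <- eids[o]
    vs <- unique(as.vector(rbind(e_v1[eids[o]], e_v2[eids[o]])))
    ov <- order(atan2(vy[vs] - cy[i], vx[vs] - cx[i]))
    cell_vertices[[i]] <- vs[ov]
  }
  empty <- vapply(cell_edges, is.null, logical(1))
  if (any(empty)) {
    stop(structure(
      class = c("hexpack_empty_cells", "error", "condition"),
      list(
        message = sprintf("cell(s) without extracted edges: label %s",
                          paste(ulab[empty], collapse = ", ")),
        call = sys.call(-1), labels = ulab[empty]
      )
    ))
  }

  mesh <- finalize_mesh(
    vertices_xy = cbind(vx, vy), edges = edges,
    cell_vertices = cell_vertices, cell_edges = cell_edges,
    edge_polylines = polylines, pixel_size = pixel_size,
    provenance = "raster",
    cell_geom = list(centroid = cbind(cx, cy), area = area)
  )
  mesh$cells$boundary <- mesh$cells$boundary | border_cell
  mesh$cells$label <- ulab
  mesh
}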