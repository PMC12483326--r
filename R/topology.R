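# Neighbor-number statistics and topological-defect classification.
#
# Cells that do not have six neighbors form clusters (connected components
# of the cell-adjacency graph restricted to non-six interior cells). A
# cluster is a dislocation when its average coordination is exactly six and
# it carries a nonzero Burgers vector (approximated by the centroid
# displacement from each 7-cell to its adjacent 5-cell); a cluster whose
# average coordination differs from six is a disclination; a balanced
# arrangement with cancelling displacements (e.g. 5-7-7-5) is neutral and
# counted as neither.

#' Neighbor-number distribution over interior cells
#'
#' @param mesh a `tissue_mesh`.
#' @return named numeric vector of fractions over the categories
#'   `<=4`, `5`, `6`, `7`, `>=8` (sums to 1).
#' @export
neighbor_distribution <- function(mesh) {
  ic <- interior_cells(mesh)
  if (!length(ic)) stop("mesh has no interior cells")
  z <- mesh$cells$z[ic]
  out <- c(
    `<=4` = mean(z <= 4), `5` = mean(z == 5), `6` = mean(z == 6),
    `7` = mean(z == 7), `>=8` = mean(z >= 8)
  )
  out
}

#' Find clusters of topological defects
#'
#' Connected components of non-six-neighbor interior cells under cell
#' adjacency. Each cluster carries its mean coordination (kept as an exact
#' integer sum so the comparison with six is rational, not floating point),
#' a Burgers-vector estimate (sum over adjacent (5,7) member pairs of the
#' centroid displacement from the 7-cell to the 5-cell), and a `truncated`
#' flag set when the cluster touches a non-interior cell that also deviates
#' from six neighbors (the defect may continue beyond the analysis region).
#'
#' @param mesh a `tissue_mesh`.
#' @return list of `defect_cluster` objects (fields: `members`, `z`,
#'   `mean_z`, `burgers`, `truncated`, `classification`), classification
#'   already assigned via [classify_clusters()].
#' @export
find_defect_clusters <- function(mesh) {
  ic <- interior_cells(mesh)
  bad <- ic[mesh$cells$z[ic] != 6]
  if (!length(bad)) return(list())
  edges <- do.call(rbind, lapply(bad, function(b) {
    nb <- intersect(mesh$neighbors[[b]], bad)
    if (length(nb)) cbind(b, nb) else cbind(b, b)
  }))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(bad))
  )
  memb <- igraph::components(g)$membership
  memb <- memb[as.character(bad)]
  clusters <- lapply(split(bad, memb), function(members) {
    z <- mesh$cells$z[members]
    burgers <- c(0, 0)
    fives <- members[z == 5]
    sevens <- members[z == 7]
    for (s7 in sevens) {
      for (s5 in intersect(mesh$neighbors[[s7]], fives)) {
        burgers <- burgers + c(
          mesh$cells$x[s5] - mesh$cells$x[s7],
          mesh$cells$y[s5] - mesh$cells$y[s7]
        )
      }
    }
    all_nb <- unique(unlist(mesh$neighbors[members]))
    outside <- setdiff(all_nb, ic)
    truncated <- any(mesh$cells$z[outside] != 6)
    structure(
      list(
        members = unname(members), z = unname(z),
        z_sum = sum(z), mean_z = mean(z),
        burgers = burgers, truncated = truncated,
        classification = NA_character_
      ),
      class = "defect_cluster"
    )
  })
  classify_clusters(unname(clusters))
}

#' Classify defect clusters
#'
#' Applies the classification rule: mean coordination exactly six (compared
#' as an exact integer identity, `sum(z) == 6 * n`) with a nonzero Burgers
#' estimate is a dislocation; mean coordination different from six is a
#' disclination; mean six with a vanishing Burgers estimate (cancelling
#' displacements) is neutral and excluded from both defect counts.
#'
#' @param clusters list of `defect_cluster` objects.
#' @return the same list with `classification` filled in.
#' @export
classify_clusters <- function(clusters) {
  lapply(clusters, function(cl) {
    balanced <- cl$z_sum == 6L * length(cl$members)
    bmag <- sqrt(sum(cl$burgers^2))
    cl$classification <- if (balanced && bmag > 0) {
      "dislocation"
    } else if (!balanced) {
      "disclination"
    } else {
      "neutral"
    }
    cl
  })
}

#' Defect frequencies over interior cells
#'
#' Fraction of interior cells belonging to clusters of each class (neutral
#' clusters count as neither defect type).
#'
#' @param mesh a `tissue_mesh`.
#' @param include_truncated drop clusters flagged `truncated` when `FALSE`.
#' @return named list: `dislocation_fraction`, `disclination_fraction`,
#'   `neutral_fraction`, `n_interior`.
#' @export
defect_frequencies <- function(mesh, include_truncated = TRUE) {
  ic <- interior_cells(mesh)
  if (!length(ic)) stop("mesh has no interior cells")
  clusters <- find_defect_clusters(mesh)
  if (!include_truncated)
    clusters <- Filter(function(cl) !cl$truncated, clusters)
  count <- function(class) {
    sum(vapply(clusters, function(cl) {
      if (cl$classification == class) length(cl$members) else 0L
    }, numeric(1)))
  }
  list(
    dislocation_fraction = count("dislocation") / length(ic),
    disclination_fraction = count("disclination") / length(ic),
    neutral_fraction = count("neutral") / length(ic),
    n_interior = length(ic)
  )
}

#' Defect cluster table
#'
#' One row per cluster, suitable for CSV export.
#'
#' @param clusters list of `defect_cluster` objects.
#' @return a data frame.
#' @export
defect_cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(
      members = character(0), n = integer(0), mean_z = numeric(0),
      burgers_x = numeric(0), burgers_y = numeric(0),
      classification = character(0), truncated = logical(0)
    ))
  }
  data.frame(
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ";"), ""),
    n = vapply(clusters, function(cl) length(cl$members), 0L),
    mean_z = vapply(clusters, function(cl) cl$mean_z, 0),
    burgers_x = vapply(clusters, function(cl) cl$burgers[1], 0),
    burgers_y = vapply(clusters, function(cl) cl$burgers[2], 0),
    classification = vapply(clusters, function(cl) cl$classification, ""),
    truncated = vapply(clusters, function(cl) cl$truncated, TRUE)
  )
}
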