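# Ground-truth tensions and force-balance relaxation for synthetic tissues.
#
# Mechanical model: each edge carries a line tension T_e pulling its two
# endpoint vertices together; each cell pushes its vertices outward with a
# pressure P_c conjugate to its area. The net force on vertex v is
#   F_v = sum_{e = (v,w)} T_e u_{v->w} + sum_{c around v} P_c dA_c/dr_v,
# with dA_c/dr_v = (1/2) (y_b - y_a, x_a - x_b) for a, b the neighbors of v
# in cell c's counter-clockwise cycle (the outward area gradient). A tissue
# is force-balanced when F_v vanishes at every free vertex. This force is
# minus the gradient of E = sum_e T_e L_e - sum_c P_c A_c, so relaxation is
# a deterministic quasi-Newton minimisation of E over the free vertices.

#' Assign ground-truth edge tensions
#'
#' Two generative models of orientation-dependent junctional tension:
#' `class_based` gives every AP-classified edge tension `t_ap` and every
#' Eq-classified edge `t_eq`, optionally multiplied by lognormal noise with
#' coefficient of variation `noise_cv` (multiplicative noise keeps tensions
#' positive); `sinusoidal` interpolates smoothly with
#' `T(theta) = t_eq + (t_ap - t_eq) sin^2(theta)`. Tensions are rescaled to
#' mean one and ground-truth pressures default to zero (mean-zero), so the
#' prescription matches the gauge used by the inference.
#'
#' @param mesh a `tissue_mesh`.
#' @param t_ap,t_eq tension levels for the two orientation classes (> 0).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   tension noise (>= 0).
#' @param seed RNG seed for the noise.
#' @param model `"class_based"` or `"sinusoidal"`.
#' @param intensity_levels named vector `c(AP = , Eq = )` of junctional
#'   marker intensity levels (arbitrary units) used when rendering
#'   edge-intensity images from this ground truth.
#' @param threshold_deg AP/Eq classification threshold in degrees.
#' @return object of class `ground_truth`: list with `tension` (per edge,
#'   mean 1), `pressure` (per cell, mean 0), `intensity_levels`,
#'   `tension_model`, `seed`, `noise_cv`, `relaxation_residual` (`NA` until
#'   relaxed).
#' @export
assign_tensions <- function(mesh, t_ap = 1, t_eq = 1, noise_cv = 0, seed = 1,
                            model = c("class_based", "sinusoidal"),
                            intensity_levels = c(AP = 100, Eq = 100),
                            threshold_deg = 45) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (t_ap <= 0 || t_eq <= 0) stop("t_ap and t_eq must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  model <- match.arg(model)
  th <- mesh$edges$angle
  tension <- if (model == "class_based") {
    cls <- classify_edge_orientation(th, threshold_deg)
    ifelse(cls == "AP", t_ap, t_eq)
  } else {
    t_eq + (t_ap - t_eq) * sin(th * pi / 180)^2
  }
  if (noise_cv > 0) {
    set.seed(seed)
    sdl <- sqrt(log(1 + noise_cv^2))
    tension <- tension * stats::rlnorm(length(tension), -sdl^2 / 2, sdl)
  }
  tension <- tension / mean(tension)
  structure(
    list(
      tension = tension,
      pressure = rep(0, nrow(mesh$cells)),
      intensity_levels = intensity_levels,
      tension_model = model, seed = seed, noise_cv = noise_cv,
      t_ap = t_ap, t_eq = t_eq,
      relaxation_residual = NA_real_
    ),
    class = "ground_truth"
  )
}

# Index structure for fast force evaluation: edge endpoint indices and
# (vertex, prev, next, cell) triplets for the pressure term.
#' @keywords internal
force_index <- function(mesh) {
  trip <- list()
  k <- 0L
  for (ci in mesh$cells$id) {
    vs <- mesh$cell_vertices[[ci]]
    nv <- length(vs)
    for (p in seq_len(nv)) {
      k <- k + 1L
      trip[[k]] <- c(
        v = vs[p],
        a = vs[if (p == 1) nv else p - 1],
        b = vs[if (p == nv) 1 else p + 1],
        cell = ci
      )
    }
  }
  trip <- do.call(rbind, trip)
  list(
    ev1 = mesh$edges$v1, ev2 = mesh$edges$v2,
    pv = trip[, "v"], pa = trip[, "a"], pb = trip[, "b"],
    pcell = trip[, "cell"]
  )
}

# Net force (per vertex, n x 2) given positions, tensions and pressures.
#' @keywords internal
vertex_forces <- function(xy, idx, tension, pressure) {
  dx <- xy[idx$ev2, 1] - xy[idx$ev1, 1]
  dy <- xy[idx$ev2, 2] - xy[idx$ev1, 2]
  L <- sqrt(dx^2 + dy^2)
  fx <- tension * dx / L
  fy <- tension * dy / L
  n <- nrow(xy)
  Fx <- numeric(n); Fy <- numeric(n)
  sx <- rowsum(c(fx, -fx), c(idx$ev1, idx$ev2))
  sy <- rowsum(c(fy, -fy), c(idx$ev1, idx$ev2))
  Fx[as.integer(rownames(sx))] <- sx[, 1]
  Fy[as.integer(rownames(sy))] <- sy[, 1]
  if (any(pressure != 0)) {
    gx <- 0.5 * (xy[idx$pb, 2] - xy[idx$pa, 2]) * pressure[idx$pcell]
    gy <- 0.5 * (xy[idx$pa, 1] - xy[idx$pb, 1]) * pressure[idx$pcell]
    Px <- rowsum(gx, idx$pv)
    Py <- rowsum(gy, idx$pv)
    Fx[as.integer(rownames(Px))] <- Fx[as.integer(rownames(Px))] + Px[, 1]
    Fy[as.integer(rownames(Py))] <- Fy[as.integer(rownames(Py))] + Py[, 1]
  }
  cbind(Fx, Fy)
}

#' Relax a tissue to force balance
#'
#' Moves the interior (free) vertices of the mesh, holding boundary vertices
#' fixed, until the net tension + pressure force vanishes at every free
#' vertex. Because that force is minus the gradient of the tissue energy,
#' relaxation is a deterministic L-BFGS minimisation; convergence is declared
#' when the largest free-vertex force magnitude falls below `tol`.
#'
#' With `area_stiffness = 0` the energy is the pure prescription
#' `sum_e T_e L_e - sum_c P_c A_c` with the pressures taken from the ground
#' truth. Heterogeneous tensions make this energy unstable to edge collapse
#' (a vertex whose incident tensions violate the triangle inequalities has
#' no balanced configuration with positive edge lengths), so for noisy or
#' strongly anisotropic prescriptions an area-elastic term
#' `(K/2) sum_c (A_c - A0_c)^2` (with `A0` the starting areas) replaces the
#' fixed pressures. At its minimum the cell pressures are
#' `P_c = -K (A_c - A0_c)`; these are written back into the returned ground
#' truth (shifted to mean zero, which leaves interior-vertex balance
#' unchanged), so the relaxed geometry and the (T*, P*) pair satisfy the
#' same vertex balance equations used by the inference.
#'
#' Heterogeneous tensions can drive T1 events: an edge whose tension exceeds
#' what its surroundings can hold shrinks to zero length and the energy
#' minimum has no smooth force balance there. When an inner minimisation
#' stalls with edges shorter than `t1_frac` times the median starting edge
#' length, those edges are contracted (their endpoints merge into a single
#' higher-valence junction, which the inference handles), the tension of the
#' vanished edge is dropped, and relaxation continues on the new topology.
#'
#' @param mesh a `tissue_mesh`.
#' @param ground_truth a `ground_truth` from [assign_tensions()].
#' @param tol convergence tolerance on the maximum free-vertex force
#'   magnitude (in mean-tension units).
#' @param max_iter maximum L-BFGS iterations per inner minimisation.
#' @param area_stiffness area-elastic modulus K (0 = pure fixed-pressure
#'   relaxation).
#' @param t1_frac edge-contraction threshold as a fraction of the median
#'   starting edge length.
#' @param max_rounds maximum number of minimisation / contraction rounds.
#' @return the relaxed `tissue_mesh` (possibly with fewer edges than the
#'   input if T1 contractions occurred), with attributes
#'   `relaxation_residual` (max free-vertex force), `relaxation_iterations`,
#'   `t1_contractions`, and `ground_truth` (tensions aligned to the returned
#'   mesh's edges, renormalised to mean one; pressures and
#'   `relaxation_residual` updated). Errors if the residual does not reach
#'   `tol`.
#' @export
relax_to_force_balance <- function(mesh, ground_truth, tol = 1e-6,
                                   max_iter = 3000, area_stiffness = 0,
                                   t1_frac = 0.05, max_rounds = 8) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(ground_truth, "ground_truth"))
  if (tol <= 0) stop("tol must be positive")
  K <- area_stiffness
  tension <- ground_truth$tension
  pressure0 <- ground_truth$pressure
  t1_tol <- t1_frac * stats::median(mesh$edges$length)
  # reference areas for the area-elastic term: cell identity (list order) is
  # preserved across T1 rebuilds
  A0 <- mesh$cells$area
  n_t1 <- 0L
  iters <- 0L

  inner <- function(mesh, tension) {
    idx <- force_index(mesh)
    free <- which(!mesh$vertices$boundary)
    if (!length(free)) stop("mesh has no free (interior) vertices")
    xy0 <- cbind(mesh$vertices$x, mesh$vertices$y)
    unpack <- function(p) {
      xy <- xy0
      xy[free, 1] <- p[seq_along(free)]
      xy[free, 2] <- p[seq_along(free) + length(free)]
      xy
    }
    cell_areas <- function(xy) {
      cr <- xy[idx$pv, 1] * xy[idx$pb, 2] - xy[idx$pb, 1] * xy[idx$pv, 2]
      rowsum(cr, idx$pcell)[, 1] / 2  # cells are 1..C; rowsum sorts numerically
    }
    pressures_at <- function(xy) {
      if (K > 0) -K * (cell_areas(xy) - A0) else pressure0
    }
    energy <- function(p) {
      xy <- unpack(p)
      dx <- xy[idx$ev2, 1] - xy[idx$ev1, 1]
      dy <- xy[idx$ev2, 2] - xy[idx$ev1, 2]
      en <- sum(tension * sqrt(dx^2 + dy^2))
      if (K > 0) {
        en + K / 2 * sum((cell_areas(xy) - A0)^2)
      } else if (any(pressure0 != 0)) {
        en - sum(pressure0 * cell_areas(xy))
      } else en
    }
    gradient <- function(p) {
      xy <- unpack(p)
      FF <- vertex_forces(xy, idx, tension, pressures_at(xy))
      -c(FF[free, 1], FF[free, 2])
    }
    p0 <- c(xy0[free, 1], xy0[free, 2])
    res <- stats::optim(p0, energy, gradient, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 10))
    xy <- unpack(res$par)
    P <- pressures_at(xy)
    FF <- vertex_forces(xy, idx, tension, P)
    list(
      xy = xy, pressure = P,
      resid = max(sqrt(FF[free, 1]^2 + FF[free, 2]^2)),
      iters = unname(res$counts[1])
    )
  }

  for (round in seq_len(max_rounds)) {
    st <- inner(mesh, tension)
    iters <- iters + st$iters
    mesh$vertices$x <- st$xy[, 1]
    mesh$vertices$y <- st$xy[, 2]
    mesh <- refresh_mesh_geometry(mesh)
    if (st$resid < tol) break
    collapsed <- which(mesh$edges$length < t1_tol)
    if (length(collapsed)) {
      reb <- contract_short_edges(mesh, tension, t1_tol)
      n_t1 <- n_t1 + reb$n_contracted
      mesh <- reb$mesh
      tension <- reb$tension
    }
    # otherwise: restart the quasi-Newton minimisation from the current state
    if (round == max_rounds) {
      stop(sprintf(
        "force-balance relaxation did not converge after %d rounds: residual %.3g >= tol %.3g",
        max_rounds, st$resid, tol
      ))
    }
  }
  # renormalise tensions (edges may have been dropped); scaling (T, P)
  # jointly preserves balance, and a constant pressure shift leaves
  # interior-vertex balance unchanged
  sc <- mean(tension)
  tension <- tension / sc
  P_final <- st$pressure / sc
  P_final <- P_final - mean(P_final)
  ground_truth$tension <- tension
  ground_truth$pressure <- P_final
  ground_truth$relaxation_residual <- st$resid / sc
  attr(mesh, "relaxation_residual") <- st$resid / sc
  attr(mesh, "relaxation_iterations") <- iters
  attr(mesh, "t1_contractions") <- n_t1
  attr(mesh, "ground_truth") <- ground_truth
  mesh
}

# Contract all edges shorter than tol by rebuilding the mesh from its cell
# polygons with vertex snapping at tol, and remap per-edge tensions onto the
# new edge set (tensions of vanished edges are dropped).
#' @keywords internal
contract_short_edges <- function(mesh, tension, tol) {
  polys <- lapply(mesh$cells$id, function(ci) {
    vs <- mesh$cell_vertices[[ci]]
    cbind(mesh$vertices$x[vs], mesh$vertices$y[vs])
  })
  new_mesh <- build_mesh_from_polygons(polys, snap_tol = tol)
  # map old vertices to new ones by proximity
  old_xy <- cbind(mesh$vertices$x, mesh$vertices$y)
  new_xy <- cbind(new_mesh$vertices$x, new_mesh$vertices$y)
  near <- vapply(seq_len(nrow(old_xy)), function(i) {
    d2 <- (new_xy[, 1] - old_xy[i, 1])^2 + (new_xy[, 2] - old_xy[i, 2])^2
    j <- which.min(d2)
    if (d2[j] > (2 * tol)^2) stop("T1 contraction: vertex mapping failed")
    j
  }, integer(1))
  new_key <- paste0(
    pmin(new_mesh$edges$v1, new_mesh$edges$v2), "_",
    pmax(new_mesh$edges$v1, new_mesh$edges$v2)
  )
  old_v1 <- near[mesh$edges$v1]
  old_v2 <- near[mesh$edges$v2]
  old_key <- paste0(pmin(old_v1, old_v2), "_", pmax(old_v1, old_v2))
  keep <- old_v1 != old_v2
  new_tension <- as.numeric(tapply(tension[keep], old_key[keep], mean)[new_key])
  if (anyNA(new_tension)) stop("T1 contraction: tension remapping failed")
  # carry over augmented boundary flags (cells preserve their list order)
  new_mesh$cells$boundary <- new_mesh$cells$boundary | mesh$cells$boundary
  list(mesh = new_mesh, tension = new_tension,
       n_contracted = sum(!keep))
}
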