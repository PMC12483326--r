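# Bayesian force inference: relative edge tensions and cell pressures from
# tissue geometry alone, assuming mechanical equilibrium at every vertex.
#
# The balance conditions are linear in the unknowns x = (T_1..T_E, P_1..P_C):
# two equations (x and y) per interior vertex. Because only ratios of forces
# are observable (and boundary conditions plus non-three-way junctions make
# the system indeterminate), the solution is regularised by a Gaussian prior
# of mean one on tensions (weight mu) and a weak mean-zero prior on
# pressures that fixes the pressure gauge. mu is selected by minimising
# ABIC, the Bayesian information criterion of the marginal likelihood
#   ABIC(mu) = N log(S/N) - log det(mu B) + log det(A'A + mu B) + const,
# where S is the attained penalised residual, over a log-spaced grid with
# golden-section refinement. The solver is a direct sparse Cholesky solve of
# the normal equations: fully deterministic.

#' Assemble the vertex force-balance system
#'
#' Two rows per interior vertex. Tension columns carry the unit chord vector
#' of each incident edge (pointing away from the vertex); pressure columns
#' carry the outward area gradient `(1/2) R90(b - a)` for each incident cell
#' with `a`, `b` the neighbors of the vertex in that cell's counter-clockwise
#' cycle. Vertices with four or more incident edges contribute rows with all
#' incident terms (no splitting).
#'
#' @param mesh a `tissue_mesh`.
#' @return object of class `balance_system`: list with the sparse matrix
#'   `A` (2 V_int rows, E + C columns), `n_edges`, `n_cells`,
#'   `interior_vertices`, `included_edges` (edges appearing in at least one
#'   equation), `n_equations`, `n_unknowns`.
#' @export
assemble_balance_system <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  iv <- which(!mesh$vertices$boundary)
  if (!length(iv)) stop("mesh has no interior vertex: balance system is empty")
  E <- nrow(mesh$edges); C <- nrow(mesh$cells)
  row_of <- integer(nrow(mesh$vertices))
  row_of[iv] <- seq_along(iv)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  vx <- mesh$vertices$x; vy <- mesh$vertices$y

  # tension terms
  for (e in seq_len(E)) {
    a <- mesh$edges$v1[e]; b <- mesh$edges$v2[e]
    L <- mesh$edges$length[e]
    # chord-based unit vector (straight-edge force model)
    ux <- (vx[b] - vx[a]) / sqrt((vx[b] - vx[a])^2 + (vy[b] - vy[a])^2)
    uy <- (vy[b] - vy[a]) / sqrt((vx[b] - vx[a])^2 + (vy[b] - vy[a])^2)
    if (row_of[a] > 0) {
      r <- 2L * row_of[a] - 1L
      ii <- c(ii, r, r + 1L); jj <- c(jj, e, e); xx <- c(xx, ux, uy)
    }
    if (row_of[b] > 0) {
      r <- 2L * row_of[b] - 1L
      ii <- c(ii, r, r + 1L); jj <- c(jj, e, e); xx <- c(xx, -ux, -uy)
    }
  }
  # pressure terms
  for (ci in seq_len(C)) {
    vs <- mesh$cell_vertices[[ci]]
    nv <- length(vs)
    for (p in seq_len(nv)) {
      v <- vs[p]
      if (row_of[v] == 0) next
      a <- vs[if (p == 1) nv else p - 1]
      b <- vs[if (p == nv) 1 else p + 1]
      r <- 2L * row_of[v] - 1L
      ii <- c(ii, r, r + 1L); jj <- c(jj, E + ci, E + ci)
      xx <- c(xx, 0.5 * (vy[b] - vy[a]), 0.5 * (vx[a] - vx[b]))
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(2L * length(iv), E + C))
  structure(
    list(
      A = A, n_edges = E, n_cells = C, interior_vertices = iv,
      included_edges = sort(unique(jj[jj <= E])),
      n_equations = 2L * length(iv), n_unknowns = E + C
    ),
    class = "balance_system"
  )
}

# Penalised least-squares solve at a given mu. The tension prior (weight mu)
# is a proper Gaussian; the pressure prior is flat (improper), with a fixed
# infinitesimal ridge eps0 that only fixes the pressure gauge and therefore
# does not enter the mu-dependent prior bookkeeping.
#' @keywords internal
solve_balance <- function(AtA, pen_T, pen_P, x0, mu) {
  G <- AtA + Matrix::Diagonal(x = mu * pen_T + pen_P)
  rhs <- mu * pen_T * x0
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(G)),
                 error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf(
      "balance system singular after regularisation (mu = %g); system rank < %d unknowns",
      mu, length(x0)
    ))
  }
  x <- as.numeric(Matrix::solve(ch, rhs))
  list(x = x, chol = ch, G = G)
}

#' @keywords internal
abic_score <- function(A, AtA, pen_T, pen_P, x0, mu, n_eq, n_tension) {
  sol <- solve_balance(AtA, pen_T, pen_P, x0, mu)
  r <- as.numeric(A %*% sol$x)
  S <- sum(r^2) + mu * sum(pen_T * (sol$x - x0)^2) + sum(pen_P * sol$x^2)
  logdetG <- 2 * as.numeric(Matrix::determinant(sol$chol, sqrt = TRUE)$modulus)
  abic <- n_eq * log(S / n_eq) - n_tension * log(mu) + logdetG
  list(abic = abic, S = S, sol = sol)
}

#' Infer relative edge tensions and cell pressures
#'
#' Solves the regularised force-balance problem
#' `min ||A x||^2 + mu ||T - 1||^2 + eps0 ||P||^2`, where the Gaussian
#' mean-one tension prior has weight `mu` and `eps0` is a fixed
#' infinitesimal ridge that only pins the pressure gauge (pressures
#' otherwise carry a flat prior). `mu` is selected by ABIC unless supplied;
#' the solution is then renormalised to mean tension one (over the edges
#' that enter at least one balance equation) and mean pressure zero. Edges
#' touching no interior vertex are constrained only by the prior and
#' flagged `prior_dominated`. Negative inferred tensions are counted and
#' reported, not treated as errors.
#'
#' @param mesh a `tissue_mesh`.
#' @param mu regularisation weight; `NULL` (default) selects by ABIC over
#'   `10^seq(-4, 4)` with golden-section refinement.
#' @param eps pressure gauge ridge, relative to the mean diagonal of the
#'   pressure block of the normal matrix (scale-free).
#' @return object of class `force_solution`: list with `tension` (per edge,
#'   mean 1 over included edges), `pressure` (per cell, mean 0), `residual`
#'   (root-mean-square force imbalance per equation), `residual_max_vertex`,
#'   `mu`, `abic`, `n_equations`, `n_unknowns`, `prior_dominated` (logical
#'   per edge), `n_negative_tensions`.
#' @export
infer_forces <- function(mesh, mu = NULL, eps = 1e-8) {
  sys <- assemble_balance_system(mesh)
  E <- sys$n_edges; C <- sys$n_cells
  if (sys$n_unknowns < 2) stop("need at least 2 unknowns")
  A <- sys$A
  AtA <- Matrix::crossprod(A)
  dP <- Matrix::diag(AtA)[E + seq_len(C)]
  eps0 <- eps * max(mean(dP), .Machine$double.eps)
  pen_T <- c(rep(1, E), rep(0, C))
  pen_P <- c(rep(0, E), rep(eps0, C))
  x0 <- c(rep(1, E), rep(0, C))
  score <- function(m) {
    abic_score(A, AtA, pen_T, pen_P, x0, m, sys$n_equations, E)
  }

  if (is.null(mu)) {
    grid <- 10^seq(-4, 4, length.out = 17)
    scores <- vapply(grid, function(m) score(m)$abic, numeric(1))
    k <- which.min(scores)
    lo <- log10(grid[max(1, k - 1)]); hi <- log10(grid[min(length(grid), k + 1)])
    # golden-section refinement on log10(mu)
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- score(10^c1)$abic
    f2 <- score(10^c2)$abic
    while (b - a > 0.02) {
      if (f1 <= f2) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a)
        f1 <- score(10^c1)$abic
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a)
        f2 <- score(10^c2)$abic
      }
    }
    mu <- 10^((a + b) / 2)
  }
  fit <- score(mu)
  x <- fit$sol$x

  prior_dominated <- !(seq_len(E) %in% sys$included_edges)
  mT <- mean(x[seq_len(E)][!prior_dominated])
  if (abs(mT) < 1e-12)
    stop("degenerate solution: mean inferred tension is zero")
  x <- x / mT
  P <- x[E + seq_len(C)]
  P <- P - mean(P)
  tension <- x[seq_len(E)]

  r <- as.numeric(A %*% c(tension, P))
  rx <- r[seq(1, length(r), 2)]; ry <- r[seq(2, length(r), 2)]
  structure(
    list(
      tension = tension, pressure = P,
      residual = sqrt(mean(r^2)),
      residual_max_vertex = max(sqrt(rx^2 + ry^2)),
      mu = mu, abic = fit$abic,
      n_equations = sys$n_equations, n_unknowns = sys$n_unknowns,
      prior_dominated = prior_dominated,
      n_negative_tensions = sum(tension < 0)
    ),
    class = "force_solution"
  )
}

#' @export
print.force_solution <- function(x, ...) {
  cat(sprintf(
    "force_solution: %d tensions (mean 1), %d pressures; mu = %.3g, rms residual = %.3g\n",
    length(x$tension), length(x$pressure), x$mu, x$residual
  ))
  if (x$n_negative_tensions > 0)
    cat(sprintf("  note: %d negative inferred tensions\n", x$n_negative_tensions))
  invisible(x)
}

#' Tension-orientation statistics
#'
#' Per-edge table of inferred tension against edge length and orientation,
#' the tension-length Pearson correlation, mean tension by AP/Eq class, and
#' the polar distribution of edge orientations for edges at or above mean
#' tension (T >= 1, "high tension") and below it, mirrored into both
#' half-planes and binned into 18 angular bins of 20 degrees.
#'
#' @param solution a `force_solution`.
#' @param mesh the `tissue_mesh` the solution was computed on.
#' @param threshold_deg AP/Eq classification threshold.
#' @return named list: `edges` (data frame), `r_TL`, `mean_T_AP`,
#'   `mean_T_Eq`, `polar_high`, `polar_low` (each a list with `angles_deg`,
#'   `lengths`, and an 18-bin `histogram` data frame).
#' @export
tension_orientation_stats <- function(solution, mesh, threshold_deg = 45) {
  stopifnot(inherits(solution, "force_solution"), inherits(mesh, "tissue_mesh"))
  if (length(solution$tension) != nrow(mesh$edges))
    stop("solution and mesh are inconsistent")
  cls <- classify_edge_orientation(mesh$edges$angle, threshold_deg)
  edges <- data.frame(
    id = mesh$edges$id,
    tension = solution$tension,
    length = mesh$edges$length,
    angle = mesh$edges$angle,
    class = cls,
    prior_dominated = solution$prior_dominated
  )
  use <- !solution$prior_dominated
  if (sum(use) < 3) stop("fewer than 3 informative edges: correlation undefined")
  r_TL <- stats::cor(edges$tension[use], edges$length[use])
  polar <- function(sel) {
    th <- edges$angle[sel]; L <- edges$length[sel]
    ang <- c(th, th + 180)  # edges are apolar: mirror into both half-planes
    len <- c(L, L)
    br <- seq(0, 360, by = 20)
    bin <- cut(ang %% 360, br, right = FALSE, include.lowest = TRUE)
    list(
      angles_deg = ang, lengths = len,
      histogram = data.frame(
        bin_center = br[-1] - 10,
        count = as.integer(table(bin)),
        summed_length = as.numeric(tapply(len, bin, sum, default = 0))
      )
    )
  }
  list(
    edges = edges,
    r_TL = r_TL,
    mean_T_AP = mean(edges$tension[use & cls == "AP"]),
    mean_T_Eq = mean(edges$tension[use & cls == "Eq"]),
    polar_high = polar(use & edges$tension >= 1 - 1e-12),
    polar_low = polar(use & edges$tension < 1 - 1e-12)
  )
}
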