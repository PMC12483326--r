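# Topological-defect surgery on the generating point set.
#
# A dislocation is inserted by applying the continuum displacement field of
# an edge dislocation (isotropic elasticity, Poisson ratio 1/3) with Burgers
# vector equal to one lattice vector to the generating points, then merging
# point pairs driven closer than half a spacing. The Voronoi tessellation of
# the result carries exactly one adjacent 5/7 neighbor pair at the core.
#
# A disclination is a global topological charge: it cannot be inserted
# locally without a compensating defect appearing elsewhere. The surgery
# therefore rebuilds the whole point set as a cone lattice - S equal sectors
# of triangular lattice (S = 5 or 7) matched along their seams - whose
# tessellation has a single isolated non-six cell at the apex.

#' Insert a topological defect into a tissue point set
#'
#' @param tp a `tissue_points` object from [voronoi_tissue_points()].
#' @param kind `"dislocation"` (bound 5/7 pair, nonzero Burgers vector) or
#'   `"disclination"` (isolated non-six cell).
#' @param site defect position (x, y); default: centre of mass of the points.
#' @param charge for disclinations, the coordination of the apex cell
#'   (5 or 7).
#' @param jitter Gaussian positional noise (fraction of spacing) applied to
#'   the rebuilt cone lattice for disclinations; ignored for dislocations
#'   (which keep the jitter already present in `tp`).
#' @param seed RNG seed for the disclination jitter.
#' @return a modified `tissue_points` object.
#' @export
insert_defect_pair <- function(tp, kind = c("dislocation", "disclination"),
                               site = NULL, charge = 5L, jitter = 0,
                               seed = 1) {
  stopifnot(inherits(tp, "tissue_points"))
  kind <- match.arg(kind)
  pts <- tp$points
  s <- tp$spacing
  if (is.null(site)) site <- c(mean(pts[, 1]), mean(pts[, 2]))
  rng <- c(range(pts[, 1]), range(pts[, 2]))
  if (site[1] < rng[1] + 2 * s || site[1] > rng[2] - 2 * s ||
      site[2] < rng[3] + 2 * s || site[2] > rng[4] - 2 * s)
    stop("defect site too near the tissue boundary")
  if (kind == "dislocation") {
    dislocation_surgery(tp, site)
  } else {
    if (!charge %in% c(5L, 7L)) stop("disclination charge must be 5 or 7")
    cone_lattice_points(n_cells = nrow(pts), site = site, s = s,
                        sectors = as.integer(charge), jitter = jitter,
                        seed = seed)
  }
}

#' @keywords internal
dislocation_surgery <- function(tp, site, nu = 1 / 3) {
  pts <- tp$points
  s <- tp$spacing
  b <- s  # Burgers magnitude: one vertical lattice vector
  # local frame with the Burgers vector along +X: (X, Y) = (y - y0, -(x - x0))
  X <- pts[, 2] - site[2]
  Y <- -(pts[, 1] - site[1])
  r2 <- pmax(X^2 + Y^2, 1e-12)
  uX <- b / (2 * pi) * (atan2(Y, X) + X * Y / (2 * (1 - nu) * r2))
  uY <- -b / (2 * pi) * ((1 - 2 * nu) / (4 * (1 - nu)) * log(r2 / b^2) +
                           (X^2 - Y^2) / (4 * (1 - nu) * r2))
  pts2 <- pts + cbind(-uY, uX)  # rotate displacement back to the lab frame
  pts2 <- merge_close_points(pts2, 0.5 * s)
  win <- c(min(pts2[, 1]), max(pts2[, 1]), min(pts2[, 2]), max(pts2[, 2])) +
    0.55 * s * c(-1, 1, -1, 1)
  structure(list(points = pts2, spacing = s, window = win),
            class = "tissue_points")
}

# Greedy pairwise merge of points closer than `dmin` (merged pairs are
# replaced by their midpoint and not re-merged).
#' @keywords internal
merge_close_points <- function(pts, dmin) {
  dd <- as.matrix(stats::dist(pts))
  diag(dd) <- Inf
  drop <- integer(0)
  while (min(dd) < dmin) {
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    pts[ij[1], ] <- (pts[ij[1], ] + pts[ij[2], ]) / 2
    drop <- c(drop, ij[2])
    dd[c(ij[1], ij[2]), ] <- Inf
    dd[, c(ij[1], ij[2])] <- Inf
  }
  if (length(drop)) pts <- pts[-drop, , drop = FALSE]
  pts
}

# Cone lattice: S sectors of triangular lattice with sector opening 2*pi/S,
# matched along seams; ring k holds S*k points, the apex has coordination S.
#' @keywords internal
cone_lattice_points <- function(n_cells, site, s, sectors, jitter = 0,
                                seed = 1) {
  K <- 1L
  while (1 + sectors * K * (K + 1) / 2 < n_cells) K <- K + 1L
  step <- 2 * pi / sectors
  pts <- matrix(site, 1, 2, byrow = TRUE)
  for (sec in seq_len(sectors) - 1L) {
    u1 <- s * c(cos(sec * step), sin(sec * step))
    u2 <- s * c(cos((sec + 1) * step), sin((sec + 1) * step))
    for (i in seq_len(K)) {
      for (j in 0:(K - i)) {
        pts <- rbind(pts, site + i * u1 + j * u2)
      }
    }
  }
  if (jitter > 0) {
    set.seed(seed)
    pts <- pts + matrix(stats::rnorm(2 * nrow(pts), sd = jitter * s), ncol = 2)
  }
  win <- c(min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2])) +
    0.55 * s * c(-1, 1, -1, 1)
  structure(list(points = pts, spacing = s, window = win),
            class = "tissue_points")
}
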