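test_that("uniform tension and zero pressure satisfy the assembled balance", {
  mesh <- generate_hex_lattice(8, 8)
  sys <- assemble_balance_system(mesh)
  x <- c(rep(1, sys$n_edges), rep(0, sys$n_cells))
  expect_lt(max(abs(sys$A %*% x)), 1e-12)
  expect_equal(sys$n_equations, 2L * sum(!mesh$vertices$boundary))
  expect_equal(sys$n_unknowns, nrow(mesh$edges) + nrow(mesh$cells))
})

test_that("a mesh without interior vertices cannot be assembled", {
  single <- build_mesh_from_polygons(list(regular_hexagon()))
  expect_error(assemble_balance_system(single), "interior")
})

test_that("inference on a regular lattice returns the trivial solution", {
  mesh <- generate_hex_lattice(8, 8)
  sol <- infer_forces(mesh)
  use <- !sol$prior_dominated
  expect_equal(unname(sol$tension[use]), rep(1, sum(use)), tolerance = 1e-6)
  expect_equal(unname(sol$pressure), rep(0, nrow(mesh$cells)), tolerance = 1e-6)
  expect_equal(mean(sol$tension[use]), 1, tolerance = 1e-9)
  expect_equal(mean(sol$pressure), 0, tolerance = 1e-9)
})

test_that("pressure gauge: constant pressure shift lies in the null space", {
  mesh <- generate_voronoi_tissue(120, jitter = 0.2, seed = 3)
  sys <- assemble_balance_system(mesh)
  x0 <- c(stats::runif(sys$n_edges, 0.5, 1.5), stats::rnorm(sys$n_cells))
  x1 <- x0
  x1[sys$n_edges + seq_len(sys$n_cells)] <- x1[sys$n_edges + seq_len(sys$n_cells)] + 3.7
  expect_equal(as.numeric(sys$A %*% x0), as.numeric(sys$A %*% x1),
               tolerance = 1e-9)
})

test_that("inferred tensions are invariant to uniform coordinate scaling", {
  mesh <- lattice_12()
  gt <- assign_tensions(mesh, 1.3, 0.7)
  relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-6)
  sol1 <- infer_forces(relaxed, mu = 0.001)
  scaled <- hexpack:::transform_mesh(relaxed, diag(2) * 3.1)
  sol2 <- infer_forces(scaled, mu = 0.001)
  expect_equal(sol2$tension, sol1$tension, tolerance = 1e-6)
})

test_that("sparse solver matches a dense least-squares oracle", {
  mesh <- generate_hex_lattice(5, 5)  # 25 cells
  gt <- assign_tensions(mesh, 1.2, 0.8)
  relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-6)
  mu <- 0.5
  sol <- infer_forces(relaxed, mu = mu)
  sys <- assemble_balance_system(relaxed)
  E <- sys$n_edges; C <- sys$n_cells
  A <- as.matrix(sys$A)
  dP <- diag(crossprod(A))[E + seq_len(C)]
  eps0 <- 1e-8 * mean(dP)
  # stacked dense least squares: [A; sqrt(mu) I_T; sqrt(eps0) I_P]
  Astack <- rbind(
    A,
    cbind(sqrt(mu) * diag(E), matrix(0, E, C)),
    cbind(matrix(0, C, E), sqrt(eps0) * diag(C))
  )
  b <- c(rep(0, nrow(A)), rep(sqrt(mu), E), rep(0, C))
  x <- qr.solve(Astack, b)
  mT <- mean(x[seq_len(E)][!sol$prior_dominated])
  x <- x / mT
  P <- x[E + seq_len(C)]; P <- P - mean(P)
  expect_equal(sol$tension, x[seq_len(E)], tolerance = 1e-8)
  expect_equal(sol$pressure, P, tolerance = 1e-8)
})

test_that("noise-free anisotropic tensions are recovered from geometry", {
  mesh <- lattice_12()
  gt <- assign_tensions(mesh, t_ap = 1.3, t_eq = 0.7)
  relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-6)
  gt <- attr(relaxed, "ground_truth")
  sol <- infer_forces(relaxed)
  use <- !sol$prior_dominated
  expect_gte(stats::cor(sol$tension[use], gt$tension[use]), 0.9)
  expect_equal(mean(sol$tension[use]), 1, tolerance = 1e-9)
})

test_that("recovery degrades gracefully with tension noise", {
  med_cor <- vapply(c(0, 0.05, 0.1), function(cv) {
    cors <- vapply(1:5, function(s) {
      mesh <- generate_hex_lattice(10, 10)
      gt <- assign_tensions(mesh, 1.3, 0.7, noise_cv = cv, seed = s)
      relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-5,
                                        area_stiffness = if (cv > 0) 10 else 0)
      gt <- attr(relaxed, "ground_truth")
      sol <- infer_forces(relaxed)
      use <- !sol$prior_dominated
      stats::cor(sol$tension[use], gt$tension[use])
    }, numeric(1))
    stats::median(cors)
  }, numeric(1))
  expect_true(all(diff(med_cor) <= 0.02))  # non-increasing up to noise
  expect_gte(med_cor[3], 0.8)
})

test_that("orientation statistics capture tension anisotropy", {
  mesh <- lattice_12()
  gt <- assign_tensions(mesh, 1.3, 0.7)
  relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-6)
  sol <- infer_forces(relaxed)
  st <- tension_orientation_stats(sol, relaxed)
  expect_gt(st$mean_T_AP, st$mean_T_Eq)
  expect_lt(st$r_TL, 0)
  expect_equal(sum(st$polar_high$histogram$count), 2 * sum(
    st$edges$tension >= 1 & !st$edges$prior_dominated
  ))
})

test_that("uniform-tension polar distribution covers all edges", {
  mesh <- generate_hex_lattice(6, 6)
  sol <- infer_forces(mesh)
  st <- tension_orientation_stats(sol, mesh)
  use <- !sol$prior_dominated
  # all tensions equal one -> every informative edge is in the >= mean set
  expect_equal(length(st$polar_high$angles_deg), 2 * sum(use))
  expect_equal(length(st$polar_low$angles_deg), 0)
})

test_that("tiny meshes give a correlation error", {
  sq2 <- build_mesh_from_polygons(list(unit_square(), unit_square(dx = 1)))
  expect_error(infer_forces(sq2), "interior")
})
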