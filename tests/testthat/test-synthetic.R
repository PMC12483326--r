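test_that("regular hex lattice has unit edges and six neighbors everywhere inside", {
  mesh <- lattice_10()
  ic <- interior_cells(mesh)
  expect_true(all(mesh$cells$z[ic] == 6))
  int_e <- !mesh$edges$boundary
  expect_equal(unname(range(mesh$edges$length[int_e])), c(1, 1),
               tolerance = 1e-12)
})

test_that("eq_stretch sets the Eq:AP mean edge-length ratio", {
  mesh <- generate_hex_lattice(8, 8, eq_stretch = 7.9 / 4.4)
  cls <- classify_edge_orientation(mesh$edges$angle)
  int_e <- !mesh$edges$boundary
  ratio <- mean(mesh$edges$length[int_e & cls == "Eq"]) /
    mean(mesh$edges$length[int_e & cls == "AP"])
  expect_equal(ratio, 7.9 / 4.4, tolerance = 0.05)
})

test_that("lattice generator rejects bad parameters", {
  expect_error(generate_hex_lattice(2, 5), ">= 3")
  expect_error(generate_hex_lattice(5, 5, eq_stretch = 0), "positive")
  expect_error(generate_hex_lattice(5, 5, eq_stretch = -2), "positive")
})

test_that("unjittered Voronoi tissue reproduces the hexagonal lattice", {
  mesh <- generate_voronoi_tissue(200, jitter = 0)
  ic <- interior_cells(mesh)
  expect_gt(length(ic), 50)
  expect_true(all(mesh$cells$z[ic] == 6))
})

test_that("Voronoi tissues are deterministic in the seed", {
  m1 <- generate_voronoi_tissue(150, jitter = 0.5, seed = 11)
  m2 <- generate_voronoi_tissue(150, jitter = 0.5, seed = 11)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$edges, m2$edges)
  expect_identical(m1$cells, m2$cells)
  f <- mean(m1$cells$z[interior_cells(m1)] == 6)
  expect_lt(f, 1)
})

test_that("six-neighbor fraction decreases with jitter on average", {
  mean_frac <- vapply(c(0, 0.2, 0.5), function(j) {
    mean(vapply(1:20, function(s) {
      m <- generate_voronoi_tissue(150, jitter = j, seed = s)
      mean(m$cells$z[interior_cells(m)] == 6)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_frac) <= 0))
})

test_that("dislocation surgery yields exactly one adjacent 5/7 pair", {
  tp <- voronoi_tissue_points(300, jitter = 0)
  mesh <- voronoi_mesh(insert_defect_pair(tp, "dislocation"))
  clusters <- find_defect_clusters(mesh)
  expect_length(clusters, 1)
  expect_identical(cluster_signature(clusters[[1]]), "5-7")
  expect_identical(clusters[[1]]$classification, "dislocation")
})

test_that("disclination surgery yields one isolated non-six cell", {
  tp <- voronoi_tissue_points(300, jitter = 0)
  for (charge in c(5L, 7L)) {
    mesh <- voronoi_mesh(insert_defect_pair(tp, "disclination", charge = charge))
    clusters <- find_defect_clusters(mesh)
    expect_length(clusters, 1)
    expect_identical(cluster_signature(clusters[[1]]), as.character(charge))
    expect_identical(clusters[[1]]$classification, "disclination")
  }
})

test_that("defect surgery near the boundary is rejected", {
  tp <- voronoi_tissue_points(100, jitter = 0)
  corner <- c(min(tp$points[, 1]), min(tp$points[, 2]))
  expect_error(insert_defect_pair(tp, "dislocation", site = corner),
               "boundary")
})

test_that("no insertion means no defects", {
  mesh <- voronoi_mesh(voronoi_tissue_points(200, jitter = 0))
  expect_length(find_defect_clusters(mesh), 0)
})

test_that("assigned tensions satisfy the ground-truth normalisation", {
  mesh <- lattice_10()
  gt <- assign_tensions(mesh, t_ap = 1, t_eq = 1, noise_cv = 0)
  expect_true(all(gt$tension == 1))
  gt2 <- assign_tensions(mesh, t_ap = 1.3, t_eq = 0.7, noise_cv = 0)
  expect_equal(mean(gt2$tension), 1, tolerance = 1e-9)
  expect_length(unique(round(gt2$tension, 12)), 2)
  expect_true(all(gt2$tension > 0))
  expect_equal(mean(gt2$pressure), 0, tolerance = 1e-9)
  # noisy tensions stay positive and keep mean one
  gt3 <- assign_tensions(mesh, 1.3, 0.7, noise_cv = 0.3, seed = 3)
  expect_true(all(gt3$tension > 0))
  expect_equal(mean(gt3$tension), 1, tolerance = 1e-9)
})

test_that("sinusoidal tension model peaks at vertical edges", {
  mesh <- generate_voronoi_tissue(150, jitter = 0.3, seed = 2)
  gt <- assign_tensions(mesh, t_ap = 1.3, t_eq = 0.7, model = "sinusoidal")
  steepest <- which.min(abs(mesh$edges$angle - 90))
  expect_equal(which.max(gt$tension), steepest)
})

test_that("uniform tension on a regular lattice is already balanced", {
  mesh <- generate_hex_lattice(8, 8)
  gt <- assign_tensions(mesh, 1, 1)
  relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-8)
  expect_lt(attr(relaxed, "relaxation_residual"), 1e-8)
  # geometry essentially unchanged
  expect_equal(relaxed$vertices$x, mesh$vertices$x, tolerance = 1e-9)
})

test_that("anisotropic relaxation shortens the high-tension AP edges", {
  mesh <- lattice_12()
  gt <- assign_tensions(mesh, t_ap = 1.3, t_eq = 0.7)
  relaxed <- relax_to_force_balance(mesh, gt, tol = 1e-6)
  cls <- classify_edge_orientation(mesh$edges$angle)
  int_e <- !mesh$edges$boundary
  expect_lt(mean(relaxed$edges$length[int_e & cls == "AP"]),
            mean(mesh$edges$length[int_e & cls == "AP"]))
  # the relaxed geometry satisfies the assembled balance equations with the
  # ground-truth forces, at the relaxation tolerance
  gt2 <- attr(relaxed, "ground_truth")
  sys <- assemble_balance_system(relaxed)
  r <- as.numeric(sys$A %*% c(gt2$tension, gt2$pressure))
  rx <- r[seq(1, length(r), 2)]; ry <- r[seq(2, length(r), 2)]
  expect_lt(max(sqrt(rx^2 + ry^2)), 1e-6)
  expect_lt(gt2$relaxation_residual, 1e-6)
  expect_equal(mean(gt2$tension), 1, tolerance = 1e-9)
  expect_equal(mean(gt2$pressure), 0, tolerance = 1e-9)
})

test_that("degenerate relaxation tolerance is rejected", {
  mesh <- generate_hex_lattice(5, 5)
  gt <- assign_tensions(mesh, 1.2, 0.8)
  expect_error(relax_to_force_balance(mesh, gt, tol = 0), "positive")
})

test_that("identical seeds give bit-identical tensions and rasters", {
  mesh <- generate_voronoi_tissue(120, jitter = 0.2, seed = 4)
  g1 <- assign_tensions(mesh, 1.3, 0.7, noise_cv = 0.1, seed = 9)
  g2 <- assign_tensions(mesh, 1.3, 0.7, noise_cv = 0.1, seed = 9)
  expect_identical(g1$tension, g2$tension)
  i1 <- render_edge_intensity_image(mesh, g1, noise_sd = 3, seed = 5)
  i2 <- render_edge_intensity_image(mesh, g2, noise_sd = 3, seed = 5)
  expect_identical(i1, i2)
})
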