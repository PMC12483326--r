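test_that("neighbor distribution of a defect-free lattice is all six", {
  nd <- neighbor_distribution(lattice_10())
  expect_equal(unname(nd[["6"]]), 1)
  expect_equal(sum(nd), 1)
})

test_that("neighbor distribution counts an inserted disclination", {
  tp <- voronoi_tissue_points(300, jitter = 0)
  mesh <- voronoi_mesh(insert_defect_pair(tp, "disclination", charge = 5L))
  nd <- neighbor_distribution(mesh)
  n_int <- length(interior_cells(mesh))
  expect_equal(unname(nd[["5"]]), 1 / n_int)
  expect_equal(unname(nd[["6"]]), (n_int - 1) / n_int)
  expect_equal(sum(nd), 1)
})

test_that("neighbor distribution errors on an interior-free mesh", {
  single <- build_mesh_from_polygons(list(regular_hexagon()))
  expect_error(neighbor_distribution(single), "interior")
})

test_that("cluster classification follows the mean-coordination/Burgers rule", {
  mk <- function(z, burgers) {
    structure(list(members = seq_along(z), z = z, z_sum = sum(z),
                   mean_z = mean(z), burgers = burgers, truncated = FALSE,
                   classification = NA_character_),
              class = "defect_cluster")
  }
  out <- classify_clusters(list(
    mk(c(5L, 7L), c(1.2, 0)),        # bound pair, nonzero Burgers
    mk(5L, c(0, 0)),                 # isolated five
    mk(7L, c(0, 0)),                 # isolated seven
    mk(c(5L, 7L, 7L, 5L), c(0, 0)),  # balanced chain, cancelling Burgers
    mk(c(4L, 8L), c(0, 0))           # balanced but exotic: neutral by rule
  ))
  expect_identical(
    vapply(out, function(cl) cl$classification, ""),
    c("dislocation", "disclination", "disclination", "neutral", "neutral")
  )
})

test_that("defect frequencies count member cells over interior cells", {
  mesh0 <- voronoi_mesh(voronoi_tissue_points(200, jitter = 0))
  f0 <- defect_frequencies(mesh0)
  expect_equal(f0$dislocation_fraction, 0)
  expect_equal(f0$disclination_fraction, 0)

  tp <- voronoi_tissue_points(300, jitter = 0)
  mesh1 <- voronoi_mesh(insert_defect_pair(tp, "dislocation"))
  f1 <- defect_frequencies(mesh1)
  n_int <- length(interior_cells(mesh1))
  expect_equal(f1$dislocation_fraction, 2 / n_int)
  expect_equal(f1$disclination_fraction, 0)

  mesh2 <- voronoi_mesh(insert_defect_pair(tp, "disclination", charge = 7L))
  f2 <- defect_frequencies(mesh2)
  expect_equal(f2$disclination_fraction, 1 / length(interior_cells(mesh2)))
})

test_that("class fractions and six fraction partition the interior", {
  mesh <- generate_voronoi_tissue(250, jitter = 0.35, seed = 6)
  f <- defect_frequencies(mesh)
  nd <- neighbor_distribution(mesh)
  expect_equal(
    f$dislocation_fraction + f$disclination_fraction + f$neutral_fraction +
      unname(nd[["6"]]),
    1,
    tolerance = 1e-12
  )
})

test_that("classification is rotation-invariant and Burgers rotates covariantly", {
  tp <- voronoi_tissue_points(300, jitter = 0)
  mesh <- voronoi_mesh(insert_defect_pair(tp, "dislocation"))
  cl <- find_defect_clusters(mesh)[[1]]
  th <- 90 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotated <- hexpack:::transform_mesh(mesh, R)
  # augmented Voronoi boundary flags are carried by the cells table already
  cl_rot <- find_defect_clusters(rotated)[[1]]
  expect_identical(cl_rot$classification, cl$classification)
  expect_equal(cl_rot$burgers, as.numeric(R %*% cl$burgers), tolerance = 1e-9)
})

test_that("defect cluster table has one row per cluster", {
  mesh <- generate_voronoi_tissue(250, jitter = 0.4, seed = 3)
  clusters <- find_defect_clusters(mesh)
  tab <- defect_cluster_table(clusters)
  expect_equal(nrow(tab), length(clusters))
  expect_true(all(tab$classification %in% c("dislocation", "disclination", "neutral")))
  expect_equal(nrow(defect_cluster_table(list())), 0)
})
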