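test_that("two labels split by a straight line give one interior edge", {
  lab <- matrix(0L, 40, 61)
  lab[2:39, 2:30] <- 1L
  lab[2:39, 32:60] <- 2L
  mesh <- extract_mesh_from_labels(lab, pixel_size = 0.5)
  int_e <- which(!mesh$edges$boundary)
  expect_length(int_e, 1)
  # divider is 38 px tall; polyline length within 2 px * pixel_size
  expect_equal(mesh$edges$length[int_e], 38 * 0.5, tolerance = 2 * 0.5 / (38 * 0.5))
  expect_equal(mesh$cells$z, c(1L, 1L))
  expect_true(all(mesh$cells$boundary))
})

test_that("empty and malformed label images are rejected", {
  expect_error(extract_mesh_from_labels(matrix(0L, 10, 10)), "background")
  split_lab <- matrix(0L, 20, 20)
  split_lab[2:8, 2:18] <- 1L
  split_lab[12:18, 2:18] <- 1L  # label 1 in two disconnected pieces
  expect_error(extract_mesh_from_labels(split_lab), "connected")
  expect_error(extract_mesh_from_labels(matrix(-1L, 3, 3)), "non-negative")
})

test_that("labels below the size threshold are excluded with a warning", {
  lab <- matrix(0L, 40, 61)
  lab[2:39, 2:30] <- 1L
  lab[2:39, 32:60] <- 2L
  lab[20, 31] <- 3L  # single stray pixel
  expect_warning(mesh <- extract_mesh_from_labels(lab, pixel_size = 1),
                 "fewer than")
  expect_equal(nrow(mesh$cells), 2)
})

test_that("render/extract round trip recovers lattice neighbor counts", {
  mesh <- generate_hex_lattice(8, 8)
  img <- render_label_image(mesh, px_per_um = 8)
  extracted <- extract_mesh_from_labels(img, pixel_size = attr(img, "pixel_size"))
  expect_gte(round_trip_z_agreement(mesh, img, extracted), 0.99)
  expect_silent(validate_mesh(extracted))
})

test_that("extraction is deterministic", {
  mesh <- generate_hex_lattice(5, 5)
  img <- render_label_image(mesh, px_per_um = 8)
  e1 <- extract_mesh_from_labels(img, pixel_size = attr(img, "pixel_size"))
  e2 <- extract_mesh_from_labels(img, pixel_size = attr(img, "pixel_size"))
  expect_identical(e1$vertices, e2$vertices)
  expect_identical(e1$edges$length, e2$edges$length)
  expect_identical(e1$cells, e2$cells)
})

test_that("region adjacency equals edge-sharing adjacency on extracted meshes", {
  mesh <- generate_hex_lattice(6, 6)
  img <- render_label_image(mesh, px_per_um = 8)
  ex <- extract_mesh_from_labels(img, pixel_size = attr(img, "pixel_size"))
  for (i in ex$cells$id) {
    nb_from_edges <- sort(unique(stats::na.omit(unlist(lapply(
      ex$cell_edges[[i]],
      function(e) setdiff(c(ex$edges$cell1[e], ex$edges$cell2[e]), i)
    )))))
    expect_identical(ex$neighbors[[i]], as.integer(nb_from_edges))
  }
})
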