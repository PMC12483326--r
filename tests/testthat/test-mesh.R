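test_that("two unit squares sharing a side form one interior edge", {
  mesh <- build_mesh_from_polygons(list(unit_square(), unit_square(dx = 1)))
  expect_equal(sum(!mesh$edges$boundary), 1)
  expect_equal(mesh$cells$z, c(1, 1))
  expect_true(all(mesh$cells$boundary))
  expect_silent(validate_mesh(mesh))
})

test_that("a single polygon yields a boundary-only mesh", {
  mesh <- build_mesh_from_polygons(list(regular_hexagon()))
  expect_equal(sum(!mesh$edges$boundary), 0)
  expect_equal(mesh$cells$z, 0)
  expect_true(mesh$cells$boundary)
  expect_length(interior_cells(mesh), 0)
})

test_that("degenerate and overlapping polygons are rejected", {
  line <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(build_mesh_from_polygons(list(line)), "degenerate")
  # three polygons sharing one edge: impossible planar topology
  sq <- unit_square()
  expect_error(
    build_mesh_from_polygons(list(sq, sq + cbind(rep(1, 4), 0),
                                  sq + cbind(rep(1, 4), 0))),
    "topology|twice"
  )
})

test_that("hex lattice interior cells all have six neighbors", {
  mesh <- lattice_10()
  ic <- interior_cells(mesh)
  expect_length(ic, 64)  # 8x8 interior block of a 10x10 lattice
  expect_true(all(mesh$cells$z[ic] == 6))
  expect_silent(validate_mesh(mesh))
})

test_that("edge length is symmetric between its two adjacent cells", {
  mesh <- lattice_10()
  int_e <- which(!mesh$edges$boundary)
  for (e in int_e[1:20]) {
    a <- mesh$edges$cell1[e]; b <- mesh$edges$cell2[e]
    ea <- mesh$cell_edges[[a]]; eb <- mesh$cell_edges[[b]]
    expect_true(e %in% ea && e %in% eb)
    expect_identical(mesh$edges$length[ea[ea == e]],
                     mesh$edges$length[eb[eb == e]])
  }
})

test_that("mesh JSON writer round-trips to an identical mesh", {
  mesh <- generate_hex_lattice(6, 6, eq_stretch = 1.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_mesh_json(mesh, path)
  back <- read_mesh_json(path)
  for (nm in names(mesh)) {
    expect_true(isTRUE(all.equal(mesh[[nm]], back[[nm]], tolerance = 0)),
                label = sprintf("component %s identical", nm))
  }
})

test_that("raster mesh JSON round trip preserves polylines and geometry", {
  mesh <- generate_hex_lattice(4, 4)
  img <- render_label_image(mesh, px_per_um = 8)
  mx <- extract_mesh_from_labels(img, pixel_size = attr(img, "pixel_size"))
  path <- withr::local_tempfile(fileext = ".json")
  write_mesh_json(mx, path)
  back <- read_mesh_json(path)
  expect_equal(back$edges$length, mx$edges$length, tolerance = 0)
  expect_equal(back$cells$area, mx$cells$area, tolerance = 0)
  expect_identical(back$cells$z, mx$cells$z)
})

test_that("cell and edge tables export one row per element", {
  mesh <- lattice_10()
  expect_equal(nrow(mesh_cell_table(mesh)), nrow(mesh$cells))
  expect_equal(nrow(mesh_edge_table(mesh)), nrow(mesh$edges))
})
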