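test_that("uniform-intensity image gives ratio one for every cell", {
  mesh <- generate_hex_lattice(6, 6)
  gt <- assign_tensions(mesh, intensity_levels = c(AP = 150, Eq = 150))
  img <- render_edge_intensity_image(mesh, gt, px_per_um = 8, noise_sd = 0)
  res <- edge_intensity_ratio(img, mesh)
  expect_equal(res$tissue_ratio, 1, tolerance = 0.02)
  expect_equal(res$n_excluded, 0)
})

test_that("a two-fold AP enrichment is recovered as ratio two", {
  mesh <- generate_hex_lattice(6, 6)
  gt <- assign_tensions(mesh, intensity_levels = c(AP = 200, Eq = 100))
  img <- render_edge_intensity_image(mesh, gt, px_per_um = 8, noise_sd = 0)
  res <- edge_intensity_ratio(img, mesh)
  expect_equal(res$tissue_ratio, 2, tolerance = 0.05)
})

test_that("the 1.19-fold control-like preset is recovered under noise", {
  mesh <- generate_hex_lattice(6, 6)
  gt <- assign_tensions(mesh, intensity_levels = c(AP = 119, Eq = 100))
  img <- render_edge_intensity_image(mesh, gt, px_per_um = 8, noise_sd = 5,
                                     seed = 2)
  res <- edge_intensity_ratio(img, mesh)
  expect_equal(res$tissue_ratio, 1.19, tolerance = 0.05)
})

test_that("ratio is invariant to multiplying the image by a constant", {
  mesh <- generate_hex_lattice(5, 5)
  gt <- assign_tensions(mesh, intensity_levels = c(AP = 180, Eq = 90))
  img <- render_edge_intensity_image(mesh, gt, px_per_um = 8, noise_sd = 1,
                                     seed = 7)
  r1 <- edge_intensity_ratio(img, mesh)$tissue_ratio
  img4 <- img * 4.2
  attributes(img4) <- attributes(img)
  r2 <- edge_intensity_ratio(img4, mesh)$tissue_ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("mean gray values reproduce the rendered class levels", {
  mesh <- generate_hex_lattice(6, 6)
  gt <- assign_tensions(mesh, intensity_levels = c(AP = 200, Eq = 100))
  img <- render_edge_intensity_image(mesh, gt, px_per_um = 8, noise_sd = 0)
  mfi <- edge_mfi(img, mesh)
  ap <- mfi$edges$mean_gray[mfi$edges$class == "AP"]
  eq <- mfi$edges$mean_gray[mfi$edges$class == "Eq"]
  expect_equal(mean(ap), 200, tolerance = 1e-9)
  expect_equal(mean(eq), 100, tolerance = 1e-9)
})

test_that("a constant image has constant mean gray everywhere", {
  mesh <- generate_hex_lattice(5, 5)
  gt <- assign_tensions(mesh)
  tmpl <- render_edge_intensity_image(mesh, gt, px_per_um = 8)
  img <- matrix(7, nrow(tmpl), ncol(tmpl))
  attributes(img) <- attributes(tmpl)
  mfi <- edge_mfi(img, mesh)
  expect_true(all(abs(mfi$edges$mean_gray - 7) < 1e-12))
  expect_equal(mfi$image_mfi, 7)
})

test_that("meshes outside the image frame are rejected", {
  mesh <- generate_hex_lattice(5, 5)
  img <- matrix(1, 5, 5)  # far too small for the mesh extent
  expect_error(edge_intensity_records(img, mesh), "pixel size|bounds")
  attr(img, "pixel_size") <- 1
  expect_error(edge_intensity_records(img, mesh), "bounds")
})

test_that("doubling the stroke width changes the estimate only mildly", {
  mesh <- generate_hex_lattice(6, 6, edge_len = 2)
  gt <- assign_tensions(mesh, intensity_levels = c(AP = 160, Eq = 80))
  img <- render_edge_intensity_image(mesh, gt, px_per_um = 8,
                                     line_width_px = 8, noise_sd = 0)
  r3 <- edge_intensity_records(img, mesh, line_width_px = 3)
  r6 <- edge_intensity_records(img, mesh, line_width_px = 6)
  rel <- abs(r6$normalized_intensity / 2 - r3$normalized_intensity) /
    r3$normalized_intensity
  expect_lt(stats::median(rel, na.rm = TRUE), 0.05)
})

test_that("ROI morphometrics follow the stated arithmetic", {
  expect_equal(cell_area_from_roi(10000, 100), 100)
  expect_equal(cell_density_from_roi(100, 10000), 10)
  # algebraic identity: area x density = 1000 for any valid input
  for (n in c(37, 91, 200)) {
    expect_equal(cell_area_from_roi(9109.6, n) * cell_density_from_roi(n, 9109.6),
                 1000, tolerance = 1e-12)
  }
  expect_error(cell_area_from_roi(9109.6, 0), ">= 1")
  expect_error(cell_density_from_roi(10, -5), "positive")
})
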