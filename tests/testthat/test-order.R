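# Independent brute-force oracle: psi_n from an explicit list of neighbor
# angles, written without any mesh machinery.
psi_oracle <- function(angles_deg, n) {
  mean(exp(1i * n * angles_deg * pi / 180))
}

test_that("psi agrees with the brute-force oracle on canonical neighbor sets", {
  expect_equal(Mod(psi_oracle(seq(0, 300, by = 60), 6)), 1, tolerance = 1e-12)
  expect_equal(Mod(psi_oracle(c(0, 90), 6)), 0, tolerance = 1e-12)
  expect_equal(Mod(psi_oracle(seq(0, 288, by = 72), 6)), 0, tolerance = 1e-12)
  expect_equal(psi_oracle(c(0, 180), 2), 1 + 0i, tolerance = 1e-12)
})

test_that("per-cell psi matches the oracle computed from raw centroids", {
  mesh <- lattice_10()
  ic <- interior_cells(mesh)
  for (j in ic[c(1, 10, 30)]) {
    nb <- mesh$neighbors[[j]]
    ang <- atan2(mesh$cells$y[nb] - mesh$cells$y[j],
                 mesh$cells$x[nb] - mesh$cells$x[j]) * 180 / pi
    for (n in c(2, 6)) {
      expect_equal(psi_n_cell(mesh, j, n), psi_oracle(ang, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("defect-free lattice has full hexatic and no nematic order", {
  mesh <- lattice_10()
  expect_equal(global_psi_n(mesh, 6), 1, tolerance = 1e-12)
  # brute-force check of the nematic cancellation over all interior cells
  ic <- interior_cells(mesh)
  acc <- 0i
  for (j in ic) {
    nb <- mesh$neighbors[[j]]
    ang <- atan2(mesh$cells$y[nb] - mesh$cells$y[j],
                 mesh$cells$x[nb] - mesh$cells$x[j]) * 180 / pi
    acc <- acc + psi_oracle(ang, 2)
  }
  expect_equal(global_psi_n(mesh, 2), Mod(acc / length(ic)), tolerance = 1e-12)
  expect_lt(global_psi_n(mesh, 2), 1e-10)
})

test_that("psi of an isolated cell is missing, not zero", {
  mesh <- build_mesh_from_polygons(list(regular_hexagon()))
  expect_true(is.na(psi_n_cell(mesh, 1, 6)))
  expect_error(global_psi_n(mesh, 6), "interior|defined")
})

test_that("|psi6| is six-fold rotation covariant and psi2 two-fold", {
  mesh <- generate_voronoi_tissue(150, jitter = 0.3, seed = 8)
  rot <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  }
  m60 <- hexpack:::transform_mesh(mesh, rot(60))
  m180 <- hexpack:::transform_mesh(mesh, rot(180))
  ic <- interior_cells(mesh)
  expect_equal(Mod(psi_n_cell(m60, ic, 6)), Mod(psi_n_cell(mesh, ic, 6)),
               tolerance = 1e-9)
  expect_equal(psi_n_cell(m180, ic, 2), psi_n_cell(mesh, ic, 2),
               tolerance = 1e-9)
})

test_that("global hexatic order decreases with jitter in the mean", {
  psis <- vapply(c(0, 0.15, 0.35), function(j) {
    mean(vapply(1:20, function(s) {
      global_psi_n(generate_voronoi_tissue(150, jitter = j, seed = s), 6)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(psis) < 0))
})

test_that("shape tensor gives canonical anisotropy ratios", {
  hexm <- build_mesh_from_polygons(list(regular_hexagon()))
  expect_equal(anisotropy_ratio(hexm, 1), 1, tolerance = 1e-12)
  sq <- build_mesh_from_polygons(list(unit_square()))
  expect_equal(anisotropy_ratio(sq, 1), 1, tolerance = 1e-12)
  rect <- build_mesh_from_polygons(list(cbind(c(0, 1, 1, 0), c(0, 0, 2, 2))))
  expect_equal(anisotropy_ratio(rect, 1), 2, tolerance = 1e-12)
  s <- shape_tensor(hexm, 1)
  expect_equal(s[1, 2], s[2, 1])
  expect_gt(s[1, 1] + s[2, 2], 0)
  # trace identity for length weighting: perimeter / area
  expect_equal(s[1, 1] + s[2, 2], 6 / hexm$cells$area[1], tolerance = 1e-12)
})

test_that("anisotropy grows strictly with vertical stretching", {
  ratios <- vapply(c(1, 1.3, 1.7, 2.4), function(k) {
    ring <- regular_hexagon()
    ring[, 2] <- ring[, 2] * k
    anisotropy_ratio(build_mesh_from_polygons(list(ring)), 1)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("edge orientation classifier follows the 45-degree convention", {
  expect_identical(classify_edge_orientation(0), "Eq")
  expect_identical(classify_edge_orientation(60), "AP")
  expect_identical(classify_edge_orientation(45), "Eq")   # tie -> Eq
  expect_identical(classify_edge_orientation(135), "Eq")  # 180 - 135 = 45
  expect_identical(classify_edge_orientation(90), "AP")
  expect_error(classify_edge_orientation(NaN), "angle")
})

test_that("flat-top hexagon counts 4 AP and 2 Eq edges", {
  mesh <- build_mesh_from_polygons(list(regular_hexagon()))
  counts <- ap_eq_counts(mesh, 1)
  expect_equal(counts$nAP, 4)
  expect_equal(counts$nEq, 2)
  expect_equal(counts$ratio, 2)
})

test_that("rotating the tissue by 90 degrees swaps AP and Eq edge totals", {
  # lattice edges sit at 0, 60 and 120 degrees; rotation by 90 maps them to
  # 90, 150 and 30, so the class totals must swap exactly
  mesh <- lattice_10()
  rot <- hexpack:::transform_mesh(mesh, matrix(c(0, 1, -1, 0), 2, 2))
  cls0 <- classify_edge_orientation(mesh$edges$angle)
  cls90 <- classify_edge_orientation(rot$edges$angle)
  expect_equal(sum(cls90 == "AP"), sum(cls0 == "Eq"))
  expect_equal(sum(cls90 == "Eq"), sum(cls0 == "AP"))
})

test_that("edge length statistics follow the stretched-lattice geometry", {
  mesh <- generate_hex_lattice(8, 8, eq_stretch = 1.8)
  els <- edge_length_stats(mesh)
  expect_lt(els$length_ratio, 1)      # AP edges shorter than Eq
  expect_lt(els$mean_cell_ratio, 1)
  expect_equal(els$n_cells_excluded, 0)
})

test_that("order summary reports per-cell rows and sane global values", {
  mesh <- generate_voronoi_tissue(150, jitter = 0.25, seed = 9)
  os <- order_summary(mesh)
  expect_equal(nrow(os$cells), nrow(mesh$cells))
  expect_true(all(os$cells$psi6_abs <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(os$cells$psi2_abs <= 1 + 1e-12, na.rm = TRUE))
  expect_gte(os$tissue$Psi6, 0); expect_lte(os$tissue$Psi6, 1)
  expect_gte(os$tissue$Psi2, 0); expect_lte(os$tissue$Psi2, 1)
  expect_type(os$tissue$crystal, "logical")
})
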