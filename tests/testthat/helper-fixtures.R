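# Shared fixtures and small utilities. Everything is built in code;
# moderately expensive meshes are memoised per test run.

local_fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(local_fixture_env[[name]])) {
    local_fixture_env[[name]] <- build()
  }
  local_fixture_env[[name]]
}

lattice_10 <- function() fixture("lattice_10", function() generate_hex_lattice(10, 10))
lattice_12 <- function() fixture("lattice_12", function() generate_hex_lattice(12, 12))

unit_square <- function(dx = 0, dy = 0) {
  cbind(c(0, 1, 1, 0) + dx, c(0, 0, 1, 1) + dy)
}

regular_hexagon <- function(edge = 1) {
  # flat-top: two horizontal edges, vertices at 0, 60, ..., 300 degrees
  th <- (0:5) * pi / 3
  cbind(edge * cos(th), edge * sin(th))
}

# signature string of a defect cluster, e.g. "5-7"
cluster_signature <- function(cl) paste(sort(cl$z), collapse = "-")

# match interior cells of a generator mesh to extracted-mesh cells by
# centroid and report the fraction with identical neighbor counts
round_trip_z_agreement <- function(mesh, label_img, extracted) {
  ps <- attr(label_img, "pixel_size")
  offx <- attr(label_img, "xmin")
  offy <- attr(label_img, "ymax") - nrow(label_img) * ps
  ic <- interior_cells(mesh)
  agree <- vapply(ic, function(j) {
    d2 <- (extracted$cells$x + offx - mesh$cells$x[j])^2 +
      (extracted$cells$y + offy - mesh$cells$y[j])^2
    extracted$cells$z[which.min(d2)] == mesh$cells$z[j]
  }, logical(1))
  mean(agree)
}
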