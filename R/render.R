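# Raster rendering of synthetic tissues: integer label images (one positive
# label per cell, one-pixel boundaries of 0) and edge-intensity images
# (junctional-marker mimics: each edge drawn at its orientation class's
# intensity level over a dark background, plus Gaussian noise).
#
# Raster convention: row 1 is the top of the image; pixel (r, c) has centre
# (x, y) = (xmin + (c - 0.5) * ps, ymax - (r - 0.5) * ps) in micrometres,
# so the mathematical y-up frame is restored at load time.

#' @keywords internal
raster_canvas <- function(mesh, px_per_um, pad_px = 2L) {
  ps <- 1 / px_per_um
  xmin <- min(mesh$vertices$x) - pad_px * ps
  ymax <- max(mesh$vertices$y) + pad_px * ps
  nc <- ceiling((max(mesh$vertices$x) - xmin) * px_per_um) + pad_px
  nr <- ceiling((ymax - min(mesh$vertices$y)) * px_per_um) + pad_px
  list(xmin = xmin, ymax = ymax, nrow = as.integer(nr), ncol = as.integer(nc),
       pixel_size = ps)
}

#' @keywords internal
px_center_xy <- function(canvas, r, c) {
  cbind(canvas$xmin + (c - 0.5) * canvas$pixel_size,
        canvas$ymax - (r - 0.5) * canvas$pixel_size)
}

#' Render a label image of a tissue
#'
#' Scanline-fills every cell polygon with a unique positive integer label,
#' then overdraws all edges as one-pixel boundaries of value 0.
#'
#' @param mesh a `tissue_mesh`.
#' @param px_per_um raster resolution in pixels per micrometre (>= 2).
#' @return integer matrix (rows = image rows, top first) with attributes
#'   `pixel_size` (µm/px), `xmin`, `ymax` (µm coordinates of the canvas).
#'   Cells too small to render (< 9 px) trigger a warning.
#' @export
render_label_image <- function(mesh, px_per_um = 8) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (px_per_um < 2) stop("px_per_um must be >= 2")
  cv <- raster_canvas(mesh, px_per_um)
  img <- matrix(0L, cv$nrow, cv$ncol)
  ps <- cv$pixel_size
  for (ci in mesh$cells$id) {
    vs <- mesh$cell_vertices[[ci]]
    px <- mesh$vertices$x[vs]; py <- mesh$vertices$y[vs]
    r_lo <- max(1L, floor((cv$ymax - max(py)) / ps) + 1L)
    r_hi <- min(cv$nrow, ceiling((cv$ymax - min(py)) / ps))
    nxt <- c(seq_along(vs)[-1], 1L)
    for (r in r_lo:r_hi) {
      y <- cv$ymax - (r - 0.5) * ps
      # even-odd crossing x positions
      cross <- numeric(0)
      for (k in seq_along(vs)) {
        y1 <- py[k]; y2 <- py[nxt[k]]
        if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
          t <- (y - y1) / (y2 - y1)
          cross <- c(cross, px[k] + t * (px[nxt[k]] - px[k]))
        }
      }
      cross <- sort(cross)
      for (k in seq_len(length(cross) %/% 2)) {
        c_lo <- ceiling((cross[2 * k - 1] - cv$xmin) / ps + 0.5)
        c_hi <- floor((cross[2 * k] - cv$xmin) / ps + 0.5)
        if (c_hi >= c_lo)
          img[r, max(1L, c_lo):min(cv$ncol, c_hi)] <- ci
      }
    }
  }
  # one-pixel boundaries of 0: carve the midline wherever two labels touch
  # (deterministic, stays exactly one pixel wide along the pixel grid)
  right <- cbind(img[, -1], 0L)
  down <- rbind(img[-1, ], 0L)
  carve <- (img > 0 & right > 0 & img != right) |
    (img > 0 & down > 0 & img != down)
  img[carve] <- 0L
  counts <- tabulate(img[img > 0], nbins = nrow(mesh$cells))
  if (any(counts < 9))
    warning(sprintf("%d cell(s) rendered with fewer than 9 pixels; increase px_per_um",
                    sum(counts < 9)))
  attr(img, "pixel_size") <- ps
  attr(img, "xmin") <- cv$xmin
  attr(img, "ymax") <- cv$ymax
  img
}

#' Render an edge-intensity image of a tissue
#'
#' Draws every edge at the intensity level of its orientation class
#' (`ground_truth$intensity_levels[c("AP", "Eq")]`) with the given line
#' width over a dark background, then adds Gaussian noise and clips at zero.
#' Where strokes overlap (near vertices) the brighter value wins.
#'
#' @param mesh a `tissue_mesh`.
#' @param ground_truth a `ground_truth` carrying `intensity_levels`.
#' @param px_per_um raster resolution (pixels per micrometre, >= 2).
#' @param line_width_px stroke width in pixels.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param seed RNG seed for the noise.
#' @param background background level (a.u.).
#' @return numeric matrix with the same coordinate attributes as
#'   [render_label_image()].
#' @export
render_edge_intensity_image <- function(mesh, ground_truth, px_per_um = 8,
                                        line_width_px = 3, noise_sd = 0,
                                        seed = 1, background = 0) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(ground_truth, "ground_truth"))
  if (px_per_um < 2) stop("px_per_um must be >= 2")
  lv <- ground_truth$intensity_levels
  if (is.null(names(lv)) || !all(c("AP", "Eq") %in% names(lv)))
    stop("ground_truth$intensity_levels must be named with AP and Eq")
  cv <- raster_canvas(mesh, px_per_um)
  img <- matrix(background, cv$nrow, cv$ncol)
  ps <- cv$pixel_size
  cls <- classify_edge_orientation(mesh$edges$angle)
  half_w <- line_width_px / 2
  for (e in seq_len(nrow(mesh$edges))) {
    a <- mesh$edges$v1[e]; b <- mesh$edges$v2[e]
    level <- lv[[cls[e]]]
    # pixel-space segment
    r0 <- (cv$ymax - mesh$vertices$y[a]) / ps + 0.5
    c0 <- (mesh$vertices$x[a] - cv$xmin) / ps + 0.5
    r1 <- (cv$ymax - mesh$vertices$y[b]) / ps + 0.5
    c1 <- (mesh$vertices$x[b] - cv$xmin) / ps + 0.5
    rlo <- max(1L, floor(min(r0, r1) - half_w - 1))
    rhi <- min(cv$nrow, ceiling(max(r0, r1) + half_w + 1))
    clo <- max(1L, floor(min(c0, c1) - half_w - 1))
    chi <- min(cv$ncol, ceiling(max(c0, c1) + half_w + 1))
    if (rlo > rhi || clo > chi) next
    rr <- rlo:rhi; cc <- clo:chi
    Rm <- matrix(rr, length(rr), length(cc))
    Cm <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    vx <- r1 - r0; vy <- c1 - c0
    L2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((Rm - r0) * vx + (Cm - c0) * vy) / L2))
    d <- sqrt((Rm - r0 - t * vx)^2 + (Cm - c0 - t * vy)^2)
    hit <- d <= half_w
    sub <- img[rr, cc]
    sub[hit] <- pmax(sub[hit], level)
    img[rr, cc] <- sub
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd), nrow(img))
    img[img < 0] <- 0
  }
  attr(img, "pixel_size") <- ps
  attr(img, "xmin") <- cv$xmin
  attr(img, "ymax") <- cv$ymax
  img
}

#' Read and write label / intensity rasters
#'
#' Label images are written as unsigned 16-bit TIFF or PNG (by file
#' extension); intensity images as 32-bit float TIFF. Readers return plain
#' matrices.
#'
#' @param img matrix to write.
#' @param path file path (`.tif`/`.tiff` or `.png` for labels).
#' @return `read_*`: a matrix; `write_*`: `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  if (max(img) > 65535L) stop("labels exceed 16-bit range")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    # 16-bit labels across two 8-bit channels (high byte in red, low in
    # green); lossless and readable by any PNG reader
    hi <- img %/% 256L
    lo <- img %% 256L
    arr <- array(0, dim = c(nrow(img), ncol(img), 3))
    arr[, , 1] <- hi / 255
    arr[, , 2] <- lo / 255
    png::writePNG(arr, path)
  } else {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) {
      out <- round(m[, , 1] * 255) * 256L + round(m[, , 2] * 255)
    } else {
      out <- round(m * 65535)
    }
  } else {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    out <- round(m * 65535)
  }
  matrix(as.integer(out), nrow(out), ncol(out))
}

# intensity rasters are stored as 16-bit TIFF over a fixed 0..65535 range
# (values are arbitrary units; relative precision ~1.5e-5 of full scale)
#' @rdname write_label_image
#' @export
write_intensity_image <- function(img, path) {
  if (min(img) < 0 || max(img) > 65535)
    stop("intensity values must lie in [0, 65535]")
  tiff::writeTIFF(matrix(round(as.numeric(img)) / 65535, nrow(img)), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_intensity_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * 65535
}
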