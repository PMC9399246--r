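#' Volumetric scalar grid
#'
#' Container for a 3D scalar field (HU for CT, arbitrary density for
#' phantoms). Axis convention throughout the package: array axis 1 is
#' anterior--posterior (anterior at index 1; frontal rays travel toward
#' increasing index), axis 2 left--right, axis 3 cranio--caudal.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param axis_convention character length-3 naming the anatomical meaning of
#'   each array axis.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values,
                        spacing = c(1, 1, 1),
                        axis_convention = c("anterior_posterior", "left_right",
                                            "cranio_caudal")) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_named("anoscore_invalid_spacing", "spacing components must be strictly positive")
  }
  if (length(axis_convention) != 3) stop("axis_convention must name all three axes")
  structure(list(values = values, spacing = spacing,
                 axis_convention = axis_convention),
            class = "volume_grid")
}

#' Write / read a volume as raw binary with a JSON sidecar
#'
#' The voxel data are stored as little-endian float64 in column-major order;
#' the sidecar records dimensions, spacing and the axis convention so the
#' container round-trips exactly.
#'
#' @param volume a [volume_grid()].
#' @param prefix path prefix; writes `<prefix>.raw` and `<prefix>.json`.
#' @return `write_volume` invisibly returns `prefix`; `read_volume` returns a
#'   [volume_grid()].
#' @export
write_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "volume_grid"))
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(volume$values), con, size = 8, endian = "little")
  jsonlite::write_json(list(dim = dim(volume$values), spacing = volume$spacing,
                            axis_convention = volume$axis_convention),
                       paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dm <- as.integer(meta$dim)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(dm), size = 8, endian = "little")
  volume_grid(array(vals, dim = dm), spacing = meta$spacing,
              axis_convention = meta$axis_convention)
}

#' Load a CT DICOM series as a volume
#'
#' Reads one axial CT series from a directory, sorts slices by position,
#' applies the rescale slope/intercept so values are Hounsfield units, and
#' validates that geometry attributes are consistent across slices. Parsing
#' is delegated to the Python `pydicom` library through a bundled script
#' (`python` must be on the PATH); the array is re-oriented so that axis 1 is
#' anterior--posterior with anterior at index 1.
#'
#' @param path directory containing the DICOM files of a single series.
#' @return A [volume_grid()] in Hounsfield units.
#' @export
load_dicom_series <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  script <- system.file("python", "dicom_to_raw.py", package = "anoscore")
  if (script == "") stop("bundled dicom_to_raw.py not found")
  prefix <- tempfile("dicomvol")
  res <- suppressWarnings(
    system2("python", c(shQuote(script), shQuote(path), shQuote(prefix)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(res, "status") %||% 0L
  if (status != 0) {
    stop_named("anoscore_dicom_error", paste(res, collapse = "\n"))
  }
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dm <- as.integer(meta$dim)  # (rows=AP, cols=LR, slices=CC)
  con <- file(paste0(prefix, ".raw"), "rb")
  vals <- readBin(con, "double", n = prod(dm), size = 4, endian = "little")
  close(con)
  unlink(paste0(prefix, c(".raw", ".json")))
  volume_grid(array(vals, dim = dm), spacing = as.numeric(meta$spacing),
              axis_convention = c("anterior_posterior", "left_right",
                                  "cranio_caudal"))
}

# ---- isosurface extraction (marching tetrahedra) ---------------------------

#' Extract a triangulated isosurface from a volume
#'
#' Piecewise-linear isosurface at `iso_level` by marching tetrahedra: each
#' grid cell is split into six tetrahedra sharing the main diagonal (a
#' decomposition whose face diagonals match across neighbouring cells, so the
#' surface is crack-free), and crossing edges are linearly interpolated.
#' Vertices are returned in mm via the voxel spacing. Shared vertices are not
#' merged; faces index the vertex list directly.
#'
#' @param volume a [volume_grid()].
#' @param iso_level scalar threshold; must lie strictly inside the volume's
#'   value range.
#' @return An object of class `surface_mesh` with `vertices` (N x 3 mm),
#'   `faces` (M x 3 integer) and `iso_level`.
#' @export
extract_isosurface <- function(volume, iso_level) {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$values
  rng <- range(v)
  if (!(iso_level > rng[1] && iso_level < rng[2])) {
    stop_named("anoscore_no_crossing",
               sprintf("iso_level %g does not cross the volume (value range [%g, %g])",
                       iso_level, rng[1], rng[2]))
  }
  dm <- dim(v)
  n0 <- dm[1]; n1 <- dm[2]; n2 <- dm[3]
  sp <- volume$spacing

  # corner offsets of the unit cell, standard numbering
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  # six tetrahedra sharing the diagonal corner1--corner7
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

  # linear indices of cell origins
  oi <- rep(seq_len(n0 - 1), times = (n1 - 1) * (n2 - 1))
  oj <- rep(rep(seq_len(n1 - 1), each = n0 - 1), times = n2 - 1)
  ok <- rep(seq_len(n2 - 1), each = (n0 - 1) * (n1 - 1))
  corner_lin <- matrix(0L, length(oi), 8)
  for (c8 in 1:8) {
    corner_lin[, c8] <- (oi + off[c8, 1]) +
      (oj + off[c8, 2] - 1L) * n0 +
      (ok + off[c8, 3] - 1L) * n0 * n1
  }

  lin_to_xyz <- function(l) {
    l0 <- l - 1L
    i <- l0 %% n0
    j <- (l0 %/% n0) %% n1
    k <- l0 %/% (n0 * n1)
    cbind(i * sp[1], j * sp[2], k * sp[3])
  }
  # interpolated crossing point on edge (l1, l2)
  interp_edge <- function(l1, l2) {
    v1 <- v[l1]; v2 <- v[l2]
    t <- (iso_level - v1) / (v2 - v1)
    p1 <- lin_to_xyz(l1); p2 <- lin_to_xyz(l2)
    p1 + t * (p2 - p1)
  }

  # case tables: apex configurations for single-vertex cases, and the
  # (above pair, below pair) for double-vertex cases
  single <- list(`1` = c(1, 2, 3, 4), `2` = c(2, 1, 3, 4),
                 `4` = c(3, 1, 2, 4), `8` = c(4, 1, 2, 3),
                 `14` = c(1, 2, 3, 4), `13` = c(2, 1, 3, 4),
                 `11` = c(3, 1, 2, 4), `7` = c(4, 1, 2, 3))
  pairs <- list(`3` = c(1, 2, 3, 4), `5` = c(1, 3, 2, 4), `9` = c(1, 4, 2, 3),
                `6` = c(2, 3, 1, 4), `10` = c(2, 4, 1, 3), `12` = c(3, 4, 1, 2))

  verts <- list(); nv <- 0L
  for (t6 in seq_len(nrow(tets))) {
    id4 <- corner_lin[, tets[t6, ], drop = FALSE]
    above <- matrix(v[id4] >= iso_level, nrow = nrow(id4))
    code <- above %*% c(1L, 2L, 4L, 8L)
    for (cs in names(single)) {
      sel <- which(code == as.integer(cs))
      if (!length(sel)) next
      cfg <- single[[cs]]
      a <- id4[sel, cfg[1]]; b <- id4[sel, cfg[2]]
      cc <- id4[sel, cfg[3]]; d <- id4[sel, cfg[4]]
      nv <- nv + 1L
      verts[[nv]] <- rbind(interp_edge(a, b), interp_edge(a, cc), interp_edge(a, d))
      attr(verts[[nv]], "ntri") <- length(sel)
      attr(verts[[nv]], "layout") <- "tri3"
    }
    for (cs in names(pairs)) {
      sel <- which(code == as.integer(cs))
      if (!length(sel)) next
      cfg <- pairs[[cs]]
      a <- id4[sel, cfg[1]]; b <- id4[sel, cfg[2]]
      cc <- id4[sel, cfg[3]]; d <- id4[sel, cfg[4]]
      # quad cycle e_ac, e_bc, e_bd, e_ad
      e1 <- interp_edge(a, cc); e2 <- interp_edge(b, cc)
      e3 <- interp_edge(b, d);  e4 <- interp_edge(a, d)
      nv <- nv + 1L
      verts[[nv]] <- rbind(e1, e2, e3, e4)
      attr(verts[[nv]], "ntri") <- length(sel)
      attr(verts[[nv]], "layout") <- "quad4"
    }
  }

  V <- matrix(numeric(0), 0, 3)
  F <- matrix(integer(0), 0, 3)
  base <- 0L
  for (blk in verts[seq_len(nv)]) {
    m <- attr(blk, "ntri")
    if (attr(blk, "layout") == "tri3") {
      # blk rows: [e1(1..m), e2(1..m), e3(1..m)]
      V <- rbind(V, blk)
      idx <- seq_len(m)
      F <- rbind(F, cbind(base + idx, base + m + idx, base + 2L * m + idx))
      base <- base + 3L * m
    } else {
      V <- rbind(V, blk)
      idx <- seq_len(m)
      e1 <- base + idx; e2 <- base + m + idx
      e3 <- base + 2L * m + idx; e4 <- base + 3L * m + idx
      F <- rbind(F, cbind(e1, e2, e3), cbind(e1, e3, e4))
      base <- base + 4L * m
    }
  }
  if (nrow(F) == 0) {
    stop_named("anoscore_no_crossing", "no tetrahedron crosses iso_level")
  }
  structure(list(vertices = V, faces = F, iso_level = iso_level),
            class = "surface_mesh")
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a `surface_mesh`.
#' @return Sum of triangle areas (mm^2).
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# ---- frontal depth rendering ----------------------------------------------

#' First-crossing depth map of a volume along the anterior--posterior axis
#'
#' For every (left-right, cranio-caudal) ray the depth (mm from the anterior
#' image plane) of the first linear-interpolated crossing of `iso_level`
#' along increasing axis-1 index is computed. Rays that never cross are
#' reported as misses.
#'
#' @param volume a [volume_grid()].
#' @param iso_level scalar threshold.
#' @return A list with `depth` (n1 x n2 matrix, mm; `NA` where missed) and
#'   `hit` (logical matrix).
#' @export
depth_map <- function(volume, iso_level = 0.5) {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$values
  dm <- dim(v)
  n0 <- dm[1]
  m <- matrix(v >= iso_level, nrow = n0)   # columns are rays
  cm <- m
  for (i in 2:n0) cm[i, ] <- cm[i, ] | cm[i - 1L, ]
  hit <- cm[n0, ]
  idx <- n0 + 1L - colSums(cm)             # first index with value >= iso
  depth <- rep(NA_real_, ncol(m))
  sp0 <- volume$spacing[1]
  at_face <- hit & idx == 1L
  depth[at_face] <- 0
  inner <- which(hit & idx > 1L)
  if (length(inner)) {
    i2 <- idx[inner]
    lin2 <- (inner - 1L) * n0 + i2
    v2 <- v[lin2]; v1 <- v[lin2 - 1L]
    frac <- (iso_level - v1) / (v2 - v1)
    depth[inner] <- ((i2 - 2L) + frac) * sp0
  }
  list(depth = matrix(depth, dm[2], dm[3]),
       hit = matrix(hit, dm[2], dm[3]))
}

#' Render a frontal depth-map image
#'
#' Orthographic frontal projection: each pixel holds the normalized depth
#' from the anterior image plane to the first surface intersection along the
#' anterior--posterior axis. Hit depths are min-max normalized to
#' `[0, 0.95]`; rays that miss map to the background value exactly 1.0, so
#' the background is strictly the brightest value. Accepts either a
#' [volume_grid()] (rays cast through the scalar field at `iso_level`) or a
#' `surface_mesh` (triangles rasterized with a z-buffer). Image rows run
#' along the cranio-caudal axis, columns along left--right.
#'
#' @param x a [volume_grid()] or `surface_mesh`.
#' @param image_size output side length in pixels.
#' @param iso_level threshold used for the volume path (default 0.5, suited
#'   to phantom density fields; use e.g. -300 for CT HU).
#' @return An object of class `rendered_image`.
#' @export
render_frontal <- function(x, image_size = NULL, iso_level = 0.5) {
  if (inherits(x, "volume_grid")) {
    dmap <- depth_map(x, iso_level)
    if (!any(dmap$hit)) stop_named("anoscore_no_crossing", "no ray crosses iso_level")
    d <- dmap$depth
    pix <- normalize_depth(d)
    # rows = cranio-caudal, cols = left-right
    pix <- t(pix)
    img <- rendered_image(pix, provenance = list(source = "volume", iso_level = iso_level))
    if (!is.null(image_size) && image_size != ncol(pix)) {
      img <- resize_normalize(img, image_size)
    }
    return(img)
  }
  if (inherits(x, "surface_mesh")) {
    if (is.null(image_size)) stop("image_size is required for mesh rendering")
    return(render_mesh_frontal(x, image_size))
  }
  stop("x must be a volume_grid or surface_mesh")
}

normalize_depth <- function(d) {
  hit <- !is.na(d)
  pix <- matrix(1.0, nrow(d), ncol(d))
  dh <- d[hit]
  if (length(dh)) {
    rngd <- range(dh)
    pix[hit] <- if (rngd[2] > rngd[1]) {
      (dh - rngd[1]) / (rngd[2] - rngd[1]) * 0.95
    } else 0
  }
  pix
}

# z-buffer rasterization of a mesh, orthographic along axis 1 (AP)
render_mesh_frontal <- function(mesh, image_size) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) stop("empty mesh")
  # project: image plane spanned by (axis2 = LR -> columns, axis3 = CC -> rows)
  lr <- V[, 2]; cc <- V[, 3]; dep <- V[, 1]
  rngx <- range(lr); rngy <- range(cc)
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1])
  if (span <= 0) stop_named("anoscore_degenerate_bbox", "degenerate mesh bounding box")
  pad <- 0.02 * span
  x0 <- rngx[1] - pad; y0 <- rngy[1] - pad
  scale <- (image_size - 1) / (span + 2 * pad)
  px <- (lr - x0) * scale + 1
  py <- (cc - y0) * scale + 1
  zbuf <- matrix(Inf, image_size, image_size)  # rows = cc, cols = lr
  for (f in seq_len(nrow(F))) {
    i1 <- F[f, 1]; i2 <- F[f, 2]; i3 <- F[f, 3]
    xs <- c(px[i1], px[i2], px[i3]); ys <- c(py[i1], py[i2], py[i3])
    zs <- c(dep[i1], dep[i2], dep[i3])
    cmin <- max(1L, floor(min(xs))); cmax <- min(image_size, ceiling(max(xs)))
    rmin <- max(1L, floor(min(ys))); rmax <- min(image_size, ceiling(max(ys)))
    if (cmin > cmax || rmin > rmax) next
    det <- (ys[2] - ys[3]) * (xs[1] - xs[3]) + (xs[3] - xs[2]) * (ys[1] - ys[3])
    if (abs(det) < 1e-12) next
    for (cI in cmin:cmax) {
      for (rI in rmin:rmax) {
        l1 <- ((ys[2] - ys[3]) * (cI - xs[3]) + (xs[3] - xs[2]) * (rI - ys[3])) / det
        l2 <- ((ys[3] - ys[1]) * (cI - xs[3]) + (xs[1] - xs[3]) * (rI - ys[3])) / det
        l3 <- 1 - l1 - l2
        if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
          z <- l1 * zs[1] + l2 * zs[2] + l3 * zs[3]
          if (z < zbuf[rI, cI]) zbuf[rI, cI] <- z
        }
      }
    }
  }
  d <- ifelse(is.finite(zbuf), zbuf, NA_real_)
  rendered_image(normalize_depth(d),
                 provenance = list(source = "mesh", iso_level = mesh$iso_level))
}

#' Rendered 2D frontal surface image
#'
#' @param pixels square numeric matrix with values in `[0, 1]`; background
#'   pixels are exactly 1.0.
#' @param provenance list describing the source.
#' @return An object of class `rendered_image`.
#' @export
rendered_image <- function(pixels, provenance = list()) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (any(pixels < 0 | pixels > 1)) stop("pixel values must lie in [0,1]")
  structure(list(pixels = pixels, size = nrow(pixels),
                 render_mode = "depth_map", provenance = provenance),
            class = "rendered_image")
}

#' Bilinear resize of a rendered image
#'
#' Resizes with bilinear interpolation (via EBImage) and clips to `[0, 1]`.
#' A no-op when `out_size` equals the current size.
#'
#' @param image a `rendered_image` or plain pixel matrix.
#' @param out_size output side length in pixels (>= 8).
#' @return Same class as the input.
#' @export
resize_normalize <- function(image, out_size) {
  stopifnot(is_count(out_size, min = 8))
  pix <- as_pixel_matrix(image)
  if (nrow(pix) == out_size && ncol(pix) == out_size) return(image)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(pix),
                                            w = out_size, h = out_size,
                                            filter = "bilinear"))
  out <- clamp01(matrix(out, out_size, out_size))
  if (inherits(image, "rendered_image")) {
    rendered_image(out, provenance = c(image$provenance, list(resized_from = nrow(pix))))
  } else {
    out
  }
}

#' Read / write a grayscale PNG image
#'
#' @param path file path.
#' @return `read_image_png` returns a pixel matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' @rdname read_image_png
#' @param pixels numeric matrix in `[0, 1]`.
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(clamp01(as_pixel_matrix(pixels)), path)
  invisible(path)
}
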