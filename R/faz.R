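#' Foveal avascular zone region from a polygon delineation
#'
#' The FAZ is delineated (in the study workflow, manually with a polygon tool
#' on the superficial plexus image) as an ordered vertex list in mm scan
#' coordinates. Its area is the absolute shoelace area of the polygon; the
#' raster form, used to mask the density computation, applies the pixel-centre
#' rule against a [scan_geometry()].
#'
#' The FAZ is measured on the SCP only; the retinal plexuses merge at the FAZ
#' edge, so a single delineation is used to mask all three plexus images.
#'
#' @param vertices_mm Numeric n x 2 matrix (or data.frame / list of pairs) of
#'   (x, y) vertices in mm. `NULL` or a 0-row matrix gives an empty region.
#' @return An object of class `octa_faz` with fields `vertices_mm` and
#'   `area_mm2`.
#' @examples
#' faz <- faz_region(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' faz$area_mm2 # 1
#' @export
faz_region <- function(vertices_mm) {
  v <- normalize_vertices(vertices_mm)
  area <- if (nrow(v) == 0L) 0 else polygon_area(v)
  structure(list(vertices_mm = v, area_mm2 = area), class = "octa_faz")
}

#' @export
print.octa_faz <- function(x, ...) {
  cat(sprintf("<octa_faz> %d vertices, area %.3f mm^2\n",
              nrow(x$vertices_mm), x$area_mm2))
  invisible(x)
}

normalize_vertices <- function(v) {
  if (is.null(v)) return(matrix(numeric(0), 0, 2))
  if (is.data.frame(v)) v <- as.matrix(v)
  if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
  if (!is.matrix(v) || (nrow(v) > 0 && ncol(v) != 2L) || anyNA(v)) {
    abort_octa("vertices must be an n x 2 numeric matrix of (x, y) in mm",
               "octa_bad_polygon")
  }
  storage.mode(v) <- "double"
  unname(v)
}

#' Absolute shoelace area of a simple polygon (mm^2)
#'
#' Orientation-independent; vertices may wind either way. Degenerate inputs
#' with fewer than 3 vertices return area 0 with a warning; self-intersecting
#' polygons are rejected.
#'
#' @param vertices_mm n x 2 numeric matrix of (x, y) vertices in mm.
#' @return Area in mm^2.
#' @examples
#' polygon_area(cbind(c(0, 1, 0), c(0, 0, 1))) # 0.5
#' @export
polygon_area <- function(vertices_mm) {
  v <- normalize_vertices(vertices_mm)
  n <- nrow(v)
  if (n < 3L) {
    warning("polygon has fewer than 3 vertices; area is 0", call. = FALSE)
    return(0)
  }
  if (!is_simple_polygon(v)) {
    abort_octa("polygon is self-intersecting", "octa_bad_polygon")
  }
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# O(n^2) pairwise proper-crossing test between non-adjacent edges.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(TRUE)
  j <- c(2:n, 1L)
  a <- v; b <- v[j, , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      # skip edges sharing a vertex (adjacent, incl. the closing edge)
      if (k == i + 1L || (i == 1L && k == n)) next
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[k, 1], a[k, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[k, 1], b[k, 2])
      d3 <- cross(a[k, 1], a[k, 2], b[k, 1], b[k, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[k, 1], a[k, 2], b[k, 1], b[k, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize a FAZ polygon onto a pixel grid
#'
#' A pixel belongs to the raster iff its centre lies inside the polygon
#' (even-odd rule). The raster area `count * px_scale_mm^2` converges to the
#' shoelace area as the grid is refined.
#'
#' @param faz An [faz_region()] (or a bare vertex matrix).
#' @param geometry Target [scan_geometry()].
#' @return Logical `n_px x n_px` matrix, `TRUE` inside the FAZ.
#' @export
rasterize_faz <- function(faz, geometry) {
  if (!inherits(faz, "octa_faz")) faz <- faz_region(faz)
  stopifnot(inherits(geometry, "octa_geometry"))
  n <- geometry$n_px
  v <- faz$vertices_mm
  if (nrow(v) < 3L) return(matrix(FALSE, n, n))
  if (min(v[, 1]) > geometry$extent_mm || max(v[, 1]) < 0 ||
      min(v[, 2]) > geometry$extent_mm || max(v[, 2]) < 0) {
    warning("FAZ polygon lies outside the scan extent; raster is empty",
            call. = FALSE)
    return(matrix(FALSE, n, n))
  }
  pc <- pixel_centers(geometry)
  crossings <- matrix(0L, n, n)   # rows = y, cols = x
  nv <- nrow(v)
  jj <- c(2:nv, 1L)
  for (e in seq_len(nv)) {
    y1 <- v[e, 2]; y2 <- v[jj[e], 2]
    if (y1 == y2) next
    rows <- which((y1 > pc$y) != (y2 > pc$y))
    if (!length(rows)) next
    xint <- v[e, 1] + (pc$y[rows] - y1) / (y2 - y1) * (v[jj[e], 1] - v[e, 1])
    # ray cast toward +x: pixel centre is left of the intersection
    crossings[rows, ] <- crossings[rows, ] +
      outer(xint, pc$x, function(xi, cx) as.integer(cx < xi))
  }
  crossings %% 2L == 1L
}

#' Read / write FAZ polygons as JSON vertex lists
#'
#' Schema: `{"vertices_mm": [[x, y], ...]}` with coordinates in mm (origin at
#' the top-left pixel centre, x rightward, y downward).
#' @param faz An `octa_faz`.
#' @param path JSON file path.
#' @return `write_faz` returns `path` invisibly; `read_faz` an `octa_faz`.
#' @export
write_faz <- function(faz, path) {
  stopifnot(inherits(faz, "octa_faz"))
  jsonlite::write_json(
    list(vertices_mm = lapply(seq_len(nrow(faz$vertices_mm)),
                              function(i) as.numeric(faz$vertices_mm[i, ]))),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_faz
#' @export
read_faz <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vertices_mm
  if (is.list(v)) v <- do.call(rbind, v)
  if (length(v) == 0L) v <- NULL
  faz_region(v)
}

#' Construct a jittered near-circular FAZ polygon of exact target area
#'
#' Builds an `n_vertices`-gon with per-vertex radial jitter, then rescales so
#' the shoelace area equals `area_mm2` exactly. Used by the synthetic cohort
#' generator (typical SCP FAZ areas: ~0.103 mm^2 for VMT-like eyes, ~0.198
#' mm^2 for healthy controls).
#'
#' @param area_mm2 Target polygon area (mm^2), > 0.
#' @param center_mm Length-2 centre (x, y) in mm.
#' @param n_vertices Number of vertices (default 12).
#' @param jitter Relative SD of radial jitter (default 0.08).
#' @param seed RNG seed.
#' @return An [faz_region()].
#' @export
synthetic_faz_polygon <- function(area_mm2, center_mm, n_vertices = 12L,
                                  jitter = 0.08, seed = 1L) {
  stopifnot(area_mm2 > 0, length(center_mm) == 2L, n_vertices >= 3L)
  with_seed(seed, {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    r <- pmax(0.2, 1 + stats::rnorm(n_vertices, 0, jitter))
    v <- cbind(r * cos(th), r * sin(th))
    a0 <- polygon_area(v)
    v <- v * sqrt(area_mm2 / a0)
    faz_region(cbind(v[, 1] + center_mm[1], v[, 2] + center_mm[2]))
  })
}
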