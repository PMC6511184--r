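#' Scan geometry: the coordinate contract every image shares
#'
#' An en-face OCT-A acquisition is a square field of view of physical side
#' `extent_mm` sampled on an `n_px` x `n_px` A-scan grid. All images, surface
#' maps and rasterized FAZ masks attached to one eye share a single geometry.
#'
#' Coordinates are millimetres with the origin at the centre of the top-left
#' pixel, x increasing rightward (columns) and y increasing downward (rows),
#' so pixel `[r, c]` has centre `((c - 1) * px_scale_mm, (r - 1) * px_scale_mm)`.
#'
#' @param extent_mm Physical side of the square scan in mm (3.0 and 6.0 are the
#'   device presets; any positive value is accepted).
#' @param n_px Number of pixels (A-scans) per side. If `NULL`, the preset grid
#'   for 3 mm (245 px) or 6 mm (350 px) is used; other extents require `n_px`.
#' @return An object of class `octa_geometry` with fields `extent_mm`, `n_px`
#'   and `px_scale_mm = extent_mm / n_px`.
#' @examples
#' scan_geometry(6)            # 6 x 6 mm AngioPlex-like preset, 350 px
#' scan_geometry(3, n_px = 64) # downsampled grid for quick simulations
#' @export
scan_geometry <- function(extent_mm, n_px = NULL) {
  stopifnot(is.numeric(extent_mm), length(extent_mm) == 1L)
  if (!is.finite(extent_mm) || extent_mm <= 0) {
    abort_octa("extent_mm must be a positive real", "octa_bad_geometry")
  }
  if (is.null(n_px)) {
    n_px <- if (isTRUE(all.equal(extent_mm, 3))) 245L
            else if (isTRUE(all.equal(extent_mm, 6))) 350L
            else abort_octa("n_px must be given for non-preset extents",
                            "octa_bad_geometry")
  }
  n_px <- as.integer(n_px)
  if (!is.finite(n_px) || n_px <= 0L) {
    abort_octa("empty geometry", "octa_bad_geometry")
  }
  structure(
    list(extent_mm = as.numeric(extent_mm), n_px = n_px,
         px_scale_mm = as.numeric(extent_mm) / n_px),
    class = "octa_geometry"
  )
}

#' @export
print.octa_geometry <- function(x, ...) {
  cat(sprintf("<octa_geometry> %.1f x %.1f mm, %d x %d px (%.4f mm/px)\n",
              x$extent_mm, x$extent_mm, x$n_px, x$n_px, x$px_scale_mm))
  invisible(x)
}

#' x/y coordinates (mm) of all pixel centres
#' @param geometry An `octa_geometry`.
#' @return List with vectors `x` (per column) and `y` (per row), length `n_px`.
#' @export
pixel_centers <- function(geometry) {
  stopifnot(inherits(geometry, "octa_geometry"))
  s <- geometry$px_scale_mm
  list(x = (seq_len(geometry$n_px) - 1) * s,
       y = (seq_len(geometry$n_px) - 1) * s)
}

same_geometry <- function(a, b, tol = 1e-9) {
  a$n_px == b$n_px && abs(a$extent_mm - b$extent_mm) < tol
}

check_grid <- function(m, geometry, what = "grid") {
  if (!is.matrix(m) || nrow(m) != geometry$n_px || ncol(m) != geometry$n_px) {
    abort_octa(sprintf("%s dimensions do not match geometry (%d x %d expected)",
                       what, geometry$n_px, geometry$n_px), "octa_bad_grid")
  }
  invisible(m)
}
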