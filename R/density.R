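#' FAZ-subtracted perfusion density
#'
#' The headline metric: the ratio of perfused (foreground) pixels to the total
#' scan area after subtracting the FAZ, i.e. the mean of the binarized slab
#' restricted to non-excluded pixels. Dimensionless in `[0, 1]`. Foreground
#' pixels inside the exclusion mask are ignored entirely — they count in
#' neither numerator nor denominator.
#'
#' @param m An `octa_masked` (see [apply_faz_mask()]).
#' @return Density in `[0, 1]`.
#' @examples
#' g <- scan_geometry(3, n_px = 2)
#' b <- binary_angiogram(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), g)
#' perfusion_density(masked_angiogram(b, matrix(FALSE, 2, 2))) # 0.5
#' @export
perfusion_density <- function(m) {
  stopifnot(inherits(m, "octa_masked"))
  roi <- !m$excluded
  n_roi <- sum(roi)
  if (n_roi == 0L) abort_octa("empty region of interest", "octa_empty_roi")
  sum(m$binary$pixels & roi) / n_roi
}

#' Measure one eye at one timepoint across the three plexuses
#'
#' Runs the full macro path per plexus image — reference channel, global mean
#' threshold, strict binarization, FAZ masking — and returns tidy
#' per-measurement rows. The single SCP-delineated FAZ masks all three
#' plexuses (the density is a peri-FAZ density); the FAZ area is attached to
#' the SCP row only.
#'
#' @param images Named list with elements `SCP`, `DCP`, `CC`: each an
#'   [angiogram()] or a file path readable by [read_angiogram()]. Missing
#'   plexuses yield a partial result with a warning.
#' @param faz An [faz_region()] delineated on the SCP.
#' @param geometry The shared [scan_geometry()].
#' @param eye_id Identifier.
#' @param timepoint `"baseline"` or `"month1"`.
#' @return A data.frame with one row per available plexus: `eye_id`,
#'   `timepoint`, `plexus`, `extent_mm`, `density`, `faz_area_mm2` (NA except
#'   SCP), `threshold`.
#' @export
measure_eye <- function(images, faz, geometry, eye_id,
                        timepoint = c("baseline", "month1")) {
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(faz, "octa_faz"), inherits(geometry, "octa_geometry"))
  plexuses <- c("SCP", "DCP", "CC")
  missing <- setdiff(plexuses, names(images))
  if (length(missing)) {
    warning(sprintf("eye %s/%s: missing plexus image(s): %s",
                    eye_id, timepoint, paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  excl <- rasterize_faz(faz, geometry)
  rows <- lapply(intersect(plexuses, names(images)), function(p) {
    img <- images[[p]]
    if (is.character(img)) img <- read_angiogram(img, geometry)
    gray <- to_reference_channel(img)
    thr <- mean_threshold(gray)
    dens <- perfusion_density(apply_faz_mask(binarize(gray, thr), excl))
    data.frame(eye_id = as.character(eye_id), timepoint = timepoint,
               plexus = p, extent_mm = geometry$extent_mm, density = dens,
               faz_area_mm2 = if (p == "SCP") faz$area_mm2 else NA_real_,
               threshold = thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
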