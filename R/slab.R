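#' Derive capillary-plexus slab boundaries from ILM/RPE surfaces
#'
#' Pure per-A-scan arithmetic, no smoothing. The outer plexiform layer is
#' estimated at a fixed offset above the RPE, the inner plexiform layer at 70%
#' of the ILM-to-OPL thickness, and the choriocapillaris slab is a fixed 20 um
#' band below the RPE:
#' \deqn{z_{OPL} = z_{RPE} - 110}
#' \deqn{z_{IPL} = z_{ILM} + 0.70 (z_{OPL} - z_{ILM})}
#' \deqn{CC = [z_{RPE} + 29,\ z_{RPE} + 49)}
#' Slabs use half-open depth intervals: SCP = `[z_ilm, z_ipl)`,
#' DCP = `[z_ipl, z_opl)`, so SCP and DCP tile `[z_ilm, z_opl)` without
#' double-counting the IPL plane.
#'
#' @param s An [surface_set()].
#' @return An object of class `octa_boundaries` with depth grids `z_ipl`,
#'   `z_opl`, `cc_inner`, `cc_outer` and the thickness grid `t_ilm_opl` (um).
#' @examples
#' g <- scan_geometry(6, n_px = 4)
#' s <- surface_set(matrix(100, 4, 4), matrix(410, 4, 4), g)
#' b <- derive_boundaries(s)
#' b$z_opl[1, 1] # 300
#' b$z_ipl[1, 1] # 240
#' @export
derive_boundaries <- function(s) {
  stopifnot(inherits(s, "octa_surfaces"))
  z_opl <- s$z_rpe - 110
  t_ilm_opl <- z_opl - s$z_ilm
  z_ipl <- s$z_ilm + 0.70 * t_ilm_opl
  structure(
    list(z_ipl = z_ipl, z_opl = z_opl,
         cc_inner = s$z_rpe + 29, cc_outer = s$z_rpe + 49,
         t_ilm_opl = t_ilm_opl, geometry = s$geometry),
    class = "octa_boundaries")
}

#' Flag A-scans whose derived boundaries are anatomically impossible
#'
#' Mirrors the study's manual exclusion of inaccurately segmented scans: an
#' A-scan is flagged when the axial ordering
#' `z_ilm <= z_ipl <= z_opl <= z_rpe` fails (e.g. the derived OPL falls above
#' the ILM in a thin or corrupted scan) or any boundary is negative. Returns a
#' per-pixel mask rather than raising: the study excluded whole eyes, so the
#' exclusion policy belongs to the cohort layer.
#'
#' @param b Boundaries from [derive_boundaries()].
#' @param s The [surface_set()] the boundaries were derived from.
#' @return Object of class `octa_qc`: `ok` (no violations), `violation_mask`
#'   (logical grid) and `reason` (text).
#' @export
validate_segmentation <- function(b, s) {
  stopifnot(inherits(b, "octa_boundaries"), inherits(s, "octa_surfaces"))
  bad_order <- !(s$z_ilm <= b$z_ipl & b$z_ipl <= b$z_opl & b$z_opl <= s$z_rpe)
  bad_neg <- s$z_ilm < 0 | b$z_ipl < 0 | b$z_opl < 0 | s$z_rpe < 0 |
    b$cc_inner < 0 | b$cc_outer < 0
  mask <- bad_order | bad_neg
  reason <- if (!any(mask)) {
    "ok"
  } else {
    paste0(c(if (any(bad_order)) "boundary ordering violated (z_ilm <= z_ipl <= z_opl <= z_rpe)",
             if (any(bad_neg)) "negative boundary depth"),
           collapse = "; ")
  }
  structure(list(ok = !any(mask), violation_mask = mask, reason = reason),
            class = "octa_qc")
}

#' @export
print.octa_qc <- function(x, ...) {
  cat(sprintf("<octa_qc> %s (%d flagged A-scans): %s\n",
              if (x$ok) "OK" else "FAIL", sum(x$violation_mask), x$reason))
  invisible(x)
}

#' En-face projection of an OCT volume within a slab
#'
#' Aggregates, per A-scan, the voxels whose centre depth lies in the chosen
#' slab's half-open interval `[inner, outer)`. The device's internal
#' projection rule is unspecified; both `max` (default, the common OCT-A
#' convention) and `mean` are exposed.
#'
#' @param volume 3-D numeric array `n_px x n_px x n_z`, depth along the third
#'   axis.
#' @param b Boundaries from [derive_boundaries()]; pass the matching
#'   [surface_set()] as `s` so SCP can use `z_ilm`.
#' @param s The surface set (needed for the SCP inner boundary).
#' @param slab One of `"SCP"`, `"DCP"`, `"CC"`.
#' @param method `"max"` or `"mean"`.
#' @param z0_um Depth of the first voxel centre (um).
#' @param dz_um Axial voxel pitch (um).
#' @return An [angiogram()] (values clipped to `[0, 255]` are the caller's
#'   responsibility; the projection returns raw aggregates as a matrix).
#' @export
project_slab <- function(volume, b, s, slab = c("SCP", "DCP", "CC"),
                         method = c("max", "mean"), z0_um = 0, dz_um = 10) {
  slab <- match.arg(slab)
  method <- match.arg(method)
  stopifnot(is.array(volume), length(dim(volume)) == 3L,
            inherits(b, "octa_boundaries"), inherits(s, "octa_surfaces"))
  dims <- dim(volume)
  if (dims[1] != b$geometry$n_px || dims[2] != b$geometry$n_px) {
    abort_octa("volume en-face dimensions do not match geometry", "octa_bad_grid")
  }
  inner <- switch(slab, SCP = s$z_ilm, DCP = b$z_ipl, CC = b$cc_inner)
  outer_ <- switch(slab, SCP = b$z_ipl, DCP = b$z_opl, CC = b$cc_outer)
  zc <- z0_um + (seq_len(dims[3]) - 0.5) * dz_um
  acc <- matrix(if (method == "max") -Inf else 0, dims[1], dims[2])
  cnt <- matrix(0L, dims[1], dims[2])
  for (k in seq_len(dims[3])) {
    inside <- zc[k] >= inner & zc[k] < outer_
    if (!any(inside)) next
    sl <- volume[, , k]
    if (method == "max") {
      acc[inside] <- pmax(acc[inside], sl[inside])
    } else {
      acc[inside] <- acc[inside] + sl[inside]
    }
    cnt[inside] <- cnt[inside] + 1L
  }
  if (all(cnt == 0L)) {
    abort_octa("slab lies entirely outside the volume depth range",
               "octa_empty_slab")
  }
  out <- if (method == "max") {
    acc[cnt == 0L] <- NA_real_
    acc
  } else {
    acc / ifelse(cnt == 0L, NA_real_, cnt)
  }
  out
}
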