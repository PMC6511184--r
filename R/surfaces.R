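#' Per-A-scan retinal surface maps
#'
#' Depth maps (micrometres from the top of the OCT volume, increasing from
#' vitreous to choroid) of the internal limiting membrane (ILM) and retinal
#' pigment epithelium (RPE), one value per A-scan. Every slab boundary is
#' derived from these two surfaces.
#'
#' @param z_ilm,z_rpe Numeric `n_px x n_px` matrices of depths in um.
#' @param geometry The shared [scan_geometry()].
#' @return An object of class `octa_surfaces`.
#' @export
surface_set <- function(z_ilm, z_rpe, geometry) {
  stopifnot(inherits(geometry, "octa_geometry"))
  check_grid(z_ilm, geometry, "z_ilm")
  check_grid(z_rpe, geometry, "z_rpe")
  if (anyNA(z_ilm) || anyNA(z_rpe)) {
    abort_octa("surface maps must not contain NA", "octa_bad_grid")
  }
  structure(list(z_ilm = z_ilm, z_rpe = z_rpe, geometry = geometry),
            class = "octa_surfaces")
}

#' @export
print.octa_surfaces <- function(x, ...) {
  cat(sprintf(
    "<octa_surfaces> %d x %d A-scans, ILM [%.0f, %.0f] um, RPE [%.0f, %.0f] um\n",
    nrow(x$z_ilm), ncol(x$z_ilm), min(x$z_ilm), max(x$z_ilm),
    min(x$z_rpe), max(x$z_rpe)))
  invisible(x)
}

#' Write / read a surface depth grid as a CSV matrix (um)
#' @param z Numeric matrix of depths (um).
#' @param path CSV path.
#' @return `write_surface_grid` returns `path` invisibly.
#' @export
write_surface_grid <- function(z, path) {
  utils::write.table(z, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_grid
#' @export
read_surface_grid <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Generate smooth synthetic ILM/RPE surfaces with a foveal pit and optional
#' focal vitreomacular traction
#'
#' The ILM carries a Gaussian foveal pit (posterior displacement, i.e. depth
#' increases at the centre where the retina thins) plus, when
#' `vmt_peak_um > 0`, a raised-cosine anterior displacement confined to a
#' central adhesion disk of diameter `vmt_diameter_um` — the focal traction
#' morphology of an eligible VMT eye (adhesion diameter < 1500 um). Both
#' surfaces get a low-frequency seeded undulation so they are not analytically
#' flat.
#'
#' @param geometry A [scan_geometry()].
#' @param foveal_pit_depth_um Posterior ILM displacement at the foveal centre.
#' @param vmt_peak_um Peak anterior ILM displacement under traction (0 = none).
#' @param vmt_diameter_um Diameter of the adhesion disk over which traction
#'   acts.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param ilm_base_um,rpe_base_um Peripheral ILM / RPE depths (defaults 150 and
#'   470 um give a 320 um peripheral retinal thickness).
#' @param pit_radius_mm Gaussian radius of the pit (default 0.35 mm).
#' @param undulation_um Amplitude of the smooth random undulation.
#' @return An [surface_set()].
#' @export
generate_surfaces <- function(geometry, foveal_pit_depth_um = 80,
                              vmt_peak_um = 0, vmt_diameter_um = 0,
                              seed = 1L, ilm_base_um = 150, rpe_base_um = 470,
                              pit_radius_mm = 0.35, undulation_um = 3) {
  stopifnot(inherits(geometry, "octa_geometry"))
  if (geometry$n_px <= 0L) abort_octa("empty geometry", "octa_bad_geometry")
  stopifnot(vmt_diameter_um >= 0, foveal_pit_depth_um >= 0, vmt_peak_um >= 0)
  base_sep <- rpe_base_um - ilm_base_um
  if (foveal_pit_depth_um >= base_sep || vmt_peak_um >= base_sep) {
    abort_octa("pit/traction magnitude must be below the ILM-RPE separation",
               "octa_bad_geometry")
  }
  n <- geometry$n_px
  pc <- pixel_centers(geometry)
  cx <- geometry$extent_mm / 2
  r_mm <- sqrt(outer((pc$y - cx)^2, (pc$x - cx)^2, "+"))

  z_ilm <- ilm_base_um + foveal_pit_depth_um * exp(-(r_mm / pit_radius_mm)^2)
  if (vmt_peak_um > 0 && vmt_diameter_um > 0) {
    R <- vmt_diameter_um / 2000  # disk radius in mm
    lift <- ifelse(r_mm < R, vmt_peak_um * 0.5 * (1 + cos(pi * r_mm / R)), 0)
    z_ilm <- z_ilm - lift
  }

  with_seed(seed, {
    z_ilm <- z_ilm + smooth_undulation(pc, undulation_um)
    z_rpe <- rpe_base_um + smooth_undulation(pc, undulation_um)
  })
  surface_set(z_ilm, z_rpe, geometry)
}

# sum of a few random-phase plane waves; smooth, zero-mean-ish, seeded by caller
smooth_undulation <- function(pc, amp_um, n_waves = 5L) {
  if (amp_um <= 0) return(0)
  z <- 0
  ext <- max(max(pc$x), 1e-9)
  for (i in seq_len(n_waves)) {
    kx <- stats::runif(1, 0.1, 0.6) * 2 * pi / ext
    ky <- stats::runif(1, 0.1, 0.6) * 2 * pi / ext
    ph <- stats::runif(2, 0, 2 * pi)
    z <- z + outer(sin(ky * pc$y + ph[1]), sin(kx * pc$x + ph[2]))
  }
  z * (amp_um / n_waves)
}
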