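#' Reduce an angiogram to the reference (red) channel
#'
#' The ImageJ-style macro converts the 8-bit export to RGB, splits channels
#' and keeps the red one as reference. For an RGB input this returns the red
#' channel; for an already-gray input it is the identity (8-bit -> RGB
#' replication makes every channel equal to the gray values).
#'
#' @param img An [angiogram()] (gray or RGB).
#' @return A gray [angiogram()].
#' @export
to_reference_channel <- function(img) {
  stopifnot(inherits(img, "octa_angiogram"))
  if (img$channel_layout == "gray") return(img)
  angiogram(img$pixels[, , 1L], img$geometry)
}

#' Global mean threshold of a gray angiogram
#'
#' The macro's "average fix threshold": the arithmetic mean of all pixel
#' intensities, computed over the full image (including any FAZ pixels —
#' thresholding happens before the FAZ is painted).
#'
#' @param img A gray [angiogram()].
#' @return The mean intensity (numeric scalar).
#' @export
mean_threshold <- function(img) {
  stopifnot(inherits(img, "octa_angiogram"))
  if (img$channel_layout != "gray") {
    abort_octa("mean_threshold expects a gray image; call to_reference_channel first",
               "octa_bad_layout")
  }
  if (length(img$pixels) == 0L) abort_octa("empty image", "octa_empty_image")
  mean(img$pixels)
}

#' Binarize a gray angiogram at a global threshold
#'
#' A pixel is foreground (perfused, white) iff its intensity is strictly
#' greater than the threshold. Strictness resolves ties deterministically: a
#' constant image binarized at its own mean has zero vessels.
#'
#' @param img A gray [angiogram()].
#' @param threshold Finite numeric threshold; defaults to [mean_threshold()].
#' @return An `octa_binary`.
#' @export
binarize <- function(img, threshold = mean_threshold(img)) {
  stopifnot(inherits(img, "octa_angiogram"), is.finite(threshold))
  if (img$channel_layout != "gray") {
    abort_octa("binarize expects a gray image; call to_reference_channel first",
               "octa_bad_layout")
  }
  binary_angiogram(img$pixels > threshold, img$geometry)
}

#' Attach the FAZ exclusion mask to a binary angiogram
#'
#' Marks the rasterized FAZ as excluded (the macro's "blue" pixels); the
#' binary image is unchanged outside the mask and downstream density ignores
#' excluded pixels entirely.
#'
#' @param bin An `octa_binary`.
#' @param faz An [faz_region()], or a logical matrix already rasterized on the
#'   same geometry.
#' @return An `octa_masked`.
#' @export
apply_faz_mask <- function(bin, faz) {
  stopifnot(inherits(bin, "octa_binary"))
  excluded <- if (is.matrix(faz) && is.logical(faz)) {
    check_grid(faz, bin$geometry, "FAZ raster")
    faz
  } else {
    rasterize_faz(faz, bin$geometry)
  }
  masked_angiogram(bin, excluded)
}
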