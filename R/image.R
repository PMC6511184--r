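#' En-face angiogram containers
#'
#' An `octa_angiogram` wraps a grayscale matrix or an RGB array of intensities
#' in `[0, 255]` together with its [scan_geometry()]. `octa_binary` holds the
#' binarized form (`TRUE` = perfused/white). `octa_masked` attaches an
#' exclusion mask (the FAZ, the macro's "blue" pixels) to a binary angiogram;
#' excluded pixels carry no perfusion meaning downstream.
#'
#' @param pixels Numeric matrix (gray) or `n x n x 3` array (RGB), values in
#'   `[0, 255]`.
#' @param geometry An `octa_geometry` matching the pixel dimensions.
#' @return An object of class `octa_angiogram`.
#' @export
angiogram <- function(pixels, geometry) {
  stopifnot(inherits(geometry, "octa_geometry"))
  if (is.matrix(pixels)) {
    layout <- "gray"
    check_grid(pixels, geometry, "angiogram")
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] != 3L) {
      abort_octa("unsupported layout: expected gray matrix or 3-channel RGB",
                 "octa_bad_layout")
    }
    layout <- "rgb"
    check_grid(pixels[, , 1L], geometry, "angiogram")
  } else {
    abort_octa("unsupported layout: expected gray matrix or 3-channel RGB",
               "octa_bad_layout")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort_octa("angiogram intensities must lie in [0, 255]", "octa_bad_range")
  }
  structure(list(pixels = pixels, geometry = geometry, channel_layout = layout),
            class = "octa_angiogram")
}

#' @rdname angiogram
#' @export
binary_angiogram <- function(pixels, geometry) {
  stopifnot(inherits(geometry, "octa_geometry"), is.logical(pixels))
  check_grid(pixels, geometry, "binary angiogram")
  if (anyNA(pixels)) abort_octa("binary angiogram must not contain NA",
                                "octa_bad_range")
  structure(list(pixels = pixels, geometry = geometry), class = "octa_binary")
}

#' @rdname angiogram
#' @param binary An `octa_binary`.
#' @param excluded Logical matrix, `TRUE` where pixels are excluded from
#'   analysis (the rasterized FAZ).
#' @export
masked_angiogram <- function(binary, excluded) {
  stopifnot(inherits(binary, "octa_binary"), is.logical(excluded))
  check_grid(excluded, binary$geometry, "exclusion mask")
  structure(list(binary = binary, excluded = excluded,
                 geometry = binary$geometry), class = "octa_masked")
}

#' @export
print.octa_angiogram <- function(x, ...) {
  cat(sprintf("<octa_angiogram> %s, %d x %d px, range [%.0f, %.0f]\n",
              x$channel_layout, nrow_px(x), nrow_px(x),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.octa_binary <- function(x, ...) {
  cat(sprintf("<octa_binary> %d x %d px, %.1f%% foreground\n",
              nrow_px(x), nrow_px(x), 100 * mean(x$pixels)))
  invisible(x)
}

nrow_px <- function(img) img$geometry$n_px

#' Read an en-face angiogram from a lossless image file
#'
#' PNG is the supported lossless interchange format (8-bit gray or RGB). JPEG
#' input is accepted for compatibility with device exports but triggers a
#' warning: lossy compression perturbs the image mean and hence the global
#' threshold, a documented reproducibility hazard.
#'
#' @param path File path (`.png`, or `.jpg`/`.jpeg` with a warning).
#' @param geometry Expected `octa_geometry` of the image.
#' @return An [angiogram()].
#' @export
read_angiogram <- function(path, geometry) {
  ext <- tolower(tools::file_ext(path))
  raw01 <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    warning("JPEG input is lossy; mean-threshold results are not bit-reproducible",
            call. = FALSE)
    jpeg::readJPEG(path)
  } else {
    abort_octa(sprintf("unsupported image format '%s' (use PNG)", ext),
               "octa_bad_format")
  }
  if (length(dim(raw01)) == 3L && dim(raw01)[3] != 3L) {
    abort_octa("unsupported layout: expected gray or 3-channel RGB",
               "octa_bad_layout")
  }
  angiogram(round(raw01 * 255), geometry)
}

#' Write an angiogram or binary mask as 8-bit PNG
#'
#' Binary masks are written as 0/255 grayscale, white = perfused.
#' @param img An `octa_angiogram` or `octa_binary`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(img, path) {
  px <- if (inherits(img, "octa_binary")) {
    matrix(as.numeric(img$pixels), nrow_px(img), nrow_px(img))
  } else if (inherits(img, "octa_angiogram")) {
    img$pixels / 255
  } else {
    abort_octa("img must be an octa_angiogram or octa_binary", "octa_bad_type")
  }
  png::writePNG(px, path)
  invisible(path)
}
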