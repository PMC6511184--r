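#' Synthetic OCT-A generation
#'
#' The study's patient scans are not deposited, so the pipeline is exercised
#' end-to-end on a synthetic stand-in: depth-stratified vascular plexuses
#' drawn as connected branching random walks (capillary-scale widths of 1-3
#' px), an avascular foveal zone cut out by polygon, grayscale rendering with
#' Gaussian blur plus additive noise, and paired longitudinal cohorts with a
#' known ground-truth ledger.
#'
#' @name synthetic_octa
NULL

#' Generate a binary vascular network with a target perfusion density
#'
#' Iterative branching random walk: an initial generation of walkers starts at
#' random positions; subsequent walkers branch from points already on the
#' network, so the foreground is connected-branching structure rather than
#' i.i.d. pixel noise. Strokes are stamped with widths of 1-3 px. Walk batches
#' are added (small batches near the goal) until the foreground fraction
#' outside the FAZ reaches `target_density`; pixels inside the FAZ are then
#' cleared, so the truth image is strictly avascular there. The achieved
#' fraction is stored in attribute `"achieved_density"` and is within +/- 0.02
#' of the target.
#'
#' @param geometry A [scan_geometry()].
#' @param target_density Target foreground fraction outside the FAZ, in (0, 1).
#' @param faz Optional [faz_region()] (or logical raster) to keep avascular.
#' @param branch_params Optional list overriding `step_px`, `turn_sd`,
#'   `len_range` (steps), `width_probs` (widths 1-3).
#' @param seed RNG seed.
#' @return An `octa_binary` with attributes `achieved_density` and `faz`.
#' @export
generate_vessel_network <- function(geometry, target_density, faz = NULL,
                                    branch_params = list(), seed = 1L) {
  stopifnot(inherits(geometry, "octa_geometry"))
  if (!is.finite(target_density) || target_density <= 0 || target_density >= 1) {
    abort_octa("target_density must lie strictly between 0 and 1",
               "octa_bad_density")
  }
  n <- geometry$n_px
  excl <- if (is.null(faz)) matrix(FALSE, n, n)
          else if (is.logical(faz) && is.matrix(faz)) check_grid(faz, geometry, "FAZ raster")
          else rasterize_faz(faz, geometry)
  outside <- !excl
  n_out <- sum(outside)
  if (n_out == 0L) abort_octa("no area outside FAZ", "octa_empty_roi")

  p <- utils::modifyList(
    list(step_px = 1.0, turn_sd = 0.35,
         # capillary segment lengths scale with the grid so coarse simulation
         # grids keep fine density control
         len_range = c(max(8L, n %/% 10L), min(120L, max(16L, n %/% 3L))),
         width_probs = c(0.45, 0.35, 0.20)),
    branch_params)

  with_seed(seed, {
    canvas <- matrix(FALSE, n, n)
    target_px <- target_density * n_out
    gain_per_walk <- mean(p$len_range) * 1.6   # rough initial estimate, px/walk
    iter <- 0L
    repeat {
      iter <- iter + 1L
      have <- sum(canvas & outside)
      remaining <- target_px - have
      if (remaining <= 0 || iter > 3000L) break
      # fine-approach phase: single short width-1 strokes so the final
      # foreground fraction overshoots the target by at most a few pixels
      fine <- remaining < 0.04 * n_out
      batch <- if (fine) 1L
               else max(1L, min(200L,
                                floor(0.6 * remaining / gain_per_walk),
                                # worst-case guard: never let one batch jump
                                # across the fine-approach zone
                                floor(remaining / (3 * p$len_range[2]))))
      before <- have
      for (w in seq_len(batch)) {
        len <- sample.int(p$len_range[2] - p$len_range[1] + 1L, 1L) +
          p$len_range[1] - 1L
        width <- sample.int(3L, 1L, prob = p$width_probs)
        if (fine) {
          width <- 1L
          len <- max(4L, min(len, as.integer(ceiling(remaining * 1.5))))
        }
        if (!any(canvas)) {
          start <- stats::runif(2, 1, n)
        } else {
          # branch: start from a random point already on the network
          fg <- which(canvas)
          s <- fg[sample.int(length(fg), 1L)]
          start <- c((s - 1L) %% n + 1L, (s - 1L) %/% n + 1L)
        }
        ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(len - 1L, 0, p$turn_sd)))
        xs <- start[1] + cumsum(cos(ang)) * p$step_px
        ys <- start[2] + cumsum(sin(ang)) * p$step_px
        rr <- round(xs); cc <- round(ys)
        keep <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        rr <- rr[keep]; cc <- cc[keep]
        if (!length(rr)) next
        off <- stroke_offsets(width)
        r_all <- rep(rr, each = nrow(off)) + off[, 1]
        c_all <- rep(cc, each = nrow(off)) + off[, 2]
        ok <- r_all >= 1 & r_all <= n & c_all >= 1 & c_all <= n
        canvas[cbind(r_all[ok], c_all[ok])] <- TRUE
      }
      gained <- sum(canvas & outside) - before
      gain_per_walk <- max(5, gained / batch)
    }
    canvas[excl] <- FALSE
    out <- binary_angiogram(canvas, geometry)
    attr(out, "achieved_density") <- sum(canvas & outside) / n_out
    attr(out, "faz") <- excl
    out
  })
}

stroke_offsets <- function(width) {
  switch(width,
    `1` = cbind(0L, 0L),
    `2` = cbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L)),
    `3` = cbind(c(0L, -1L, 1L, 0L, 0L), c(0L, 0L, 0L, -1L, 1L)))
}

#' Render a truth network as a noisy grayscale angiogram
#'
#' Foreground maps to 255 and background to 0; the image is then blurred with
#' a separable Gaussian (sigma in px) and perturbed with additive Gaussian
#' noise, clipped to `[0, 255]`. With `blur_sigma_px = 0` and `noise_sd = 0`
#' the output is exactly the 0/255 rendering, so the mean-threshold pipeline
#' recovers the truth bit-exactly.
#'
#' @param truth An `octa_binary` ground-truth network.
#' @param blur_sigma_px Gaussian blur sigma in pixels (>= 0).
#' @param noise_sd Additive noise SD in intensity units (>= 0).
#' @param seed RNG seed (noise only).
#' @return A gray [angiogram()].
#' @export
render_angiogram <- function(truth, blur_sigma_px = 1.0, noise_sd = 5,
                             seed = 1L) {
  stopifnot(inherits(truth, "octa_binary"),
            blur_sigma_px >= 0, noise_sd >= 0)
  img <- matrix(as.numeric(truth$pixels) * 255, nrow_px(truth), nrow_px(truth))
  if (blur_sigma_px > 0) img <- gaussian_blur(img, blur_sigma_px)
  if (noise_sd > 0) {
    img <- with_seed(seed, img + stats::rnorm(length(img), 0, noise_sd))
  }
  angiogram(clamp(img, 0, 255), truth$geometry)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(mat) {
    n <- nrow(mat)
    pad <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                 mat[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(m))))
}

#' Baseline-to-follow-up effect model for the synthetic cohort
#'
#' Additive per-plexus density shifts applied between baseline and 1-month
#' follow-up, a FAZ area shift, and the SD of the per-eye change noise. The
#' default SCP shift of -0.014 is the reported 6 x 6 mm SCP change
#' (0.427 -> 0.413); DCP/CC/FAZ default to no change.
#'
#' @param scp_shift,dcp_shift,cc_shift Additive density changes.
#' @param faz_shift_mm2 Additive FAZ area change (mm^2).
#' @param noise_sd SD of per-eye change noise on the density scale (the
#'   longitudinal variability around the mean shift; default 0.015, chosen so
#'   a 16-eye paired Wilcoxon lands near the reported significance).
#' @return An object of class `octa_effect`.
#' @export
effect_model <- function(scp_shift = -0.014, dcp_shift = 0, cc_shift = 0,
                         faz_shift_mm2 = 0, noise_sd = 0.015) {
  stopifnot(noise_sd >= 0)
  structure(list(scp_shift = scp_shift, dcp_shift = dcp_shift,
                 cc_shift = cc_shift, faz_shift_mm2 = faz_shift_mm2,
                 noise_sd = noise_sd),
            class = "octa_effect")
}

default_baseline_params <- function(group = c("vmt", "control")) {
  group <- match.arg(group)
  list(
    scp = 0.427, dcp = 0.434, cc = 0.472,       # 6 x 6 mm baseline means
    between_eye_sd = 0.027,
    faz_area_mm2 = if (group == "vmt") 0.103 else 0.198,
    faz_sd_mm2 = if (group == "vmt") 0.031 else 0.074,
    vmt_diameter_um = if (group == "vmt") 800 else 0,
    age_mean = if (group == "vmt") 59.2 else 59.6,
    age_sd = if (group == "vmt") 3.4 else 1.4
  )
}

#' Generate a paired longitudinal synthetic cohort with ground truth
#'
#' For each eye: a per-eye true baseline density per plexus (Gaussian around
#' the group mean with between-eye SD 0.027), a follow-up density shifted by
#' the [effect_model()] plus per-eye change noise, a jittered FAZ polygon
#' (area ~0.103 mm^2 for VMT-like eyes, ~0.198 mm^2 for controls), a truth
#' network per eye x timepoint x plexus and (optionally) its noisy rendering.
#' Controls receive zero shifts. Ages are drawn per group; controls are
#' age-matched within +/- 1 year of their paired study subject.
#'
#' Everything is a pure function of `(parameters, seed)`; the ledger records
#' the achieved (pixel-exact) truth density of every image.
#'
#' @param n_eyes Eyes per group, >= 2.
#' @param geometry A [scan_geometry()].
#' @param effect An [effect_model()] (applied to the `"vmt"` group).
#' @param seed RNG seed.
#' @param groups Character subset of `c("vmt", "control")`.
#' @param plexuses Character subset of `c("SCP", "DCP", "CC")`.
#' @param render If `TRUE` attach noisy grayscale renderings; if `FALSE` only
#'   truth networks (faster).
#' @param blur_sigma_um Optical blur expressed in physical units (default 17
#'   um, about one pixel at the 6 x 6 mm / 350 px preset — the transverse PSF
#'   scale of the device). Converted to pixels per geometry, so scaled-down
#'   simulation grids are not over-blurred relative to the preset world.
#' @param blur_sigma_px Explicit pixel-unit override of `blur_sigma_um`.
#' @param noise_sd_px Additive intensity noise SD.
#' @param out_dir If non-`NULL`, write images (PNG), FAZ polygons (JSON), the
#'   cohort CSV and the ground-truth ledger (JSON) under this directory.
#' @return List of class `octa_cohort_sim`: `cohort` (tidy table: eye_id,
#'   group, age, timepoint, plexus, image_path or in-memory index),
#'   `images` (named list of angiograms, names `eyeid_timepoint_plexus`),
#'   `truths` (matching truth networks), `faz` (per eye x timepoint),
#'   `ledger` (data.frame of all ground truth), `geometry`.
#' @export
generate_cohort <- function(n_eyes = 16L, geometry = scan_geometry(6),
                            effect = effect_model(), seed = 1L,
                            groups = c("vmt", "control"),
                            plexuses = c("SCP", "DCP", "CC"),
                            render = TRUE, blur_sigma_um = 17,
                            blur_sigma_px = NULL, noise_sd_px = 5,
                            out_dir = NULL) {
  if (n_eyes < 2L) {
    abort_octa("n_eyes must be >= 2 (paired statistics are impossible otherwise)",
               "octa_bad_cohort")
  }
  groups <- match.arg(groups, several.ok = TRUE)
  plexuses <- match.arg(plexuses, c("SCP", "DCP", "CC"), several.ok = TRUE)
  stopifnot(inherits(effect, "octa_effect"))
  if (is.null(blur_sigma_px)) {
    blur_sigma_px <- blur_sigma_um / (geometry$px_scale_mm * 1000)
  }

  images <- list(); truths <- list(); faz_list <- list()
  rows <- list(); ledger <- list()
  center <- rep(geometry$extent_mm / 2, 2)

  with_seed(seed, {
    vmt_ages <- round(stats::rnorm(n_eyes, 59.2, 3.4))
    sub_seeds <- sample.int(2^30, n_eyes * length(groups) * 16L)
    si <- 0L
    nxt <- function() { si <<- si + 1L; sub_seeds[si] }

    for (g in groups) {
      bp <- default_baseline_params(g)
      eff <- if (g == "vmt") effect else effect_model(0, 0, 0, 0, effect$noise_sd)
      for (i in seq_len(n_eyes)) {
        eye_id <- sprintf("%s%02d", if (g == "vmt") "V" else "C", i)
        age <- if (g == "vmt") vmt_ages[i] else vmt_ages[i] + sample(-1:1, 1)
        faz_base_area <- max(0.02, stats::rnorm(1, bp$faz_area_mm2, bp$faz_sd_mm2))
        faz_fu_area <- max(0.02, faz_base_area + eff$faz_shift_mm2 +
                             stats::rnorm(1, 0, 0.25 * bp$faz_sd_mm2))
        true_base <- c(SCP = bp$scp, DCP = bp$dcp, CC = bp$cc) +
          stats::rnorm(3, 0, bp$between_eye_sd)
        shift <- c(SCP = eff$scp_shift, DCP = eff$dcp_shift, CC = eff$cc_shift)
        true_fu <- true_base + shift + stats::rnorm(3, 0, eff$noise_sd)
        true_base <- clamp(true_base, 0.05, 0.95)
        true_fu <- clamp(true_fu, 0.05, 0.95)

        for (tp in c("baseline", "month1")) {
          area <- if (tp == "baseline") faz_base_area else faz_fu_area
          faz <- synthetic_faz_polygon(area, center, seed = nxt())
          faz_list[[paste(eye_id, tp, sep = "_")]] <- faz
          dens <- if (tp == "baseline") true_base else true_fu
          for (pl in plexuses) {
            key <- paste(eye_id, tp, pl, sep = "_")
            net <- generate_vessel_network(geometry, dens[[pl]], faz,
                                           seed = nxt())
            truths[[key]] <- net
            if (render) {
              images[[key]] <- render_angiogram(net, blur_sigma_px,
                                                noise_sd_px, seed = nxt())
            }
            rows[[key]] <- data.frame(
              eye_id = eye_id, group = g, age = age, timepoint = tp,
              plexus = pl, extent_mm = geometry$extent_mm, image = key,
              stringsAsFactors = FALSE)
            ledger[[key]] <- data.frame(
              eye_id = eye_id, group = g, timepoint = tp, plexus = pl,
              target_density = dens[[pl]],
              true_density = attr(net, "achieved_density"),
              faz_area_mm2 = faz$area_mm2, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })

  sim <- structure(
    list(cohort = do.call(rbind, unname(rows)),
         images = images, truths = truths, faz = faz_list,
         ledger = do.call(rbind, unname(ledger)),
         geometry = geometry, effect = effect, seed = seed),
    class = "octa_cohort_sim")
  if (!is.null(out_dir)) write_cohort_sim(sim, out_dir)
  sim
}

#' @export
print.octa_cohort_sim <- function(x, ...) {
  cat(sprintf("<octa_cohort_sim> %d measurement slots (%d eyes x groups), seed %d\n",
              nrow(x$cohort), length(unique(x$cohort$eye_id)), x$seed))
  invisible(x)
}

#' Write a simulated cohort to disk (PNG images, JSON FAZ/ledger, CSV table)
#'
#' Produces the on-disk layout the `measure` pipeline stage consumes: one PNG
#' per eye x timepoint x plexus, one FAZ JSON per eye x timepoint, a cohort
#' CSV with columns `eye_id, group, age, timepoint, plexus, extent_mm,
#' image_path, faz_path`, and `ledger.json` with all ground truth.
#'
#' @param sim An `octa_cohort_sim`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the cohort CSV, invisibly.
#' @export
write_cohort_sim <- function(sim, out_dir) {
  stopifnot(inherits(sim, "octa_cohort_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- sim$cohort
  tab$image_path <- file.path(out_dir, paste0(tab$image, ".png"))
  tab$faz_path <- file.path(out_dir,
                            paste0(tab$eye_id, "_", tab$timepoint, "_faz.json"))
  for (i in seq_len(nrow(tab))) {
    key <- tab$image[i]
    img <- sim$images[[key]] %||% sim$truths[[key]]
    write_angiogram(img, tab$image_path[i])
  }
  for (key in names(sim$faz)) {
    write_faz(sim$faz[[key]], file.path(out_dir, paste0(key, "_faz.json")))
  }
  tab$image <- NULL
  csv <- file.path(out_dir, "cohort.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(sim$ledger, file.path(out_dir, "ledger.json"),
                       digits = NA, dataframe = "rows")
  invisible(csv)
}
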