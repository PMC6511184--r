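#' Pipeline configuration
#'
#' A serializable bundle of everything a `measure` run needs: the geometry
#' preset, threshold and projection method names, the RNG seed and the I/O
#' paths. Round-trips through JSON unchanged.
#'
#' @param input_csv Cohort CSV path (columns `eye_id, group, timepoint,
#'   plexus, extent_mm, image_path, faz_path`, optionally `age`,
#'   `ilm_path`, `rpe_path`).
#' @param out_dir Output directory.
#' @param extent_mm,n_px Geometry of all images.
#' @param threshold_method Currently `"mean"` (the macro's average threshold);
#'   the slot exists so alternative global thresholds can be plugged in.
#' @param projection_method `"max"` or `"mean"` (used only when projecting
#'   volumes; en-face inputs skip projection).
#' @param seed RNG seed recorded in the run log.
#' @return List of class `octa_config`.
#' @export
pipeline_config <- function(input_csv, out_dir, extent_mm = 6, n_px = NULL,
                            threshold_method = "mean",
                            projection_method = "max", seed = 1L) {
  g <- scan_geometry(extent_mm, n_px)
  structure(list(input_csv = input_csv, out_dir = out_dir,
                 extent_mm = g$extent_mm, n_px = g$n_px,
                 threshold_method = threshold_method,
                 projection_method = projection_method,
                 seed = as.integer(seed)),
            class = "octa_config")
}

#' @rdname pipeline_config
#' @param config An `octa_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "octa_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(obj$input_csv, obj$out_dir, obj$extent_mm, obj$n_px,
                  obj$threshold_method, obj$projection_method, obj$seed)
}

#' Run the measurement stage over a cohort CSV
#'
#' For every eye x timepoint: read the plexus images and the FAZ polygon, run
#' the macro path, and append tidy measurement rows. If surface-map columns
#' (`ilm_path`, `rpe_path`, CSV grids in um) are present, the slab QC is run
#' and eyes with any flagged A-scan are excluded from the measurement table
#' (the study's eye-level exclusion) and listed in the log. Unreadable files
#' are recorded as per-file errors and the run continues.
#'
#' @param config An [pipeline_config()].
#' @return List: `measurements` (data.frame), `log` (list with per-image
#'   thresholds, QC outcomes, errors, seed, package version). Also writes
#'   `measurements.csv` and `run_log.json` under `out_dir`.
#' @export
run_measure <- function(config) {
  stopifnot(inherits(config, "octa_config"))
  geometry <- scan_geometry(config$extent_mm, config$n_px)
  tab <- utils::read.csv(config$input_csv, stringsAsFactors = FALSE)
  need <- c("eye_id", "timepoint", "plexus", "image_path", "faz_path")
  if (!all(need %in% names(tab))) {
    abort_octa(paste("cohort CSV must have columns:", paste(need, collapse = ", ")),
               "octa_bad_cohort")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log <- list(seed = config$seed, threshold_method = config$threshold_method,
              package_version = as.character(utils::packageVersion("octaperf")),
              timestamp = format(Sys.time(), tz = "UTC"),
              thresholds = list(), qc = list(), errors = list(),
              excluded_eyes = character(0))
  out <- list()

  units <- split(tab, paste(tab$eye_id, tab$timepoint))
  for (u in units) {
    eye <- u$eye_id[1]; tp <- u$timepoint[1]
    # optional segmentation QC: exclude the whole eye-timepoint on failure
    if (all(c("ilm_path", "rpe_path") %in% names(u)) &&
        nzchar(u$ilm_path[1] %||% "") && !is.na(u$ilm_path[1])) {
      qc <- tryCatch({
        s <- surface_set(read_surface_grid(u$ilm_path[1]),
                         read_surface_grid(u$rpe_path[1]), geometry)
        validate_segmentation(derive_boundaries(s), s)
      }, error = function(e) {
        log$errors[[paste(eye, tp)]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(qc)) {
        log$qc[[paste(eye, tp)]] <- list(ok = qc$ok, reason = qc$reason,
                                         flagged = sum(qc$violation_mask))
        if (!qc$ok) {
          log$excluded_eyes <- union(log$excluded_eyes, eye)
          next
        }
      }
    }
    res <- tryCatch({
      faz <- read_faz(u$faz_path[1])
      imgs <- stats::setNames(as.list(u$image_path), u$plexus)
      m <- measure_eye(imgs, faz, geometry, eye, tp)
      for (i in seq_len(nrow(m))) {
        log$thresholds[[paste(eye, tp, m$plexus[i])]] <- m$threshold[i]
      }
      m$group <- u$group[match(m$plexus, u$plexus)] %||% NA
      if ("age" %in% names(u)) m$age <- u$age[1]
      m
    }, error = function(e) {
      log$errors[[paste(eye, tp)]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) out[[paste(eye, tp)]] <- res
  }

  measurements <- if (length(out)) do.call(rbind, unname(out)) else
    data.frame()
  if (nrow(measurements)) {
    measurements <- measurements[order(measurements$eye_id,
                                       measurements$timepoint,
                                       measurements$plexus), ]
    rownames(measurements) <- NULL
  }
  utils::write.csv(measurements,
                   file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(measurements = measurements, log = log)
}

#' Simulate, measure and report in one deterministic invocation
#'
#' Generates a paired synthetic cohort (study + control groups), writes it to
#' disk, runs the measurement stage on the written images, and summarizes the
#' measured densities into the report tables. The seed fully determines every
#' output.
#'
#' @param n_eyes Eyes per group.
#' @param effect An [effect_model()] applied to the study group.
#' @param extent_mm,n_px Scan geometry (defaults to the 6 x 6 mm preset).
#' @param seed RNG seed.
#' @param out_dir Working directory for images and tables (default: a
#'   tempdir subdirectory).
#' @param groups,plexuses Passed to [generate_cohort()].
#' @return List: `report` (an `octa_report`), `measurements`, `ledger`,
#'   `paths` (cohort CSV, measurement CSV, report Markdown).
#' @export
run_end_to_end <- function(n_eyes = 16L, effect = effect_model(),
                           extent_mm = 6, n_px = NULL, seed = 1L,
                           out_dir = file.path(tempdir(), "octaperf_run"),
                           groups = c("vmt", "control"),
                           plexuses = c("SCP", "DCP", "CC")) {
  geometry <- scan_geometry(extent_mm, n_px)
  sim <- generate_cohort(n_eyes, geometry, effect, seed = seed,
                         groups = groups, plexuses = plexuses,
                         out_dir = out_dir)
  cfg <- pipeline_config(file.path(out_dir, "cohort.csv"), out_dir,
                         extent_mm = geometry$extent_mm, n_px = geometry$n_px,
                         seed = seed)
  mres <- run_measure(cfg)
  report <- summarize_cohort(mres$measurements)
  md_path <- file.path(out_dir, "report.md")
  writeLines(format_report_markdown(report), md_path)
  utils::write.csv(report$density, file.path(out_dir, "report_density.csv"),
                   row.names = FALSE)
  list(report = report, measurements = mres$measurements, ledger = sim$ledger,
       paths = list(cohort_csv = file.path(out_dir, "cohort.csv"),
                    measurements_csv = file.path(out_dir, "measurements.csv"),
                    report_md = md_path))
}
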