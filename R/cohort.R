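#' Summarize a measured cohort into the study's report tables
#'
#' For each scan extent and plexus, reports per group the baseline and 1-month
#' mean +/- SD of FAZ-subtracted perfusion density, the within-group paired
#' Wilcoxon p (baseline vs month 1, eyes with both timepoints), and the
#' between-group Mann-Whitney p at each timepoint. A companion FAZ table does
#' the same for SCP FAZ area. No multiple-testing correction is applied; the
#' number of tests run is recorded in the result.
#'
#' @param cohort Tidy data.frame with columns `eye_id`, `group`, `timepoint`
#'   (`baseline`/`month1`), `plexus`, `extent_mm`, `density` and optionally
#'   `faz_area_mm2`, `age`. One row per eye x timepoint x plexus x extent.
#' @param stratify_by Optional extra grouping column name (e.g. an anatomical
#'   success flag) producing the success-stratified table variant.
#' @return List of class `octa_report`: `density` (summary data.frame), `faz`
#'   (FAZ area summary or NULL), `n_tests`, `incomplete` (eyes missing a
#'   timepoint).
#' @export
summarize_cohort <- function(cohort, stratify_by = NULL) {
  need <- c("eye_id", "group", "timepoint", "plexus", "extent_mm", "density")
  if (!all(need %in% names(cohort))) {
    abort_octa(paste("cohort table must have columns:",
                     paste(need, collapse = ", ")), "octa_bad_cohort")
  }
  if (!is.null(stratify_by)) {
    cohort$group <- paste(cohort$group, cohort[[stratify_by]], sep = "/")
  }
  key <- paste(cohort$eye_id, cohort$timepoint, cohort$plexus, cohort$extent_mm)
  if (anyDuplicated(key)) {
    abort_octa("duplicate (eye, timepoint, plexus, extent) rows", "octa_bad_cohort")
  }

  n_tests <- 0L
  fmt_rows <- list()
  incomplete <- character(0)

  for (ext in sort(unique(cohort$extent_mm))) {
    for (pl in intersect(c("SCP", "DCP", "CC"), unique(cohort$plexus))) {
      sub <- cohort[cohort$extent_mm == ext & cohort$plexus == pl, ]
      for (g in unique(sub$group)) {
        gs <- sub[sub$group == g, ]
        base <- gs[gs$timepoint == "baseline", ]
        fu <- gs[gs$timepoint == "month1", ]
        paired_ids <- intersect(base$eye_id, fu$eye_id)
        lone <- setdiff(union(base$eye_id, fu$eye_id), paired_ids)
        incomplete <- union(incomplete, lone)
        p_paired <- NA_real_
        if (length(paired_ids) >= 1L) {
          b <- base$density[match(paired_ids, base$eye_id)]
          f <- fu$density[match(paired_ids, fu$eye_id)]
          p_paired <- wilcoxon_signed_rank(f, b)$p_value
          n_tests <- n_tests + 1L
        }
        fmt_rows[[length(fmt_rows) + 1L]] <- data.frame(
          extent_mm = ext, plexus = pl, group = g,
          n = length(paired_ids),
          baseline_mean = mean(base$density), baseline_sd = stats::sd(base$density),
          month1_mean = mean(fu$density), month1_sd = stats::sd(fu$density),
          p_paired = p_paired, complete = length(lone) == 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  density <- do.call(rbind, fmt_rows)

  # between-group columns (only when exactly two groups are present)
  groups <- unique(cohort$group)
  if (length(groups) == 2L) {
    density$p_between_baseline <- NA_real_
    density$p_between_month1 <- NA_real_
    for (i in seq_len(nrow(density))) {
      sub <- cohort[cohort$extent_mm == density$extent_mm[i] &
                      cohort$plexus == density$plexus[i], ]
      for (tp in c("baseline", "month1")) {
        a <- sub$density[sub$group == groups[1] & sub$timepoint == tp]
        b <- sub$density[sub$group == groups[2] & sub$timepoint == tp]
        if (length(a) && length(b)) {
          col <- paste0("p_between_", tp)
          density[[col]][i] <- mann_whitney(a, b)$p_value
        }
      }
    }
    # each plexus x extent x timepoint contributes one between-group test
    n_tests <- n_tests + 2L * nrow(unique(density[, c("extent_mm", "plexus")]))
  }

  faz_tab <- NULL
  if ("faz_area_mm2" %in% names(cohort) && any(!is.na(cohort$faz_area_mm2))) {
    fz <- cohort[cohort$plexus == "SCP" & !is.na(cohort$faz_area_mm2), ]
    if (nrow(fz)) {
      faz_rows <- lapply(unique(fz$group), function(g) {
        gs <- fz[fz$group == g, ]
        base <- gs[gs$timepoint == "baseline", ]
        fu <- gs[gs$timepoint == "month1", ]
        ids <- intersect(base$eye_id, fu$eye_id)
        p <- if (length(ids)) {
          n_tests <<- n_tests + 1L
          wilcoxon_signed_rank(fu$faz_area_mm2[match(ids, fu$eye_id)],
                               base$faz_area_mm2[match(ids, base$eye_id)])$p_value
        } else NA_real_
        data.frame(group = g, n = length(ids),
                   baseline_mean = mean(base$faz_area_mm2),
                   baseline_sd = stats::sd(base$faz_area_mm2),
                   month1_mean = mean(fu$faz_area_mm2),
                   month1_sd = stats::sd(fu$faz_area_mm2),
                   p_paired = p, stringsAsFactors = FALSE)
      })
      faz_tab <- do.call(rbind, faz_rows)
    }
  }

  structure(list(density = density, faz = faz_tab, n_tests = n_tests,
                 incomplete = incomplete),
            class = "octa_report")
}

#' @export
print.octa_report <- function(x, ...) {
  cat("Perfusion density (mean ± SD), after subtracting the FAZ\n")
  d <- x$density
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %gx%g mm %-3s %-12s %s -> %s  p(paired) = %s\n",
                d$extent_mm[i], d$extent_mm[i], d$plexus[i], d$group[i],
                fmt_msd(d$baseline_mean[i], d$baseline_sd[i]),
                fmt_msd(d$month1_mean[i], d$month1_sd[i]),
                fmt_p(d$p_paired[i])))
  }
  if (!is.null(x$faz)) {
    cat("FAZ area, SCP (mm^2)\n")
    for (i in seq_len(nrow(x$faz))) {
      cat(sprintf("  %-12s %s -> %s  p(paired) = %s\n", x$faz$group[i],
                  fmt_msd(x$faz$baseline_mean[i], x$faz$baseline_sd[i]),
                  fmt_msd(x$faz$month1_mean[i], x$faz$month1_sd[i]),
                  fmt_p(x$faz$p_paired[i])))
    }
  }
  cat(sprintf("(%d tests performed, no multiplicity correction)\n", x$n_tests))
  invisible(x)
}

fmt_msd <- function(m, s) {
  if (is.na(m)) return("--")
  sprintf("%.3f ± %.3f", m, if (is.na(s)) 0 else s)
}
fmt_p <- function(p) if (is.na(p)) "--" else sprintf("%.4f", p)

#' Render a report as Markdown tables
#' @param report An `octa_report`.
#' @return Character vector of Markdown lines.
#' @export
format_report_markdown <- function(report) {
  stopifnot(inherits(report, "octa_report"))
  d <- report$density
  lines <- c("## Perfusion density (mean ± SD), FAZ subtracted", "",
             "| Extent | Plexus | Group | Baseline | 1 month | p (paired) |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(d))) {
    lines <- c(lines, sprintf(
      "| %g mm | %s | %s | %s | %s | %s |",
      d$extent_mm[i], d$plexus[i], d$group[i],
      fmt_msd(d$baseline_mean[i], d$baseline_sd[i]),
      fmt_msd(d$month1_mean[i], d$month1_sd[i]), fmt_p(d$p_paired[i])))
  }
  if (!is.null(report$faz)) {
    lines <- c(lines, "", "## FAZ area, SCP (mm²)", "",
               "| Group | Baseline | 1 month | p (paired) |", "|---|---|---|---|")
    for (i in seq_len(nrow(report$faz))) {
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s |", report$faz$group[i],
        fmt_msd(report$faz$baseline_mean[i], report$faz$baseline_sd[i]),
        fmt_msd(report$faz$month1_mean[i], report$faz$month1_sd[i]),
        fmt_p(report$faz$p_paired[i])))
    }
  }
  c(lines, "", sprintf("%d tests performed; no multiplicity correction.",
                       report$n_tests))
}
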