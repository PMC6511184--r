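test_that("Wilcoxon signed rank: hand cases", {
  expect_identical(wilcoxon_signed_rank(c(3, 3, 3), c(3, 3, 3))$p_value, 1.0)
  # 5 strictly positive differences: two-sided exact p = 2/2^5
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_identical(r$p_value, 0.0625)
  expect_identical(r$statistic, 15)
  expect_match(r$method, "exact")
})

test_that("Wilcoxon exact p matches full enumeration for n <= 10 (incl. ties/zeros)", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- sample(-4:4, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    expect_identical(wilcoxon_signed_rank(d)$p_value, oracle_wilcoxon(d))
  }
  # agreement with stats::wilcox.test on untied nonzero data
  for (i in 1:15) {
    d <- round(rnorm(sample(4:10, 1)), 6)
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney: hand cases and enumeration oracle", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  expect_identical(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)

  set.seed(23)
  for (i in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    expect_identical(mann_whitney(a, b)$p_value, oracle_mann_whitney(a, b))
    expect_equal(mann_whitney(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Spearman: monotone extremes, permutation oracle, constant input", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_identical(spearman_rank(x, x * 2 + 1)$rho, 1)
  expect_identical(spearman_rank(x, rev(x))$rho, -1)

  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    r <- spearman_rank(x, y)
    expect_identical(r$test$p_value, oracle_spearman_p(x, y))
  }
  r0 <- spearman_rank(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(r0$rho))
  expect_match(r0$test$method, "constant")
})

test_that("noncentral-t power reproduces the study-size arithmetic", {
  # N = 32 (16/group), d = 1.1 -> power 0.85
  expect_lt(abs(power_two_sample_t(1.1, 16, 0.05) - 0.85), 0.02)
  # 30%-reduced effect with 32/group still reaches power 0.8
  expect_gte(power_two_sample_t(0.77, 32, 0.05), 0.80)
  # null effect: power equals the significance level
  expect_equal(power_two_sample_t(0, 16, 0.05), 0.05, tolerance = 1e-9)

  # strict monotonicity in effect size and group size
  d_grid <- seq(0, 2, by = 0.25)
  p_d <- sapply(d_grid, power_two_sample_t, n_per_group = 16)
  expect_true(all(diff(p_d) > 0))
  n_grid <- c(4, 8, 16, 32, 64)
  p_n <- sapply(n_grid, function(n) power_two_sample_t(0.8, n))
  expect_true(all(diff(p_n) > 0))

  expect_error(power_two_sample_t(1, 16, alpha = 0), "alpha")

  # Monte-Carlo cross-check (small reps here; acceptance runs 20k)
  expect_lt(abs(power_two_sample_t_mc(1.1, 16, reps = 4000, seed = 2) -
                  power_two_sample_t(1.1, 16)), 0.025)
})

test_that("age matching: hand cases and the constructive property", {
  expect_true(validate_age_matching(c(59, 60), c(59, 61))$ok)
  expect_false(validate_age_matching(50, 60)$ok)
  res <- validate_age_matching(c(55, 60), c(55, 60, 61))
  expect_false(res$ok)
  expect_match(res$reason, "sizes differ")

  set.seed(13)
  for (i in 1:25) {
    study <- round(rnorm(16, 59.2, 3.4))
    control <- sample(study + sample(-1:1, 16, replace = TRUE))
    expect_true(validate_age_matching(study, control)$ok)
  }
})

test_that("summarize_cohort formats the report tables and degenerate cohorts", {
  eyes <- sprintf("V%02d", 1:6)
  base <- expand.grid(eye_id = eyes, timepoint = c("baseline", "month1"),
                      plexus = c("SCP", "DCP", "CC"),
                      stringsAsFactors = FALSE)
  base$group <- "vmt"; base$extent_mm <- 6
  base$density <- 0.42                      # identical eyes
  base$faz_area_mm2 <- ifelse(base$plexus == "SCP", 0.1, NA)
  rep1 <- summarize_cohort(base)
  expect_true(all(rep1$density$baseline_sd == 0))
  expect_true(all(rep1$density$p_paired == 1))
  expect_identical(rep1$faz$p_paired, 1.0)
  expect_true(all(rep1$density$complete))

  expect_error(summarize_cohort(rbind(base, base[1, ])), "duplicate")

  # two groups gain between-group columns; markdown renderer runs
  ctrl <- base; ctrl$group <- "control"; ctrl$eye_id <- sub("V", "C", ctrl$eye_id)
  ctrl$density <- 0.44
  rep2 <- summarize_cohort(rbind(base, ctrl))
  expect_true(all(c("p_between_baseline", "p_between_month1") %in%
                    names(rep2$density)))
  md <- format_report_markdown(rep2)
  expect_true(any(grepl("^\\| 6 mm \\| SCP", md)))

  # stratified variant (success-subgroup table layout)
  base$success <- rep(c("resolved", "persistent"), 3)[match(base$eye_id, eyes)]
  rep3 <- summarize_cohort(base, stratify_by = "success")
  expect_identical(sort(unique(rep3$density$group)),
                   c("vmt/persistent", "vmt/resolved"))
})
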