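# Per-course pipeline, cohort analytics, paired tests and file I/O.

test_that("attainment bins use a closed 30-40 band and a strict trough limit", {
  expect_equal(attainment_class(24.6, 0.1),
               list(cmax_bin = "below", cmin_ok = TRUE))
  expect_equal(attainment_class(30.0, 0.5),
               list(cmax_bin = "in_range", cmin_ok = FALSE))
  expect_equal(attainment_class(40.0, 0.49),
               list(cmax_bin = "in_range", cmin_ok = TRUE))
  expect_equal(attainment_class(40.01, 0.49),
               list(cmax_bin = "above", cmin_ok = TRUE))
})

test_that("dose changes classify exactly and report deltas", {
  expect_equal(dose_change_class(500, 650), list(change = "increase",
                                                 delta = 150))
  expect_equal(dose_change_class(500, 500), list(change = "unchanged",
                                                 delta = 0))
  expect_equal(dose_change_class(600, 525), list(change = "decrease",
                                                 delta = -75))
  expect_equal(dose_change_class(500, NA)$change, "not_adjusted")
})

test_that("AKI marker is a >= 50% creatinine rise; missing is unevaluable", {
  expect_true(aki_flag(76, 139))
  expect_false(aki_flag(100, 149))
  expect_true(aki_flag(100, 150))
  expect_true(is.na(aki_flag(100, NA)))
})

test_that("signed-rank test matches exhaustive enumeration for n <= 10", {
  for (n in 4:10) {
    mags <- seq_len(n) + 0.5  # tieless magnitudes
    patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (k in seq_len(nrow(patterns))) {
      d <- mags * patterns[k, ]
      got <- wilcoxon_signed_rank(rep(0, n), d)
      want <- enum_signed_rank(d)
      expect_equal(got$statistic, want$statistic)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    }
  }
})

test_that("signed-rank edge cases follow the stated conventions", {
  # six all-positive differences: exact two-sided p = 2/64
  expect_equal(wilcoxon_signed_rank(rep(0, 6), 1:6)$p_value, 2 / 64)
  # perfectly antisymmetric differences sit at the null centre
  r <- wilcoxon_signed_rank(rep(0, 6), c(1, -1, 2, -2, 3, -3))
  expect_gt(r$p_value, 0.99)
  # zero differences are dropped
  expect_equal(wilcoxon_signed_rank(c(5, 5, 5, 0), c(5, 5, 5, 4))$n, 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
  # a strongly shifted large sample is highly significant
  set.seed(3)
  x <- rnorm(60)
  expect_lt(wilcoxon_signed_rank(x, x + 2)$p_value, 1e-3)
})

test_that("noiseless course round-trips through the full pipeline", {
  prior <- tiny_prior()
  cov <- ref_patient()
  truth <- prior$points[50, ]
  course <- make_course(truth, cov, c(48 + 1.05, 48 + 24), noise_cv = 0,
                        reg = once_daily_regimen(500, 4))
  res <- run_course(course, prior)
  expect_lt(res$fit$metrics$median_ape, 0.1)
  # recommended dose within one grid step of the analytic optimum
  tru_a <- cmax_mod(individual_params(truth, cov), 1)
  expect_lt(abs(res$recommendation$table$dose_grid[1] - 30 / tru_a), 25 + 1e-9)
  # determinism: identical inputs give identical outputs
  expect_identical(res, run_course(course, prior))
})

test_that("an all-BLQ course still runs and is flagged low-information", {
  prior <- tiny_prior()
  cov <- ref_patient()
  course <- course_record("P", "C", cov, reg = once_daily_regimen(500, 4),
                          observations = data.frame(time = c(49, 72),
                                                    conc = c(0.05, 0.0)),
                          initial_dose = 500)
  res <- run_course(course, prior)
  expect_true(any(grepl("low-information", res$fit$warnings)))
  expect_equal(sum(res$posterior$points$weight), 1, tolerance = 1e-12)
})

test_that("cohort summary recomputes proportions from per-course classes", {
  set.seed(61)
  prior <- tiny_prior()
  cfg <- synth_config(n_patients = 12L, n_repeat = 2L, seed = 99L)
  g <- generate_cohort(cfg, prior)
  res <- lapply(g$courses, run_course, prior = prior)
  # physician behaviour stub: accept the 30 mg/L grid dose
  for (i in seq_along(g$courses))
    g$courses[[i]]$accepted_dose <- res[[i]]$recommendation$table$dose_grid[1]
  s <- cohort_summary(g$courses, res)
  expect_equal(s$n_courses, 14)
  expect_equal(s$n_patients, 12)
  expect_equal(s$attainment$cmax_below + s$attainment$cmax_in_range +
                 s$attainment$cmax_above, 1)
  # proportions recompute exactly from the per-course classification list
  cm <- vapply(res, function(r) r$fit$est_cmax_mod_initial, numeric(1))
  expect_equal(s$attainment$cmax_below, mean(cm < 30))
  expect_equal(s$dose_changes$unchanged + s$dose_changes$increased +
                 s$dose_changes$decreased + s$dose_changes$not_adjusted, 14)
  expect_equal(sum(s$dose_changes$table$n), 14)
  # missing end-of-therapy creatinine courses are counted, never imputed
  n_missing <- sum(vapply(g$courses, function(x)
    is.na(x$cov_end$scr), logical(1)))
  expect_equal(s$aki$unevaluable, n_missing)
  # a single-course cohort has degenerate proportions
  s1 <- cohort_summary(g$courses[1], res[1])
  expect_true(all(unlist(s1$attainment) %in% c(0, 1)))
})

test_that("course CSV round-trips dosing, observations and covariates", {
  prior <- tiny_prior()
  cfg <- synth_config(n_patients = 4L, n_repeat = 1L, seed = 5L)
  g <- generate_cohort(cfg, prior)
  g$courses[[2]]$accepted_dose <- 575
  path <- tempfile(fileext = ".csv")
  write_courses(g$courses, path)
  back <- read_courses(path)
  expect_equal(length(back), length(g$courses))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$regimen$events, g$courses[[i]]$regimen$events)
    expect_equal(back[[i]]$observations$conc, g$courses[[i]]$observations$conc)
    expect_equal(back[[i]]$cov_start$scr, g$courses[[i]]$cov_start$scr)
    expect_equal(back[[i]]$cov_start$clcr, g$courses[[i]]$cov_start$clcr)
    expect_equal(back[[i]]$initial_dose, g$courses[[i]]$initial_dose)
    expect_equal(back[[i]]$accepted_dose, g$courses[[i]]$accepted_dose)
  }
  # identical writes are byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_courses(g$courses, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("prior JSON round-trips and renormalises off-scale weights", {
  prior <- tiny_prior(50)
  path <- tempfile(fileext = ".json")
  write_prior(prior, path)
  back <- read_prior(path)
  expect_equal(back$points, prior$points, tolerance = 1e-12)
  expect_equal(back$bounds, prior$bounds)
  # weights off by more than 1e-6 are renormalised with a warning
  skew <- prior
  skew$points$weight <- skew$points$weight * 1.5
  write_prior(skew, path)
  expect_warning(back2 <- read_prior(path), "renormalising")
  expect_equal(sum(back2$points$weight), 1, tolerance = 1e-12)
})
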