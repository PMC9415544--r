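# Per-course pipeline and cohort analytics: course records, CSV I/O,
# attainment bins, dose-change classification, AKI flags, paired tests and
# cohort summary tables.

#' One tobramycin course
#'
#' A course bundles the recorded dosing history (actual infusion start
#' times and durations), the TDM observations, covariates at the start and
#' end of therapy, and the dose bookkeeping: the physician's initial dose
#' and, once known, the dose finally accepted after the model-based
#' recommendation.
#'
#' @param patient_id,course_id Identifiers.
#' @param cov_start [covariate_set()] at therapy onset.
#' @param cov_end [covariate_set()] at end of therapy; serum creatinine may
#'   be `NA` (missing end-of-therapy sample).
#' @param reg A [regimen()] with the recorded events.
#' @param observations `data.frame` with columns `time` (h), `conc` (mg/L)
#'   and `role` (`"peak"`, `"trough"`, `"other"`).
#' @param initial_dose Physician's initial once-daily dose, mg.
#' @param accepted_dose Dose selected after the recommendation, mg, or `NA`.
#' @return A `course_record`.
#' @export
course_record <- function(patient_id, course_id, cov_start, cov_end = NULL,
                          reg, observations, initial_dose,
                          accepted_dose = NA_real_) {
  stopifnot(inherits(cov_start, "covariate_set"), inherits(reg, "regimen"),
            initial_dose > 0)
  stopifnot(all(c("time", "conc") %in% names(observations)))
  if (is.null(observations$role))
    observations$role <- rep("other", nrow(observations))
  span <- max(reg$events$start_time + reg$events$infusion_duration) +
    reg$interval
  if (any(observations$time < 0 | observations$time > span))
    stop("observations outside the course time span", call. = FALSE)
  structure(list(patient_id = patient_id, course_id = course_id,
                 cov_start = cov_start, cov_end = cov_end,
                 regimen = reg, observations = observations,
                 initial_dose = initial_dose, accepted_dose = accepted_dose),
            class = "course_record")
}

#' Run the full per-course pipeline
#'
#' BLQ substitution, Bayesian posterior over the prior's support points
#' (escalating to [hybrid_fit()] when more than half the posterior mass
#' sits on boundary points or the median absolute percentage error exceeds
#' 20%), point estimates and fit diagnostics, then the three-level dose
#' recommendation. Deterministic given its inputs.
#'
#' @param course A [course_record()].
#' @param prior A [discrete_prior()].
#' @param err An [assay_error_model()].
#' @param spec A [target_spec()].
#' @return List with elements `fit` (metrics, estimates, the estimated
#'   standardised peak and 24-h trough at the initial dose from the modal
#'   support point, `hybrid_used`, warnings), `recommendation`
#'   (a `dose_recommendation`) and `posterior`.
#' @export
run_course <- function(course, prior, err = assay_error_model(),
                       spec = target_spec()) {
  course$observations <- preprocess_blq(course$observations)
  warn <- character(0)
  if (all(course$observations$blq))
    warn <- c(warn, "all observations below the quantification limit; fit is low-information")
  post <- tryCatch(posterior_weights(prior, course, err),
                   error = function(e) NULL)
  if (is.null(post)) {
    # no support point explains the data at all: straight to the hybrid fit
    post <- hybrid_fit(prior, course, err)
  }
  est <- point_estimates(post, course)
  met <- fit_metrics(course$observations$conc, est$predicted)
  if (!post$hybrid_used &&
      (boundary_mass(post) > 0.5 ||
       (is.finite(met$median_ape) && met$median_ape > 20))) {
    post <- hybrid_fit(prior, course, err)
    est <- point_estimates(post, course)
    met <- fit_metrics(course$observations$conc, est$predicted)
  }
  rec <- recommend_dose(post, course$cov_start, spec)
  list(fit = list(metrics = met, estimates = est,
                  est_cmax_mod_initial = cmax_mod(est$map,
                                                  course$initial_dose,
                                                  n_doses = spec$n_ss),
                  est_cmin24_initial = cmin_24(est$map, course$initial_dose,
                                               n_doses = spec$n_ss),
                  hybrid_used = post$hybrid_used, warnings = warn),
       recommendation = rec,
       posterior = post)
}

#' Target-attainment class of a course
#'
#' Bins the standardised peak against the 30-40 mg/L band (closed
#' interval) and flags the 24-h trough against the strict 0.5 mg/L limit.
#'
#' @param cmax Standardised peak, mg/L.
#' @param cmin 24-h trough, mg/L.
#' @param spec A [target_spec()].
#' @return List with `cmax_bin` (`"below"`, `"in_range"`, `"above"`) and
#'   `cmin_ok`.
#' @export
attainment_class <- function(cmax, cmin, spec = target_spec()) {
  stopifnot(cmax >= 0, cmin >= 0)
  bin <- if (cmax < spec$cmax_low) "below"
  else if (cmax <= spec$cmax_high) "in_range"
  else "above"
  list(cmax_bin = bin, cmin_ok = cmin < spec$cmin_limit)
}

#' Dose-change classification
#'
#' Compares the physician's initial dose with the dose finally accepted
#' after the recommendation. A missing accepted dose is reported as
#' `"not_adjusted"` and excluded from paired tests.
#'
#' @param initial,accepted Doses, mg.
#' @return List with `change` (`"unchanged"`, `"increase"`, `"decrease"`,
#'   `"not_adjusted"`) and `delta` (mg, `NA` when not adjusted).
#' @export
dose_change_class <- function(initial, accepted) {
  stopifnot(initial > 0)
  if (is.na(accepted))
    return(list(change = "not_adjusted", delta = NA_real_))
  stopifnot(accepted > 0)
  change <- if (accepted > initial) "increase"
  else if (accepted < initial) "decrease"
  else "unchanged"
  list(change = change, delta = accepted - initial)
}

#' Acute-kidney-injury marker
#'
#' A rise in serum creatinine of at least 50% from baseline during therapy
#' flags the course; a missing end-of-therapy creatinine makes the course
#' unevaluable (`NA`), counted separately and never imputed.
#'
#' @param scr_start,scr_end Serum creatinine, umol/L; `scr_end` may be `NA`.
#' @return `TRUE`, `FALSE` or `NA` (unevaluable).
#' @export
aki_flag <- function(scr_start, scr_end) {
  stopifnot(scr_start > 0)
  if (is.na(scr_end)) return(NA)
  stopifnot(scr_end > 0)
  (scr_end - scr_start) / scr_start >= 0.5
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired signed-rank test: zero differences are dropped
#' (Wilcoxon's convention), the exact null distribution is used for up to
#' 25 tieless differences, and the normal approximation with tie and
#' continuity corrections otherwise.
#'
#' @param before,after Equal-length paired measurements.
#' @return List with `statistic` (V, sum of positive ranks), `p_value` and
#'   `n` (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(before, after) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0)
    stop("undefined test: all paired differences are zero", call. = FALSE)
  ties <- any(duplicated(abs(nz)))
  use_exact <- length(nz) <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(nz))
}

#' Cohort-level summary
#'
#' Assembles the study-style tables from a list of processed courses:
#' demographics, attainment proportions of the estimated standardised peak
#' at the initial dose (below 30 / 30-40 / above 40 mg/L) and of the
#' expected trough, the dose-change table stratified by peak bin with
#' medians and ranges, AKI counts, and the paired Wilcoxon tests on doses
#' and serum creatinine.
#'
#' @param courses List of [course_record()]s (with `accepted_dose` filled
#'   where known).
#' @param results Matching list of [run_course()] outputs.
#' @param spec A [target_spec()].
#' @return A `cohort_summary` list.
#' @export
cohort_summary <- function(courses, results, spec = target_spec()) {
  stopifnot(length(courses) == length(results), length(courses) >= 1)
  n <- length(courses)
  num <- function(f) vapply(courses, f, numeric(1))
  weight <- num(function(x) x$cov_start$weight)
  age <- num(function(x) x$cov_start$age)
  clcr <- num(function(x) x$cov_start$clcr)
  initial <- num(function(x) x$initial_dose)
  accepted <- num(function(x) x$accepted_dose)
  cmax_mod_i <- vapply(results, function(r)
    r$fit$est_cmax_mod_initial, numeric(1))
  cmin_i <- vapply(results, function(r)
    r$fit$est_cmin24_initial, numeric(1))
  ape <- unlist(lapply(results, function(r) r$fit$metrics$ape))
  pe <- unlist(lapply(results, function(r) r$fit$metrics$pe))

  cls <- lapply(seq_len(n), function(i)
    attainment_class(cmax_mod_i[i], cmin_i[i], spec))
  bins <- vapply(cls, `[[`, character(1), "cmax_bin")
  cmin_ok <- vapply(cls, `[[`, logical(1), "cmin_ok")

  chg <- lapply(seq_len(n), function(i)
    dose_change_class(initial[i], accepted[i]))
  change <- vapply(chg, `[[`, character(1), "change")
  delta <- vapply(chg, `[[`, numeric(1), "delta")

  # Table-3-style stratification: peak bin x dose-change class
  strata <- c("below", "in_low", "in_high", "above")
  strat_bin <- ifelse(cmax_mod_i < spec$cmax_low, "below",
                ifelse(cmax_mod_i <= spec$cmax_mid, "in_low",
                 ifelse(cmax_mod_i <= spec$cmax_high, "in_high", "above")))
  dose_change_table <- do.call(rbind, lapply(strata, function(s) {
    sel <- strat_bin == s
    up <- delta[sel & change == "increase"]
    dn <- delta[sel & change == "decrease"]
    data.frame(cmax_bin = s, n = sum(sel),
               unchanged = sum(sel & change == "unchanged"),
               increased = length(up),
               increase_median = if (length(up)) stats::median(up) else NA,
               increase_min = if (length(up)) min(up) else NA,
               increase_max = if (length(up)) max(up) else NA,
               decreased = length(dn),
               decrease_median = if (length(dn))
                 stats::median(abs(dn)) else NA)
  }))

  # expected attainment after the physicians' decision
  adjusted <- which(!is.na(accepted))
  pred_acc <- vapply(adjusted, function(i)
    unname(predict_for_dose(results[[i]]$posterior, courses[[i]]$cov_start,
                            accepted[i], spec)["cmax_mod"]), numeric(1))
  expected_attain <- if (length(adjusted))
    mean(pred_acc >= spec$cmax_low & pred_acc <= spec$cmax_high) else NA_real_

  aki <- vapply(courses, function(x)
    aki_flag(x$cov_start$scr, if (is.null(x$cov_end)) NA else x$cov_end$scr),
    logical(1))

  dose_test <- if (sum(accepted[adjusted] != initial[adjusted]) >= 1)
    wilcoxon_signed_rank(initial[adjusted], accepted[adjusted]) else NULL
  scr_start <- num(function(x) x$cov_start$scr)
  scr_end <- vapply(courses, function(x)
    if (is.null(x$cov_end)) NA_real_ else x$cov_end$scr, numeric(1))
  pairs_ok <- !is.na(scr_end)
  scr_test <- if (sum(pairs_ok) >= 6 &&
                  any(scr_end[pairs_ok] != scr_start[pairs_ok]))
    wilcoxon_signed_rank(scr_start[pairs_ok], scr_end[pairs_ok]) else NULL

  structure(list(
    n_courses = n,
    n_patients = length(unique(vapply(courses, function(x)
      as.character(x$patient_id), character(1)))),
    demographics = list(
      age = c(mean = mean(age), sd = stats::sd(age)),
      weight = c(mean = mean(weight), sd = stats::sd(weight)),
      clcr = c(mean = mean(clcr), sd = stats::sd(clcr)),
      initial_dose_mg = c(mean = mean(initial), sd = stats::sd(initial)),
      initial_dose_mg_kg = c(mean = mean(initial / weight),
                             sd = stats::sd(initial / weight))),
    fit = list(median_ape = stats::median(ape), median_pe = stats::median(pe),
               n_hybrid = sum(vapply(results, function(r)
                 r$fit$hybrid_used, logical(1)))),
    attainment = list(
      cmax_below = mean(bins == "below"),
      cmax_in_range = mean(bins == "in_range"),
      cmax_above = mean(bins == "above"),
      cmin_ok = mean(cmin_ok)),
    expected_attainment_after = expected_attain,
    dose_changes = list(per_course = change, table = dose_change_table,
                        unchanged = sum(change == "unchanged"),
                        increased = sum(change == "increase"),
                        decreased = sum(change == "decrease"),
                        not_adjusted = sum(change == "not_adjusted")),
    aki = list(n = sum(aki, na.rm = TRUE),
               prop = mean(aki, na.rm = TRUE),
               unevaluable = sum(is.na(aki))),
    tests = list(dose = dose_test, creatinine = scr_test)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d courses in %d patients\n", x$n_courses,
              x$n_patients))
  d <- x$demographics
  cat(sprintf("  weight %.1f +/- %.1f kg, CLcr %.1f +/- %.1f mL/min\n",
              d$weight["mean"], d$weight["sd"], d$clcr["mean"],
              d$clcr["sd"]))
  cat(sprintf("  initial dose %.2f +/- %.2f mg/kg\n",
              d$initial_dose_mg_kg["mean"], d$initial_dose_mg_kg["sd"]))
  cat(sprintf("  fit: median APE %.1f%%, median PE %.2f mg/L (%d hybrid fits)\n",
              x$fit$median_ape, x$fit$median_pe, x$fit$n_hybrid))
  a <- x$attainment
  cat(sprintf("  estimated peak at initial dose: %.1f%% below / %.1f%% in 30-40 / %.1f%% above; trough ok %.1f%%\n",
              100 * a$cmax_below, 100 * a$cmax_in_range, 100 * a$cmax_above,
              100 * a$cmin_ok))
  if (!is.na(x$expected_attainment_after))
    cat(sprintf("  expected in-range attainment after adjustment: %.1f%%\n",
                100 * x$expected_attainment_after))
  dc <- x$dose_changes
  cat(sprintf("  dose changes: %d unchanged, %d increased, %d decreased, %d not adjusted\n",
              dc$unchanged, dc$increased, dc$decreased, dc$not_adjusted))
  cat(sprintf("  AKI: %d flagged (%d unevaluable)\n", x$aki$n,
              x$aki$unevaluable))
  if (!is.null(x$tests$dose))
    cat(sprintf("  dose paired test: V = %g, p = %.3g\n",
                x$tests$dose$statistic, x$tests$dose$p_value))
  if (!is.null(x$tests$creatinine))
    cat(sprintf("  creatinine paired test: V = %g, p = %.3g\n",
                x$tests$creatinine$statistic, x$tests$creatinine$p_value))
  invisible(x)
}

# --- course CSV I/O (long format, one row per dose/obs/covariate event) ---

course_csv_cols <- c("patient_id", "course_id", "record_type", "time_h",
                     "amount_mg", "infusion_h", "conc_mg_L", "obs_role",
                     "age_y", "sex", "weight_kg", "scr_umol_L", "timepoint")

#' Read / write course files
#'
#' Long-format CSV, one row per event, with a `record_type` column
#' distinguishing `dose`, `obs` and `covariate` rows. Covariate rows carry
#' a `timepoint` of `start` or `end`; an `end` row with an empty
#' `scr_umol_L` records a missing end-of-therapy creatinine. The physician
#' doses ride on the first dose row (`amount_mg`) and, when known, a
#' `covariate` row is not needed for the accepted dose: it is stored in the
#' optional `accepted_mg` attribute column of the first dose row. For
#' interoperability the same records can be held in one file for a whole
#' cohort.
#'
#' @param path CSV path.
#' @return `read_courses()` returns a list of [course_record()]s.
#' @export
read_courses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(course_csv_cols, names(df))
  if (length(missing_cols))
    stop("course file misses columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keys <- unique(df[c("patient_id", "course_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    rows <- df[df$patient_id == keys$patient_id[i] &
                 df$course_id == keys$course_id[i], ]
    doses <- rows[rows$record_type == "dose", ]
    obs <- rows[rows$record_type == "obs", ]
    covs <- rows[rows$record_type == "covariate", ]
    cov_row <- function(tp) {
      r <- covs[covs$timepoint == tp, ]
      if (nrow(r) == 0) return(NULL)
      covariate_set(r$age_y[1], r$sex[1], r$weight_kg[1],
                    if (is.na(r$scr_umol_L[1])) NA_real_ else r$scr_umol_L[1])
    }
    reg <- regimen(dose_events(doses$time_h, doses$infusion_h,
                               doses$amount_mg))
    course_record(
      patient_id = keys$patient_id[i], course_id = keys$course_id[i],
      cov_start = cov_row("start"), cov_end = cov_row("end"),
      reg = reg,
      observations = data.frame(time = obs$time_h, conc = obs$conc_mg_L,
                                role = obs$obs_role),
      initial_dose = doses$amount_mg[1],
      accepted_dose = if ("accepted_mg" %in% names(rows) &&
                          !all(is.na(rows$accepted_mg)))
        rows$accepted_mg[!is.na(rows$accepted_mg)][1] else NA_real_)
  })
}

#' @rdname read_courses
#' @param courses A list of [course_record()]s.
#' @export
write_courses <- function(courses, path) {
  blank <- function(n) rep(NA, n)
  rows <- lapply(courses, function(x) {
    ev <- x$regimen$events
    obs <- x$observations
    dose_rows <- data.frame(
      patient_id = x$patient_id, course_id = x$course_id,
      record_type = "dose", time_h = ev$start_time,
      amount_mg = ev$amount, infusion_h = ev$infusion_duration,
      conc_mg_L = blank(nrow(ev)), obs_role = blank(nrow(ev)),
      age_y = blank(nrow(ev)), sex = blank(nrow(ev)),
      weight_kg = blank(nrow(ev)), scr_umol_L = blank(nrow(ev)),
      timepoint = blank(nrow(ev)),
      accepted_mg = c(x$accepted_dose, blank(nrow(ev) - 1)))
    obs_rows <- data.frame(
      patient_id = x$patient_id, course_id = x$course_id,
      record_type = "obs", time_h = obs$time,
      amount_mg = blank(nrow(obs)), infusion_h = blank(nrow(obs)),
      conc_mg_L = obs$conc, obs_role = obs$role,
      age_y = blank(nrow(obs)), sex = blank(nrow(obs)),
      weight_kg = blank(nrow(obs)), scr_umol_L = blank(nrow(obs)),
      timepoint = blank(nrow(obs)), accepted_mg = blank(nrow(obs)))
    cov_rows <- do.call(rbind, lapply(c("start", "end"), function(tp) {
      cv <- if (tp == "start") x$cov_start else x$cov_end
      if (is.null(cv)) return(NULL)
      data.frame(patient_id = x$patient_id, course_id = x$course_id,
                 record_type = "covariate", time_h = NA, amount_mg = NA,
                 infusion_h = NA, conc_mg_L = NA, obs_role = NA,
                 age_y = cv$age, sex = cv$sex, weight_kg = cv$weight,
                 scr_umol_L = cv$scr, timepoint = tp, accepted_mg = NA)
    }))
    rbind(dose_rows, obs_rows, cov_rows)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
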