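# Discrete Bayesian individual estimation: assay error model, BLQ
# substitution, posterior weights over support points, hybrid-fit range
# expansion, point estimates and fit diagnostics.

#' Assay error model
#'
#' Gaussian observation error with a concentration-dependent standard
#' deviation, SD = c0 + c1 * C, evaluated at the model-predicted
#' concentration. The default c0 = 0.1 mg/L (half the 0.2 mg/L lower limit
#' of quantification) and c1 = 0.04 (the assay's 4% repeatability bound)
#' are a documented, configurable stand-in for the clinical assay's
#' unpublished error polynomial.
#'
#' @param c0 Additive SD, mg/L (>= 0).
#' @param c1 Proportional SD per mg/L (>= 0). Not both zero.
#' @return An `assay_error_model` object.
#' @export
assay_error_model <- function(c0 = 0.1, c1 = 0.04) {
  stopifnot(c0 >= 0, c1 >= 0, c0 + c1 > 0)
  structure(list(c0 = c0, c1 = c1), class = "assay_error_model")
}

#' @rdname assay_error_model
#' @param conc Model-predicted concentration(s), mg/L.
#' @param model An `assay_error_model`.
#' @return `assay_sd()` returns the SD(s) in mg/L.
#' @export
assay_sd <- function(conc, model) {
  stopifnot(all(conc >= 0))
  model$c0 + model$c1 * conc
}

#' Below-quantification-limit substitution
#'
#' Every observation with concentration strictly below the LLOQ (0.2 mg/L)
#' is replaced by half the LLOQ (0.1 mg/L) and flagged `blq`; a value of
#' exactly 0.2 mg/L is quantifiable and kept.
#'
#' @param obs Observation `data.frame` with columns `time`, `conc` and
#'   optionally `role`.
#' @param lloq Lower limit of quantification, mg/L.
#' @return The observation table with `conc` substituted and a logical
#'   `blq` column.
#' @export
preprocess_blq <- function(obs, lloq = 0.2) {
  stopifnot(all(obs$conc >= 0), all(obs$time >= 0))
  obs$blq <- obs$conc < lloq
  obs$conc[obs$blq] <- lloq / 2
  obs
}

# Log-likelihood rows for every support point at once: predictions from the
# actual recorded regimen/sampling times. Returns the n_points vector.
loglik_points <- function(points, course, err) {
  obs <- course$observations
  micro <- map_points(points, course$cov_start)
  pred <- conc_matrix(micro, course$regimen$events, obs$time)
  sd <- err$c0 + err$c1 * pred
  ll <- -0.5 * ((matrix(obs$conc, nrow(pred), ncol(pred), byrow = TRUE) -
                   pred) / sd)^2 - log(sd) - 0.5 * log(2 * pi)
  ll[!is.finite(ll)] <- -Inf
  rowSums(ll)
}

#' Gaussian observation log-likelihood of one support point
#'
#' Sum over the course's observations of the normal log-density with mean
#' equal to the model prediction at the recorded sampling time (actual
#' infusion durations, not the nominal 30 min) and SD from [assay_sd()]
#' evaluated at the prediction. Non-finite predictions yield `-Inf` rather
#' than an error, so a pathological point is excluded, not fatal.
#'
#' @param point A [support_point()].
#' @param course A [course_record()] with BLQ preprocessing applied.
#' @param err An [assay_error_model()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(point, course, err) {
  stopifnot(nrow(course$observations) >= 1)
  loglik_points(point, course, err)
}

#' Posterior over the support points of a discrete prior
#'
#' Bayes' rule on the discrete support: posterior weight_i is proportional
#' to prior weight_i x exp(logL_i), normalised with log-sum-exp
#' stabilisation. With zero observations the posterior equals the prior.
#'
#' @inheritParams log_likelihood
#' @param prior A [discrete_prior()].
#' @return A `posterior` object: the prior's points with updated weights,
#'   the log evidence, and a `hybrid_used` flag.
#' @export
posterior_weights <- function(prior, course, err) {
  stopifnot(inherits(prior, "discrete_prior"))
  pts <- prior$points
  if (nrow(course$observations) == 0) {
    return(structure(list(points = pts, bounds = prior$bounds,
                          log_evidence = 0, hybrid_used = FALSE),
                     class = "posterior"))
  }
  ll <- loglik_points(pts, course, err)
  lw <- log(pts$weight) + ll
  M <- max(lw)
  if (!is.finite(M))
    stop("degenerate fit: no support point explains the observations; ",
         "consider hybrid_fit()", call. = FALSE)
  w <- exp(lw - M)
  pts$weight <- w / sum(w)
  structure(list(points = pts, bounds = prior$bounds,
                 log_evidence = M + log(sum(w)), hybrid_used = FALSE),
            class = "posterior")
}

# Largest posterior mass piled against one side of one dimension's range:
# the mass within the outer 5% (log scale, matching the log-uniform grid
# geometry) of a single bound. Near 1 when the posterior is pushed against
# an edge, i.e. when the individual's parameters likely lie outside the
# prior's support.
boundary_mass <- function(post) {
  pts <- post$points
  worst <- 0
  for (d in prior_dimensions) {
    b <- log(post$bounds[[d]])
    tol <- 0.05 * (b[2] - b[1])
    x <- log(pts[[d]])
    worst <- max(worst,
                 sum(pts$weight[x <= b[1] + tol]),
                 sum(pts$weight[x >= b[2] - tol]))
  }
  worst
}

#' Bayesian fit with expanded parameter ranges (hybrid fit)
#'
#' When the standard posterior cannot explain the observations — more than
#' half the posterior mass stuck on boundary support points, or a median
#' absolute percentage error above 20% — the fit is repeated over an
#' expanded prior: each dimension's range is widened by a factor of 2 on
#' the log scale about its midpoint, a quasi-random auxiliary grid (default
#' 500 Halton points) is appended carrying half the total prior mass, and
#' the posterior is recomputed. This trades prior information for range,
#' allowing individual parameters outside the original support.
#'
#' @inheritParams posterior_weights
#' @param n_aux Number of auxiliary support points.
#' @param expand Log-scale range expansion factor.
#' @param aux_mass Total prior mass given to the auxiliary grid.
#' @return A `posterior` with `hybrid_used = TRUE`.
#' @export
hybrid_fit <- function(prior, course, err, n_aux = 500L, expand = 2,
                       aux_mass = 0.5) {
  stopifnot(inherits(prior, "discrete_prior"), n_aux >= 1,
            expand >= 1, aux_mass > 0, aux_mass < 1)
  new_bounds <- lapply(prior$bounds, function(b) {
    m <- sqrt(b[1] * b[2])
    h <- 0.5 * log(b[2] / b[1])
    c(m * exp(-expand * h), m * exp(expand * h))
  })
  u <- halton(n_aux, length(new_bounds), skip = 100L)
  aux <- as.data.frame(mapply(function(b, ucol) {
    exp(log(b[1]) + ucol * (log(b[2]) - log(b[1])))
  }, new_bounds, as.data.frame(u)))
  names(aux) <- prior_dimensions
  aux$weight <- rep(aux_mass / n_aux, n_aux)
  base <- prior$points
  base$weight <- base$weight * (1 - aux_mass)
  wide <- discrete_prior(rbind(base, aux), bounds = new_bounds,
                         label = paste(prior$label, "(hybrid expansion)"))
  post <- tryCatch(posterior_weights(wide, course, err), error = function(e)
    stop("unfittable course", if (!is.null(course$course_id))
      paste0(" '", course$course_id, "'"),
      ": hybrid expansion still degenerate (", conditionMessage(e), ")",
      call. = FALSE))
  post$hybrid_used <- TRUE
  post
}

#' Posterior point estimates and predictions
#'
#' Parameter point estimates are the posterior-weighted means of the
#' population-scale parameters, mapped through the covariate model to
#' individual micro constants, with clearance reported as ke x V1 (L/h).
#' The individual predicted concentrations at the observation times come
#' from the maximum-a-posteriori support point (the modal point of the
#' discrete posterior): as the data become informative the posterior
#' collapses onto the best-supported point and the predictions collapse
#' with it, whereas a weighted-mean prediction retains a grid-spread bias
#' of the order of the support spacing however good the data are.
#'
#' @param post A `posterior`.
#' @param course The fitted [course_record()].
#' @return List with `params` ([micro_params()]), `clearance` (L/h),
#'   `population` (the weighted-mean population-scale vector), `map`
#'   (the modal support point mapped to [micro_params()]) and `predicted`
#'   (mg/L at the observation times, from the modal point).
#' @export
point_estimates <- function(post, course) {
  pts <- post$points
  popmean <- vapply(prior_dimensions,
                    function(d) sum(pts[[d]] * pts$weight), numeric(1))
  micro <- individual_params(as.list(popmean), course$cov_start)
  map_micro <- individual_params(pts[which.max(pts$weight), ],
                                 course$cov_start)
  list(params = micro,
       clearance = micro$ke * micro$v1,
       population = popmean,
       map = map_micro,
       predicted = conc_profile(map_micro, course$regimen,
                                course$observations$time))
}

#' Goodness-of-fit metrics
#'
#' Prediction error PE = predicted - observed (so underprediction is
#' negative); absolute percentage error APE = 100 |PE| / observed.
#' Reports the median and interquartile range of both, plus the R-squared
#' of the observed-versus-predicted least-squares regression (0 by
#' convention when the predictions are constant). Observations equal to
#' zero are excluded from APE with a warning.
#'
#' @param observed,predicted Equal-length numeric vectors, mg/L.
#' @return List with `pe`, `ape`, `median_pe`, `iqr_pe`, `median_ape`,
#'   `iqr_ape`, `r_squared`.
#' @export
fit_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0)
  pe <- predicted - observed
  ok <- observed != 0
  if (!all(ok))
    warning("APE undefined for zero observations; excluded")
  ape <- 100 * abs(pe[ok]) / observed[ok]
  r2 <- if (length(observed) < 2 || stats::sd(predicted) == 0 ||
            stats::sd(observed) == 0) {
    if (all(pe == 0)) 1 else 0
  } else {
    stats::cor(observed, predicted)^2
  }
  list(pe = pe, ape = ape,
       median_pe = stats::median(pe),
       iqr_pe = unname(stats::quantile(pe, c(0.25, 0.75))),
       median_ape = if (length(ape)) stats::median(ape) else NA_real_,
       iqr_ape = if (length(ape))
         unname(stats::quantile(ape, c(0.25, 0.75))) else c(NA_real_, NA_real_),
       r_squared = r2)
}
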