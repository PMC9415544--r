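# Discrete Bayesian estimation: error model, BLQ handling, posterior
# weights, hybrid fit and fit diagnostics.

test_that("assay SD is affine in the predicted concentration", {
  m <- assay_error_model(0.1, 0.04)
  expect_equal(assay_sd(25, m), 1.1)
  expect_equal(assay_sd(0, m), 0.1)
  m0 <- assay_error_model(0.25, 0)
  expect_equal(assay_sd(c(0, 10, 40), m0), rep(0.25, 3))
  expect_error(assay_error_model(0, 0))
})

test_that("BLQ substitution applies strictly below the quantification limit", {
  obs <- data.frame(time = c(1, 2, 3), conc = c(0.15, 0.20, 27.8))
  out <- preprocess_blq(obs)
  expect_equal(out$conc, c(0.1, 0.20, 27.8))
  expect_equal(out$blq, c(TRUE, FALSE, FALSE))
})

test_that("log-likelihood equals the normal log-density at the prediction", {
  # engineer a one-compartment point whose prediction is exactly 20 mg/L
  cov <- ref_patient()
  reg <- once_daily_regimen(500, n_doses = 1)
  base <- support_point(vs = 1, ki = 1e-9, ks = 0.003, k12 = 0, k21 = 0)
  m1 <- individual_params(base, cov)
  c1 <- conc_profile(m1, reg, 1.0)
  pt <- base; pt$vs <- c1 / 20  # v1 scales concentration inversely
  err <- assay_error_model(0.1, 0.04)
  mk <- function(observed) course_record("P", "C", cov, reg = reg,
    observations = data.frame(time = 1.0, conc = observed),
    initial_dose = 500)
  # residual 2 mg/L at SD 0.9: independent oracle through dnorm()
  expect_equal(log_likelihood(pt, mk(22), err),
               dnorm(22, 20, 0.9, log = TRUE), tolerance = 1e-9)
  # zero residual: -log(SD * sqrt(2*pi))
  expect_equal(log_likelihood(pt, mk(20), err),
               -log(0.9 * sqrt(2 * pi)), tolerance = 1e-9)
  # additivity over independent observations
  two <- course_record("P", "C", cov, reg = reg,
    observations = data.frame(time = c(1.0, 6.0), conc = c(22, 5)),
    initial_dose = 500)
  one_a <- mk(22)
  one_b <- course_record("P", "C", cov, reg = reg,
    observations = data.frame(time = 6.0, conc = 5), initial_dose = 500)
  expect_equal(log_likelihood(pt, two, err),
               log_likelihood(pt, one_a, err) +
                 log_likelihood(pt, one_b, err), tolerance = 1e-12)
})

test_that("posterior weights obey Bayes' rule on the discrete support", {
  cov <- ref_patient()
  prior <- tiny_prior()
  err <- assay_error_model()
  empty <- course_record("P", "C", cov, reg = once_daily_regimen(500, 1),
                         observations = data.frame(time = numeric(0),
                                                   conc = numeric(0)),
                         initial_dose = 500)
  post <- posterior_weights(prior, empty, err)
  expect_equal(post$points$weight, prior$points$weight)

  # single support point: weight 1 regardless of data
  one <- discrete_prior(transform(prior$points[5, ], weight = 1),
                        bounds = prior$bounds)
  course <- make_course(prior$points[10, ], cov, c(1.0, 24), seed = 1,
                        noise_cv = 0.04)
  expect_equal(posterior_weights(one, course, err)$points$weight, 1)

  # two equal-prior points engineered to a log-likelihood gap of ln 3
  # -> posterior (0.75, 0.25), checked against a direct dnorm computation
  reg <- once_daily_regimen(500, n_doses = 1)
  base <- support_point(vs = 1, ki = 1e-9, ks = 0.003, k12 = 0, k21 = 0)
  c_unit <- conc_profile(individual_params(base, cov), reg, 1.0)
  errc <- assay_error_model(1, 0)  # constant SD 1 so the gap is in residuals
  obs <- 20
  pred2 <- obs - sqrt(2 * log(3))  # residuals 0 and sqrt(2 ln 3)
  two_pts <- rbind(base, base)
  two_pts$vs <- c(c_unit / obs, c_unit / pred2)
  two_pts$weight <- c(0.5, 0.5)
  pr2 <- discrete_prior(two_pts)
  crs <- course_record("P", "C", cov, reg = reg,
                       observations = data.frame(time = 1.0, conc = obs),
                       initial_dose = 500)
  post2 <- posterior_weights(pr2, crs, errc)
  expect_equal(post2$points$weight, c(0.75, 0.25), tolerance = 1e-9)
  lik <- dnorm(obs, c(obs, pred2), 1)
  expect_equal(post2$points$weight, lik / sum(lik), tolerance = 1e-12)
  expect_equal(sum(post2$points$weight), 1, tolerance = 1e-12)
})

test_that("posterior is stable, normalised and permutation-equivariant", {
  set.seed(11)
  cov <- ref_patient()
  prior <- tiny_prior()
  err <- assay_error_model()
  course <- make_course(prior$points[17, ], cov, c(49 + 1, 48 + 24),
                        reg = once_daily_regimen(520, 4), noise_cv = 0.04,
                        seed = 2)
  post <- posterior_weights(prior, course, err)
  expect_equal(sum(post$points$weight), 1, tolerance = 1e-12)

  # permuting the support permutes the weights
  perm <- sample.int(nrow(prior$points))
  prior_p <- discrete_prior(prior$points[perm, ], bounds = prior$bounds)
  post_p <- posterior_weights(prior_p, course, err)
  expect_equal(post_p$points$weight, post$points$weight[perm],
               tolerance = 1e-12)

  # tiny error SD produces enormous |logL| yet finite normalised weights
  post_sharp <- posterior_weights(prior, course, assay_error_model(1e-4, 0))
  expect_equal(sum(post_sharp$points$weight), 1, tolerance = 1e-12)
  expect_true(all(is.finite(post_sharp$points$weight)))

  # splitting a point's mass over a duplicate leaves expectations unchanged
  dup <- prior$points
  dup$weight[3] <- dup$weight[3] / 2
  dup <- rbind(dup, dup[3, ])
  prior_d <- discrete_prior(dup, bounds = prior$bounds)
  post_d <- posterior_weights(prior_d, course, err)
  for (d in c("vs", "ki", "ks", "k12", "k21"))
    expect_equal(sum(post_d$points[[d]] * post_d$points$weight),
                 sum(post$points[[d]] * post$points$weight),
                 tolerance = 1e-12)
})

test_that("the generating support point dominates a noiseless fit", {
  cov <- ref_patient()
  prior <- tiny_prior()
  for (idx in c(3, 77, 150)) {
    course <- make_course(prior$points[idx, ], cov,
                          c(48 + 1.1, 48 + 24), noise_cv = 0,
                          reg = once_daily_regimen(500, 4))
    post <- posterior_weights(prior, course, assay_error_model())
    expect_equal(which.max(post$points$weight), idx)
  }
})

test_that("hybrid fit triggers for out-of-range patients and improves the fit", {
  cov <- ref_patient()
  prior <- tiny_prior(300)
  err <- assay_error_model()
  # true volume slope far above the prior's upper bound
  truth <- support_point(vs = 1.1, ki = 0.01, ks = 0.003, k12 = 0.8,
                         k21 = 0.6)
  course <- make_course(truth, cov, c(48 + 1.1, 48 + 24), noise_cv = 0,
                        reg = once_daily_regimen(550, 4))
  course$observations <- preprocess_blq(course$observations)
  std <- posterior_weights(prior, course, err)
  std_ape <- fit_metrics(course$observations$conc,
                         point_estimates(std, course)$predicted)$median_ape
  hyb <- hybrid_fit(prior, course, err)
  expect_true(hyb$hybrid_used)
  hyb_ape <- fit_metrics(course$observations$conc,
                         point_estimates(hyb, course)$predicted)$median_ape
  expect_lt(hyb_ape, std_ape)
  # the full pipeline takes the hybrid path for this course
  run <- run_course(course, prior, err)
  expect_true(run$fit$hybrid_used)
  # and never takes it for a course generated from the prior itself
  ok_course <- make_course(prior$points[42, ], cov, c(48 + 1.1, 48 + 24),
                           noise_cv = 0, reg = once_daily_regimen(500, 4))
  expect_false(run_course(ok_course, prior, err)$fit$hybrid_used)
})

test_that("fit metrics follow the stated conventions", {
  m <- fit_metrics(c(10, 20), c(11, 19))
  expect_equal(m$pe, c(1, -1))
  expect_equal(m$median_pe, 0)
  expect_equal(m$ape, c(10, 5))
  expect_equal(m$median_ape, 7.5)
  perfect <- fit_metrics(c(5, 10, 20), c(5, 10, 20))
  expect_equal(perfect$median_ape, 0)
  expect_equal(perfect$r_squared, 1)
  expect_equal(fit_metrics(c(5, 10, 20), c(7, 7, 7))$r_squared, 0)
  expect_warning(fit_metrics(c(0, 10), c(1, 11)), "APE")
  # sign convention: underprediction is negative
  expect_lt(fit_metrics(10, 9)$median_pe, 0)
})

test_that("rich sampling recovers individual ke and v1 within 5%", {
  set.seed(31)
  prior <- default_prior(500)
  err <- assay_error_model()
  times <- 48 + c(0.6, 1, 1.5, 2.5, 4, 8, 16, 23.9)
  rel_err <- t(replicate(50, {
    cov <- generate_patient(synth_config())
    truth <- sample_true_params(prior)
    course <- make_course(truth, cov, times, noise_cv = 0.01,
                          reg = once_daily_regimen(500, 4))
    course$observations <- preprocess_blq(course$observations)
    post <- posterior_weights(prior, course, err)
    est <- point_estimates(post, course)$params
    tru <- individual_params(truth, cov)
    c(ke = abs(est$ke - tru$ke) / tru$ke,
      v1 = abs(est$v1 - tru$v1) / tru$v1)
  }))
  expect_lt(median(rel_err[, "ke"]), 0.05)
  expect_lt(median(rel_err[, "v1"]), 0.05)
})
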