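# Independent oracles and small fixture builders shared across the suite.

# Numerical integration of the two-compartment infusion ODE system
# (central amount X1, peripheral X2) -- the brute-force oracle for the
# closed-form kinetics. Breakpoints of the piecewise-constant infusion
# rate are inserted into the integration grid.
ode_conc <- function(params, events, times) {
  breaks <- sort(unique(c(0, events$start_time,
                          events$start_time + events$infusion_duration,
                          times)))
  conc <- got_t <- numeric(0)
  y <- c(0, 0)
  # integrate segment by segment so the infusion rate is constant within
  # each call (restarting at every discontinuity keeps lsoda accurate)
  for (s in seq_len(length(breaks) - 1)) {
    mid <- (breaks[s] + breaks[s + 1]) / 2
    on <- mid > events$start_time &
      mid < events$start_time + events$infusion_duration
    rate <- sum(events$amount[on] / events$infusion_duration[on])
    f <- function(t, y, p)
      list(c(rate - (params$ke + params$k12) * y[1] + params$k21 * y[2],
             params$k12 * y[1] - params$k21 * y[2]))
    out <- deSolve::ode(y, breaks[s:(s + 1)], f, NULL, rtol = 1e-11,
                        atol = 1e-13, maxsteps = 1e6)
    y <- out[2, 2:3]
    if (breaks[s + 1] %in% times) {
      conc <- c(conc, y[1])
      got_t <- c(got_t, breaks[s + 1])
    }
  }
  conc[match(times, got_t)] / params$v1
}

# Exhaustive sign-pattern enumeration of the two-sided paired signed-rank
# test for tieless non-zero differences (null: signs independent fair
# coins). The oracle for the test statistic's exact p-value.
enum_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
  list(statistic = v, p_value = min(1, p))
}

# A small deterministic prior for fast tests.
tiny_prior <- function(n = 200L) default_prior(n)

# One reference adult used throughout.
ref_patient <- function() covariate_set(40, "male", 60, 88.4)

# Build a course with observations generated from `truth` under `reg`,
# optionally noise-free; times on the course clock.
make_course <- function(truth, cov, times, reg = once_daily_regimen(500, 4),
                        noise_cv = 0, roles = NULL, seed = NULL,
                        initial_dose = NULL, id = "T1") {
  if (!is.null(seed)) set.seed(seed)
  micro <- individual_params(truth, cov)
  conc <- conc_profile(micro, reg, times)
  if (noise_cv > 0) conc <- pmax(conc * (1 + rnorm(length(conc), 0, noise_cv)), 0)
  if (is.null(roles)) roles <- rep("other", length(times))
  if (is.null(initial_dose)) initial_dose <- reg$events$amount[1]
  course_record(patient_id = id, course_id = paste0(id, "-C1"),
                cov_start = cov, reg = reg,
                observations = data.frame(time = times, conc = conc,
                                          role = roles),
                initial_dose = initial_dose)
}

# Random micro-parameter set drawn log-uniformly over the documented
# kinetic ranges.
random_micro <- function() {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  micro_params(v1 = lu(0.15, 0.55) * 60, ke = lu(0.05, 0.6),
               k12 = lu(0.05, 4), k21 = lu(0.05, 4))
}
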