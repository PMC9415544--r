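# Discrete nonparametric priors: construction, JSON I/O, and the built-in
# synthetic default grid.

prior_dimensions <- c("vs", "ki", "ks", "k12", "k21")

#' Discrete population prior
#'
#' A nonparametric prior: a finite set of population-scale support points
#' (see [support_point()]) with probability weights, plus per-dimension
#' bounds. Weights are renormalised on construction; a deviation larger
#' than 1e-6 raises a warning, as it suggests a malformed prior file.
#'
#' @param points `data.frame` with columns `vs`, `ki`, `ks`, `k12`, `k21`,
#'   `weight`.
#' @param bounds Named list of `c(low, high)` per dimension; defaults to the
#'   observed range of the points.
#' @param label Free-text label carried into reports.
#' @return An object of class `discrete_prior`.
#' @export
discrete_prior <- function(points, bounds = NULL, label = "unlabelled prior") {
  stopifnot(is.data.frame(points),
            all(c(prior_dimensions, "weight") %in% names(points)))
  if (any(points$weight < 0)) stop("negative prior weight", call. = FALSE)
  s <- sum(points$weight)
  if (s <= 0) stop("prior weights sum to zero", call. = FALSE)
  if (abs(s - 1) > 1e-6)
    warning(sprintf("prior weights sum to %.8f; renormalising", s))
  points$weight <- points$weight / s
  if (is.null(bounds))
    bounds <- lapply(points[prior_dimensions], range)
  for (d in prior_dimensions) {
    b <- bounds[[d]]
    if (any(points[[d]] < b[1] - 1e-9) || any(points[[d]] > b[2] + 1e-9))
      stop(sprintf("support point outside declared bounds in dimension '%s'",
                   d), call. = FALSE)
  }
  structure(list(points = points, bounds = bounds, label = label),
            class = "discrete_prior")
}

# Halton low-discrepancy sequence (radical inverse), deterministic and
# platform independent; used for reproducible quasi-random point grids.
halton <- function(n, dim, skip = 0L) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19)[seq_len(dim)]
  idx <- seq_len(n) + skip
  sapply(bases, function(b) {
    x <- numeric(n)
    f <- 1 / b
    i <- idx
    while (any(i > 0)) {
      x <- x + f * (i %% b)
      i <- i %/% b
      f <- f / b
    }
    x
  })
}

#' Built-in synthetic default prior
#'
#' A deterministic quasi-random (Halton) grid of support points,
#' log-uniform over conservative adult ranges: vs in \[0.15, 0.55\] L/kg,
#' ki in \[0.003, 0.03\] 1/h, ks in \[0.0015, 0.005\] 1/h per mL/min,
#' k12 and k21 in \[0.05, 4\] 1/h, with equal weights.
#'
#' This is a synthetic default, not a published population model: it stands
#' in when no prior file is supplied and is the basis of the simulation
#' studies shipped with the package.
#'
#' @param n Number of support points (default 2000).
#' @return A [discrete_prior()].
#' @export
default_prior <- function(n = 2000L) {
  bounds <- list(vs = c(0.15, 0.55), ki = c(0.003, 0.03),
                 ks = c(0.0015, 0.005), k12 = c(0.05, 4), k21 = c(0.05, 4))
  u <- halton(n, length(bounds), skip = 20L)
  pts <- as.data.frame(mapply(function(b, ucol) {
    exp(log(b[1]) + ucol * (log(b[2]) - log(b[1])))
  }, bounds, as.data.frame(u)))
  names(pts) <- prior_dimensions
  pts$weight <- rep(1 / n, n)
  discrete_prior(pts, bounds,
                 label = "synthetic default (Halton log-uniform grid)")
}

#' Read / write a prior file
#'
#' Structured JSON interchange format:
#' `{label, dimensions: [{name, unit, low, high}, ...], points: [[vs, ki,
#' ks, k12, k21, weight], ...]}`. The schema is validated strictly; weights
#' are renormalised on load with a warning when off by more than 1e-6.
#'
#' @param path File path.
#' @return `read_prior()` returns a [discrete_prior()].
#' @export
read_prior <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!all(c("label", "dimensions", "points") %in% names(x)))
    stop("prior file must contain 'label', 'dimensions' and 'points'",
         call. = FALSE)
  dims <- x$dimensions
  if (!identical(dims$name, prior_dimensions))
    stop("prior file dimensions must be exactly: ",
         paste(prior_dimensions, collapse = ", "), call. = FALSE)
  pts <- x$points
  if (!is.matrix(pts) || ncol(pts) != 6)
    stop("prior file points must be rows of [vs, ki, ks, k12, k21, weight]",
         call. = FALSE)
  points <- as.data.frame(pts)
  names(points) <- c(prior_dimensions, "weight")
  bounds <- lapply(seq_len(nrow(dims)),
                   function(i) c(dims$low[i], dims$high[i]))
  names(bounds) <- dims$name
  discrete_prior(points, bounds, label = x$label)
}

#' @rdname read_prior
#' @param prior A [discrete_prior()].
#' @param units Optional named character vector of per-dimension units.
#' @export
write_prior <- function(prior, path,
                        units = c(vs = "L/kg", ki = "1/h",
                                  ks = "1/h per mL/min", k12 = "1/h",
                                  k21 = "1/h")) {
  stopifnot(inherits(prior, "discrete_prior"))
  dims <- data.frame(
    name = prior_dimensions,
    unit = unname(units[prior_dimensions]),
    low = vapply(prior$bounds[prior_dimensions], `[`, numeric(1), 1),
    high = vapply(prior$bounds[prior_dimensions], `[`, numeric(1), 2)
  )
  obj <- list(label = prior$label, dimensions = dims,
              points = unname(as.matrix(
                prior$points[c(prior_dimensions, "weight")])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
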