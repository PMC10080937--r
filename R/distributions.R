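#' Describe one parameter's uncertainty distribution
#'
#' A `dist_spec` records how a single model input is distributed in the
#' probabilistic sensitivity analysis. Probabilities and the disutility use a
#' beta distribution, costs a gamma distribution, and the relative risk a
#' lognormal, each summarised on the natural scale by a center and a spread:
#'
#' * `beta` / `gamma`: `center` is the natural-scale mean, `spread` the
#'   natural-scale standard deviation; shape parameters are recovered by the
#'   method of moments ([fit_beta_moments()], [fit_gamma_moments()]).
#' * `lognormal`: `center` is the natural-scale median, `spread` the
#'   standard deviation of the log ([lognormal_from_median()]).
#' * `point`: a degenerate distribution fixed at `center` (`spread` must be 0).
#'
#' @param family one of `"beta"`, `"gamma"`, `"lognormal"`, `"point"`.
#' @param center natural-scale mean (beta/gamma), median (lognormal), or the
#'   fixed value (point).
#' @param spread natural-scale SD (beta/gamma), log-scale SD (lognormal), or
#'   0 (point).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("beta", 0.22, 0.005)
#' dist_spec("lognormal", 0.71, 0.11)
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal", "point"),
                      center, spread = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(spread), length(spread) == 1L, is.finite(spread))
  center <- as.numeric(center)
  spread <- as.numeric(spread)
  if (spread < 0) {
    stop("invalid dist_spec: spread must be >= 0, got ", spread, call. = FALSE)
  }
  switch(family,
    beta = {
      if (center <= 0 || center >= 1) {
        stop("invalid beta dist_spec: center must lie in (0, 1), got ",
             center, call. = FALSE)
      }
      if (spread^2 >= center * (1 - center)) {
        stop("invalid beta dist_spec: spread^2 = ", spread^2,
             " must be < center*(1-center) = ", center * (1 - center),
             call. = FALSE)
      }
      if (spread <= 0) {
        stop("invalid beta dist_spec: spread must be > 0 (use family = \"point\" ",
             "for a fixed value)", call. = FALSE)
      }
    },
    gamma = {
      if (center <= 0 || spread <= 0) {
        stop("invalid gamma dist_spec: center and spread must be > 0, got center = ",
             center, ", spread = ", spread, call. = FALSE)
      }
    },
    lognormal = {
      if (center <= 0 || spread <= 0) {
        stop("invalid lognormal dist_spec: center (median) and spread (sdlog) ",
             "must be > 0, got center = ", center, ", spread = ", spread,
             call. = FALSE)
      }
    },
    point = {
      if (spread != 0) {
        stop("invalid point dist_spec: spread must be 0, got ", spread,
             call. = FALSE)
      }
    }
  )
  structure(list(family = family, center = center, spread = spread),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(center = %g, spread = %g)\n",
              x$family, x$center, x$spread))
  invisible(x)
}

#' Fit a beta distribution by the method of moments
#'
#' Recovers the shape parameters of a beta distribution whose mean and
#' standard deviation equal the supplied values: with
#' \eqn{\nu = m(1-m)/s^2 - 1}, \eqn{\alpha = m\nu} and
#' \eqn{\beta = (1-m)\nu}. Feasibility requires \eqn{s^2 < m(1-m)}.
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation; `sd^2` must be below `mean*(1-mean)`.
#' @return named list with `shape1` (alpha) and `shape2` (beta).
#' @examples
#' fit_beta_moments(0.22, 0.005)
#' @export
fit_beta_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (mean <= 0 || mean >= 1 || sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop("infeasible moments for a beta distribution: need 0 < mean < 1 and ",
         "0 < sd^2 < mean*(1-mean); got mean = ", mean, ", sd = ", sd,
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' Returns shape and rate so that the gamma mean (`shape/rate`) and SD
#' (`sqrt(shape)/rate`) equal the supplied values: `shape = (mean/sd)^2`,
#' `rate = mean/sd^2`.
#'
#' @param mean target mean, > 0.
#' @param sd target standard deviation, > 0.
#' @return named list with `shape` and `rate`.
#' @examples
#' fit_gamma_moments(880, 222)
#' @export
fit_gamma_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (mean <= 0 || sd <= 0) {
    stop("infeasible moments for a gamma distribution: need mean > 0 and ",
         "sd > 0; got mean = ", mean, ", sd = ", sd, call. = FALSE)
  }
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Parameterize a lognormal from its median and log-scale SD
#'
#' Published relative risks are usually summarised by a point estimate (the
#' median of the sampling distribution on the natural scale) and an SD on the
#' log scale. Then `meanlog = log(median)` and `sdlog` is used as given. The
#' implied equal-tailed 95% interval `exp(meanlog +/- 1.96 sdlog)` is returned
#' alongside.
#'
#' @param median natural-scale median, > 0.
#' @param sdlog standard deviation of the log, > 0.
#' @return named list with `meanlog`, `sdlog`, `ci95` (length-2 interval).
#' @examples
#' lognormal_from_median(0.71, 0.11)
#' @export
lognormal_from_median <- function(median, sdlog) {
  stopifnot(is.numeric(median), is.numeric(sdlog))
  if (median <= 0 || sdlog <= 0) {
    stop("lognormal parameterization needs median > 0 and sdlog > 0; got ",
         "median = ", median, ", sdlog = ", sdlog, call. = FALSE)
  }
  mu <- log(median)
  list(meanlog = mu, sdlog = sdlog,
       ci95 = c(exp(mu - 1.96 * sdlog), exp(mu + 1.96 * sdlog)))
}

#' Equal-tailed quantile interval of a distribution spec
#'
#' Used to set one-way sensitivity ranges: the interval between the
#' `(1-level)/2` and `(1+level)/2` quantiles of the parameter's distribution.
#' A `point` spec returns the degenerate interval at its center.
#'
#' @param spec a [dist_spec()].
#' @param level coverage in (0, 1); default 0.95.
#' @return named numeric vector `c(low, high)`.
#' @examples
#' interval_bounds(dist_spec("lognormal", 0.71, 0.11))
#' @export
interval_bounds <- function(spec, level = 0.95) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1), got ", level, call. = FALSE)
  }
  p <- c((1 - level) / 2, (1 + level) / 2)
  out <- switch(spec$family,
    point = rep(spec$center, 2L),
    beta = {
      fit <- fit_beta_moments(spec$center, spec$spread)
      stats::qbeta(p, fit$shape1, fit$shape2)
    },
    gamma = {
      fit <- fit_gamma_moments(spec$center, spec$spread)
      stats::qgamma(p, shape = fit$shape, rate = fit$rate)
    },
    lognormal = stats::qlnorm(p, meanlog = log(spec$center), sdlog = spec$spread)
  )
  c(low = out[1L], high = out[2L])
}

#' Sample from a distribution spec
#'
#' Draws `n` independent values from the distribution described by `spec`.
#' RNG state is taken from the calling environment; callers that need
#' reproducibility set the seed themselves (as [sample_parameter_draws()]
#' does, one stream per parameter).
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`, all inside the family's support.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), is.numeric(n), n >= 1)
  n <- as.integer(n)
  switch(spec$family,
    point = rep(spec$center, n),
    beta = {
      fit <- fit_beta_moments(spec$center, spec$spread)
      stats::rbeta(n, fit$shape1, fit$shape2)
    },
    gamma = {
      fit <- fit_gamma_moments(spec$center, spec$spread)
      stats::rgamma(n, shape = fit$shape, rate = fit$rate)
    },
    lognormal = stats::rlnorm(n, meanlog = log(spec$center), sdlog = spec$spread)
  )
}

# analytic mean/sd on the natural scale, used by moment-recovery checks
dist_moments <- function(spec) {
  switch(spec$family,
    point = c(mean = spec$center, sd = 0),
    beta = c(mean = spec$center, sd = spec$spread),
    gamma = c(mean = spec$center, sd = spec$spread),
    lognormal = {
      m <- exp(log(spec$center) + spec$spread^2 / 2)
      s <- m * sqrt(exp(spec$spread^2) - 1)
      c(mean = m, sd = s)
    }
  )
}
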