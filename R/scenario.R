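#' Generate a random but valid parameter table
#'
#' Draws a full model parameter table at random inside user-settable ranges,
#' with uncertainty spreads drawn inside each family's feasibility region
#' (beta: `spread^2 < center * (1 - center)`). The default ranges bracket the
#' published base case and deliberately include relative risks above 1 and
#' episode costs from cheap to catastrophic, so downstream code is exercised
#' in both the dominant and the non-dominant regime. Deterministic under
#' `seed`.
#'
#' @param seed integer seed.
#' @param p_ari_range,rr_range,m_ari_range,m_all_range,du_range ranges for the
#'   probabilities, relative risk and disutility.
#' @param c_ari_day_range,c_vitd_day_range daily-cost ranges, USD.
#' @param episode_days_range,suppl_days_range duration ranges, days.
#' @return a validated [vitd_parameters()] object.
#' @examples
#' random_scenario(seed = 7)
#' @export
random_scenario <- function(seed,
                            p_ari_range = c(0.05, 0.5),
                            rr_range = c(0.4, 1.2),
                            m_ari_range = c(1e-5, 0.01),
                            m_all_range = c(1e-5, 0.01),
                            du_range = c(0.01, 0.3),
                            c_ari_day_range = c(10, 1500),
                            c_vitd_day_range = c(0.01, 1),
                            episode_days_range = c(1, 30),
                            suppl_days_range = c(30, 365)) {
  check_range <- function(r, lo, hi, nm) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop("infeasible range for ", nm, call. = FALSE)
    }
  }
  check_range(p_ari_range, 0, 1, "p_ari")
  check_range(rr_range, 0, Inf, "rr")
  check_range(m_ari_range, 0, 1, "m_ari")
  check_range(m_all_range, 0, 1, "m_all")
  check_range(du_range, 0, 1, "du")
  check_range(c_ari_day_range, 0, Inf, "c_ari_day")
  check_range(c_vitd_day_range, 0, Inf, "c_vitd_day")

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  runifr <- function(r) stats::runif(1, r[1], r[2])
  p_ari <- runifr(p_ari_range)
  # keep the joint constraint p_ari * rr <= 1 satisfiable for any drawn rr
  rr <- runifr(c(rr_range[1], min(rr_range[2], 1 / p_ari)))
  m_ari <- runifr(m_ari_range)
  m_all <- runifr(m_all_range)
  du <- runifr(du_range)
  c_ari <- runifr(c_ari_day_range)
  c_vitd <- runifr(c_vitd_day_range)

  beta_spread <- function(center) {
    sqrt(stats::runif(1, 0.01, 0.5) * center * (1 - center))
  }
  dists <- list(
    p_ari = dist_spec("beta", p_ari, beta_spread(p_ari)),
    rr_vitd = dist_spec("lognormal", rr, stats::runif(1, 0.02, 0.3)),
    m_ari = dist_spec("beta", m_ari, beta_spread(m_ari)),
    m_all = dist_spec("beta", m_all, beta_spread(m_all)),
    du_ari = dist_spec("beta", du, beta_spread(du)),
    c_ari_day = dist_spec("gamma", c_ari, c_ari * stats::runif(1, 0.05, 0.5)),
    c_vitd_day = dist_spec("gamma", c_vitd, c_vitd * stats::runif(1, 0.05, 0.5))
  )

  vitd_parameters(
    p_ari = p_ari, rr_vitd = rr, m_ari = m_ari, m_all = m_all, du_ari = du,
    c_ari_day = c_ari, c_vitd_day = c_vitd,
    episode_days = round(runifr(episode_days_range)),
    suppl_days = round(runifr(suppl_days_range)),
    dists = dists
  )
}

#' Generate a random decision tree for oracle testing
#'
#' Builds a random chance-node tree: branch probabilities drawn uniformly on
#' the simplex at every chance node, terminal payoffs uniform on valid ranges
#' (cost in \[0, 10000\], utility in \[0, 1\]). Each internal child becomes a
#' terminal with probability 0.3, so trees of varying shape appear. Used by
#' the roll-back versus path-enumeration oracle suite. Deterministic under
#' `seed`.
#'
#' @param seed integer seed.
#' @param depth maximum depth of chance nodes, >= 1.
#' @param branching number of branches per chance node, >= 2.
#' @return a [strategy()] object passing [validate_tree()].
#' @examples
#' enumerate_paths(random_tree(seed = 1, depth = 3, branching = 3))
#' @export
random_tree <- function(seed, depth = 3, branching = 3) {
  stopifnot(depth >= 1, branching >= 2)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  leaf_count <- 0L
  make_terminal <- function() {
    leaf_count <<- leaf_count + 1L
    terminal_node(paste0("state-", leaf_count),
                  cost = stats::runif(1, 0, 10000),
                  utility = stats::runif(1, 0, 1))
  }
  grow <- function(level) {
    if (level > depth) return(make_terminal())
    raw <- -log(stats::runif(branching))  # flat Dirichlet via exponentials
    probs <- raw / sum(raw)
    children <- lapply(seq_len(branching), function(i) {
      if (level == depth || stats::runif(1) < 0.3) make_terminal()
      else grow(level + 1L)
    })
    chance_node(probs, children)
  }
  strategy(paste0("random-tree-", seed), grow(1L))
}

#' The null scenario: an intervention that does nothing and costs nothing
#'
#' Published base-case values with the relative risk fixed at 1 and the daily
#' supplement cost fixed at 0 (both as degenerate point distributions). The
#' two strategies are then identical, so every downstream increment — base
#' case and every PSA draw — is exactly zero. Used as an analytic limit in
#' tests.
#'
#' @return a [vitd_parameters()] object.
#' @examples
#' glance(evaluate_base_case(null_scenario()))
#' @export
null_scenario <- function() {
  vitd_parameters(
    rr_vitd = 1, c_vitd_day = 0,
    dists = list(rr_vitd = dist_spec("point", 1),
                 c_vitd_day = dist_spec("point", 0))
  )
}

#' Check that sampling recovers a distribution's moments
#'
#' Draws `n` values from `spec` and compares the empirical mean (and, for the
#' lognormal, the log-scale median check) against the analytic values, scaled
#' by the standard error of the mean. A deviation beyond `flag_se` standard
#' errors flags a mis-parameterized sampler.
#'
#' @param spec a non-degenerate [dist_spec()].
#' @param n number of draws, >= 100.
#' @param seed integer seed.
#' @param flag_se flag threshold in SE units; default 4.
#' @return one-row tibble: `family`, `n`, `target_mean`, `empirical_mean`,
#'   `target_sd`, `empirical_sd`, `z_mean` (deviation of the mean in SE
#'   units), `flagged`.
#' @export
moment_recovery_report <- function(spec, n, seed, flag_se = 4) {
  stopifnot(inherits(spec, "dist_spec"), n >= 100)
  if (spec$family == "point") {
    stop("moment recovery is only defined for non-degenerate distributions",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  x <- sample_dist(spec, n)
  mm <- dist_moments(spec)
  if (spec$family == "lognormal") {
    # natural-scale mean is skewed; check the log-scale mean, whose target is
    # log(median), with SE sdlog/sqrt(n)
    z <- (mean(log(x)) - log(spec$center)) / (spec$spread / sqrt(n))
  } else {
    z <- (mean(x) - mm[["mean"]]) / (mm[["sd"]] / sqrt(n))
  }
  tibble::tibble(
    family = spec$family, n = as.integer(n),
    target_mean = mm[["mean"]], empirical_mean = mean(x),
    target_sd = mm[["sd"]], empirical_sd = stats::sd(x),
    z_mean = z, flagged = abs(z) > flag_se
  )
}
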