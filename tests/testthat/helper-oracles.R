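# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# aggregate a path enumeration into expected cost/utility (oracle for rollback)
paths_expectation <- function(strat) {
  paths <- enumerate_paths(strat)
  c(cost = sum(paths$probability * paths$cost),
    utility = sum(paths$probability * paths$utility))
}

# closed-form increments of the two-strategy supplementation tree
# (intervention minus comparator); valid when p_ari * rr <= 1
closed_form_increments <- function(params) {
  v <- params$values
  s <- params$settings
  dq <- v[["p_ari"]] * (1 - v[["rr_vitd"]]) *
    ((1 - v[["m_all"]]) - (1 - v[["m_ari"]]) * (1 - v[["du_ari"]]))
  if (params$settings$scale_by_horizon) dq <- dq * s$horizon_days / 365
  dc <- v[["c_vitd_day"]] * s$suppl_days -
    v[["p_ari"]] * (1 - v[["rr_vitd"]]) * v[["c_ari_day"]] * s$episode_days
  c(delta_cost = dc, delta_qaly = dq)
}

# numerical scale of money in a scenario: bounds the achievable absolute
# precision of cost increments in double arithmetic
cost_scale <- function(params) {
  v <- params$values
  s <- params$settings
  max(1, v[["c_ari_day"]] * s$episode_days + v[["c_vitd_day"]] * s$suppl_days)
}

# gamma quantile by numerical CDF inversion: integrate the density and invert
# with uniroot, independent of qgamma
gamma_quantile_numeric <- function(p, shape, rate) {
  cdf <- function(x) {
    stats::integrate(function(t) stats::dgamma(t, shape = shape, rate = rate),
                     lower = 0, upper = x, rel.tol = 1e-12)$value
  }
  upper <- shape / rate + 20 * sqrt(shape) / rate
  stats::uniroot(function(x) cdf(x) - p, lower = 1e-12, upper = upper,
                 tol = 1e-10)$root
}

table1_params <- function(...) vitd_parameters(...)
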