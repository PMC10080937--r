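#' Model parameter table
#'
#' Builds the full set of model inputs for the cost-utility analysis of daily
#' vitamin D supplementation against pediatric acute respiratory infection
#' (ARI), together with the uncertainty distribution of each input and the
#' analysis settings. Defaults are the published base case:
#'
#' | input | default | uncertainty |
#' |---|---|---|
#' | `p_ari` probability of >=1 ARI over the horizon | 0.22 | beta, SD 0.005 |
#' | `rr_vitd` relative risk of ARI under supplementation | 0.71 | lognormal, sdlog 0.11 |
#' | `m_ari` probability of death given ARI | 0.0001 | beta, SD 0.000029 |
#' | `m_all` probability of all-cause death, ARI-free branch | 0.0008 | beta, SD 0.00022 |
#' | `du_ari` utility decrement during an ARI episode | 0.06 | beta, SD 0.015 |
#' | `c_ari_day` ARI cost per day, USD | 880 | gamma, SD 222 |
#' | `c_vitd_day` vitamin D3 400 IU daily cost, USD | 0.08 | gamma, SD 0.02 |
#'
#' Settings: `episode_days` (costed ARI episode length, default 10 days),
#' `suppl_days` (supplementation duration, default 182 days), `horizon_days`
#' (182, six months, no discounting), `wtp` (willingness-to-pay per QALY,
#' default USD 19,000), and `scale_by_horizon` (default `FALSE`: QALYs are
#' reported as unscaled expected utility weights; when `TRUE` they are
#' multiplied by `horizon_days/365`).
#'
#' @param p_ari,rr_vitd,m_ari,m_all,du_ari,c_ari_day,c_vitd_day point values;
#'   see table above.
#' @param episode_days,suppl_days,horizon_days,wtp,scale_by_horizon analysis
#'   settings; see above.
#' @param dists named list of [dist_spec()] objects for the seven uncertain
#'   parameters. By default each distribution is centered at the corresponding
#'   point value with the published spread; supply entries to override spreads
#'   or families (e.g. replace a distribution with a `point` spec to freeze a
#'   parameter). Every distribution's center must equal the point value.
#' @return an object of class `vitd_params`: a validated list with elements
#'   `values` (named numeric), `settings` (named list) and `dists` (named list
#'   of `dist_spec`).
#' @examples
#' params <- vitd_parameters()
#' tidy(params)
#' @seealso [read_parameter_config()], [tidy.vitd_params()]
#' @export
vitd_parameters <- function(p_ari = 0.22, rr_vitd = 0.71,
                            m_ari = 0.0001, m_all = 0.0008,
                            du_ari = 0.06,
                            c_ari_day = 880, c_vitd_day = 0.08,
                            episode_days = 10, suppl_days = 182,
                            horizon_days = 182, wtp = 19000,
                            scale_by_horizon = FALSE,
                            dists = list()) {
  # storage mode is normalized to double so tables loaded from JSON compare
  # identical to ones built in code
  values <- vapply(list(p_ari = p_ari, rr_vitd = rr_vitd, m_ari = m_ari,
                        m_all = m_all, du_ari = du_ari, c_ari_day = c_ari_day,
                        c_vitd_day = c_vitd_day), as.numeric, numeric(1))
  settings <- list(episode_days = as.numeric(episode_days),
                   suppl_days = as.numeric(suppl_days),
                   horizon_days = as.numeric(horizon_days),
                   wtp = as.numeric(wtp),
                   scale_by_horizon = isTRUE(scale_by_horizon))

  default_spreads <- c(p_ari = 0.005, rr_vitd = 0.11, m_ari = 0.000029,
                       m_all = 0.00022, du_ari = 0.015, c_ari_day = 222,
                       c_vitd_day = 0.02)
  default_family <- c(p_ari = "beta", rr_vitd = "lognormal", m_ari = "beta",
                      m_all = "beta", du_ari = "beta", c_ari_day = "gamma",
                      c_vitd_day = "gamma")

  full <- lapply(uncertain_parameters(), function(nm) {
    if (!is.null(dists[[nm]])) return(dists[[nm]])
    tryCatch(
      dist_spec(default_family[[nm]], values[[nm]], default_spreads[[nm]]),
      error = function(e) {
        stop("validation error for ", nm, ": ", conditionMessage(e),
             call. = FALSE)
      })
  })
  names(full) <- uncertain_parameters()

  out <- structure(list(values = values, settings = settings, dists = full),
                   class = "vitd_params")
  validate_parameters(out)
  out
}

# canonical ordering of the uncertain inputs; sampling streams follow it
uncertain_parameters <- function() {
  c("p_ari", "rr_vitd", "m_ari", "m_all", "du_ari", "c_ari_day", "c_vitd_day")
}

validate_parameters <- function(params) {
  v <- params$values
  s <- params$settings
  need <- uncertain_parameters()
  missing <- setdiff(need, names(v))
  if (length(missing) > 0) {
    stop("missing input: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    stop("validation error: non-finite parameter value", call. = FALSE)
  }
  check_prob <- function(nm) {
    if (v[[nm]] < 0 || v[[nm]] > 1) {
      stop("validation error: ", nm, " must be a probability in [0, 1], got ",
           v[[nm]], call. = FALSE)
    }
  }
  for (nm in c("p_ari", "m_ari", "m_all")) check_prob(nm)
  if (v[["du_ari"]] < 0 || v[["du_ari"]] > 1) {
    stop("validation error: du_ari must lie in [0, 1], got ", v[["du_ari"]],
         call. = FALSE)
  }
  if (v[["rr_vitd"]] <= 0) {
    stop("validation error: rr_vitd must be > 0, got ", v[["rr_vitd"]],
         call. = FALSE)
  }
  if (v[["p_ari"]] * v[["rr_vitd"]] > 1) {
    stop("validation error: p_ari * rr_vitd = ", v[["p_ari"]] * v[["rr_vitd"]],
         " exceeds 1", call. = FALSE)
  }
  for (nm in c("c_ari_day", "c_vitd_day")) {
    if (v[[nm]] < 0) {
      stop("validation error: ", nm, " must be >= 0, got ", v[[nm]],
           call. = FALSE)
    }
  }
  for (nm in c("episode_days", "suppl_days", "horizon_days", "wtp")) {
    if (!is.numeric(s[[nm]]) || length(s[[nm]]) != 1L || !is.finite(s[[nm]]) ||
        s[[nm]] < 0) {
      stop("validation error: setting ", nm, " must be a nonnegative number",
           call. = FALSE)
    }
  }
  for (nm in need) {
    spec <- params$dists[[nm]]
    if (!inherits(spec, "dist_spec")) {
      stop("validation error: dists$", nm, " is not a dist_spec", call. = FALSE)
    }
    if (spec$center != v[[nm]]) {
      stop("validation error: distribution center for ", nm, " (", spec$center,
           ") must equal its point value (", v[[nm]], ")", call. = FALSE)
    }
  }
  invisible(params)
}

#' @export
print.vitd_params <- function(x, ...) {
  cat("<vitd_params> cost-utility model inputs\n")
  print(tidy(x), n = Inf)
  s <- x$settings
  cat(sprintf(
    "settings: episode_days %g, suppl_days %g, horizon_days %g, wtp %g, scale_by_horizon %s\n",
    s$episode_days, s$suppl_days, s$horizon_days, s$wtp, s$scale_by_horizon))
  invisible(x)
}

#' Tidy a parameter table into one row per uncertain input
#'
#' @param x a [vitd_parameters()] object.
#' @param level coverage of the reported equal-tailed interval; default 0.95.
#' @param ... unused.
#' @return tibble with columns `parameter`, `value`, `family`, `spread`,
#'   `low`, `high` (the `level` equal-tailed interval).
#' @method tidy vitd_params
#' @export
tidy.vitd_params <- function(x, level = 0.95, ...) {
  purrr::map_dfr(uncertain_parameters(), function(nm) {
    spec <- x$dists[[nm]]
    b <- interval_bounds(spec, level)
    tibble::tibble(parameter = nm, value = x$values[[nm]],
                   family = spec$family, spread = spec$spread,
                   low = b[["low"]], high = b[["high"]])
  })
}

#' Read a model configuration from JSON
#'
#' The configuration document has three blocks: `parameters` (point values),
#' `distributions` (per-parameter `family` and `spread`; centers are taken
#' from the point values) and `settings`. Missing settings and distributions
#' take the published defaults; missing parameters are an error. An annotated
#' default configuration reproducing the published base case ships at
#' `system.file("extdata", "table1.json", package = "vitdcea")`.
#'
#' @param path path to a JSON configuration file.
#' @return a validated [vitd_parameters()] object.
#' @seealso [write_parameter_config()]
#' @export
read_parameter_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- cfg$parameters
  need <- uncertain_parameters()
  missing <- setdiff(need, names(pars))
  if (length(missing) > 0) {
    stop("missing input: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dists <- list()
  if (!is.null(cfg$distributions)) {
    for (nm in intersect(names(cfg$distributions), need)) {
      d <- cfg$distributions[[nm]]
      dists[[nm]] <- dist_spec(d$family, pars[[nm]],
                               if (is.null(d$spread)) 0 else d$spread)
    }
  }
  st <- if (is.null(cfg$settings)) list() else cfg$settings
  arg <- function(nm, default) if (is.null(st[[nm]])) default else st[[nm]]
  vitd_parameters(
    p_ari = pars$p_ari, rr_vitd = pars$rr_vitd, m_ari = pars$m_ari,
    m_all = pars$m_all, du_ari = pars$du_ari, c_ari_day = pars$c_ari_day,
    c_vitd_day = pars$c_vitd_day,
    episode_days = arg("episode_days", 10),
    suppl_days = arg("suppl_days", 182),
    horizon_days = arg("horizon_days", 182),
    wtp = arg("wtp", 19000),
    scale_by_horizon = arg("scale_by_horizon", FALSE),
    dists = dists
  )
}

#' Write a parameter table back to a JSON configuration
#'
#' Inverse of [read_parameter_config()]: the echoed document reloads to a
#' field-for-field identical table, providing provenance for every analysis.
#'
#' @param params a [vitd_parameters()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(params, path) {
  stopifnot(inherits(params, "vitd_params"))
  cfg <- list(
    parameters = as.list(params$values),
    distributions = lapply(params$dists, function(d) {
      list(family = d$family, spread = d$spread)
    }),
    settings = params$settings
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# return a copy of params with one value replaced (distribution center follows)
substitute_value <- function(params, name, value) {
  stopifnot(name %in% names(params$values))
  params$values[[name]] <- value
  spec <- params$dists[[name]]
  params$dists[[name]] <- structure(
    list(family = spec$family, center = value, spread = spec$spread),
    class = "dist_spec")
  validate_parameters(params)
  params
}
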