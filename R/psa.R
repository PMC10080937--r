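#' Sample joint parameter draws for the probabilistic analysis
#'
#' Draws `n` independent values from every uncertain input's distribution,
#' mutually independent across parameters. Sampling is parameter-major with
#' one RNG stream per parameter (sub-seeds derived from `seed` in the
#' canonical parameter order), so extending the model with a new parameter
#' leaves existing parameters' draws untouched. Within a draw the realized
#' values are shared by both strategies (common random numbers), so the
#' increments reflect parameter uncertainty, not sampling noise between arms.
#'
#' @param params a [vitd_parameters()] object.
#' @param n number of draws, >= 1.
#' @param seed integer seed; identical `(params, n, seed)` gives identical
#'   draws.
#' @return tibble with `.draw` (1..n) and one column per uncertain parameter.
#' @examples
#' sample_parameter_draws(vitd_parameters(), n = 5, seed = 1)
#' @export
sample_parameter_draws <- function(params, n, seed) {
  stopifnot(inherits(params, "vitd_params"), is.numeric(n), n >= 1,
            is.numeric(seed))
  n <- as.integer(n)
  nms <- uncertain_parameters()
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, length(nms))
  draws <- lapply(seq_along(nms), function(i) {
    set.seed(subseeds[i])
    sample_dist(params$dists[[nms[i]]], n)
  })
  names(draws) <- nms
  tibble::as_tibble(c(list(.draw = seq_len(n)), draws))
}

#' Run the second-order Monte Carlo probabilistic sensitivity analysis
#'
#' For each of `n` parameter draws the decision tree is evaluated for both
#' strategies at the drawn values, giving per-draw expected costs and
#' utilities and their increments (intervention minus comparator). The
#' evaluation is the exact roll-back of the two-strategy tree, computed in
#' vectorized form over draws. Lognormal relative-risk draws can push the
#' supplemented-arm ARI probability `p_ari * rr` above 1; such draws are
#' capped at 1 and counted (see the `n_capped` attribute), or rejected and
#' redrawn when `resample_infeasible = TRUE`.
#'
#' @param params a [vitd_parameters()] object.
#' @param n number of Monte Carlo replications (published analysis: 10,000).
#' @param seed integer seed.
#' @param resample_infeasible if `TRUE`, draws with `p_ari * rr > 1` are
#'   replaced by fresh draws of the pair instead of capped. Default `FALSE`.
#' @return tibble of class `vitd_psa`: `.draw`, the seven parameter columns,
#'   `cost_no_suppl`, `qaly_no_suppl`, `cost_vitd`, `qaly_vitd`, `delta_cost`,
#'   `delta_qaly`. Attributes: `seed`, `n`, `wtp`, `n_capped`,
#'   `scale_by_horizon`.
#' @examples
#' psa <- run_psa(vitd_parameters(), n = 200, seed = 42)
#' head(psa)
#' @export
run_psa <- function(params, n, seed, resample_infeasible = FALSE) {
  stopifnot(inherits(params, "vitd_params"), is.numeric(n), n >= 1)
  draws <- sample_parameter_draws(params, n, seed)

  infeasible <- draws$p_ari * draws$rr_vitd > 1
  n_capped <- sum(infeasible)
  if (resample_infeasible && n_capped > 0) {
    # redraw the whole table under successor seeds and patch the offending
    # (p_ari, rr_vitd) pairs until feasible
    attempt <- 1L
    while (any(infeasible) && attempt <= 100L) {
      fresh <- sample_parameter_draws(params, sum(infeasible),
                                      as.integer(seed) + attempt)
      draws$p_ari[infeasible] <- fresh$p_ari
      draws$rr_vitd[infeasible] <- fresh$rr_vitd
      infeasible <- draws$p_ari * draws$rr_vitd > 1
      attempt <- attempt + 1L
    }
    if (any(infeasible)) {
      stop("could not resample feasible (p_ari, rr_vitd) pairs", call. = FALSE)
    }
    n_capped <- 0L
  }

  s <- params$settings
  out <- dplyr::mutate(
    draws,
    .p_ari_suppl = pmin(.data$p_ari * .data$rr_vitd, 1),
    .episode_cost = .data$c_ari_day * s$episode_days,
    cost_no_suppl = .data$p_ari * .data$.episode_cost,
    qaly_no_suppl = .data$p_ari * (1 - .data$m_ari) * (1 - .data$du_ari) +
      (1 - .data$p_ari) * (1 - .data$m_all),
    cost_vitd = .data$.p_ari_suppl * .data$.episode_cost +
      .data$c_vitd_day * s$suppl_days,
    qaly_vitd = .data$.p_ari_suppl * (1 - .data$m_ari) * (1 - .data$du_ari) +
      (1 - .data$.p_ari_suppl) * (1 - .data$m_all)
  )
  if (s$scale_by_horizon) {
    k <- s$horizon_days / 365
    out <- dplyr::mutate(out,
                         qaly_no_suppl = .data$qaly_no_suppl * k,
                         qaly_vitd = .data$qaly_vitd * k)
  }
  out <- dplyr::mutate(out,
                       delta_cost = .data$cost_vitd - .data$cost_no_suppl,
                       delta_qaly = .data$qaly_vitd - .data$qaly_no_suppl)
  out <- dplyr::select(out, -".p_ari_suppl", -".episode_cost")

  structure(out, class = c("vitd_psa", class(out)),
            seed = as.integer(seed), n = as.integer(n), wtp = s$wtp,
            n_capped = as.integer(n_capped),
            scale_by_horizon = s$scale_by_horizon)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay `lambda` on the grid, the intervention's
#' acceptability is the fraction of draws in which its incremental net
#' monetary benefit `lambda * delta_qaly - delta_cost` is strictly positive;
#' ties go to the comparator (conservative toward the intervention). The two
#' strategies' probabilities sum to 1 at every grid point.
#'
#' @param psa a `vitd_psa` tibble from [run_psa()].
#' @param wtp_grid ascending willingness-to-pay grid, USD/QALY; default 0 to
#'   60,000 in steps of 500.
#' @return tibble of class `vitd_ceac` with columns `wtp`, `p_vitd`,
#'   `p_no_suppl`.
#' @export
ceac_curve <- function(psa, wtp_grid = seq(0, 60000, by = 500)) {
  stopifnot(inherits(psa, "vitd_psa"))
  if (nrow(psa) == 0) stop("empty PSA result", call. = FALSE)
  if (length(wtp_grid) == 0 || is.unsorted(wtp_grid)) {
    stop("wtp_grid must be a nonempty ascending grid", call. = FALSE)
  }
  p <- vapply(wtp_grid, function(l) {
    mean(l * psa$delta_qaly - psa$delta_cost > 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = as.numeric(wtp_grid), p_vitd = p,
                        p_no_suppl = 1 - p)
  structure(out, class = c("vitd_ceac", class(out)),
            seed = attr(psa, "seed"), n = attr(psa, "n"))
}

#' Cost-effectiveness plane quadrant shares
#'
#' Classifies every draw's `(delta_qaly, delta_cost)` point into the four
#' quadrants of the cost-effectiveness plane (`ne`: more QALYs at extra cost;
#' `se`: more QALYs and cheaper, i.e. dominant; `sw`: fewer QALYs but cheaper;
#' `nw`: fewer QALYs at extra cost, i.e. dominated) and also reports the
#' fraction of draws falling below the willingness-to-pay line
#' (`lambda * delta_qaly - delta_cost > 0`). Boundary points (a zero
#' increment) are assigned to the adjacent quadrant clockwise: the positive
#' QALY axis to `se`, the negative cost axis to `sw`, the negative QALY axis
#' to `nw`, the positive cost axis to `ne`, and the origin to `se`.
#'
#' @param psa a `vitd_psa` tibble from [run_psa()].
#' @param wtp willingness-to-pay for the below-WTP share; defaults to the
#'   table's WTP the PSA was run with.
#' @return one-row tibble: `ne`, `se`, `sw`, `nw` (summing to 1), and
#'   `below_wtp`.
#' @export
quadrant_shares <- function(psa, wtp = attr(psa, "wtp")) {
  stopifnot(inherits(psa, "vitd_psa"))
  if (nrow(psa) == 0) stop("empty PSA result", call. = FALSE)
  dq <- psa$delta_qaly
  dc <- psa$delta_cost
  quadrant <- dplyr::case_when(
    dq > 0 & dc <= 0 ~ "se",
    dq <= 0 & dc < 0 ~ "sw",
    dq < 0 & dc >= 0 ~ "nw",
    dq >= 0 & dc > 0 ~ "ne",
    TRUE ~ "se"  # origin
  )
  share <- function(q) mean(quadrant == q)
  tibble::tibble(
    ne = share("ne"), se = share("se"), sw = share("sw"), nw = share("nw"),
    below_wtp = mean(wtp * dq - dc > 0)
  )
}

#' Acceptability frontier
#'
#' At each willingness-to-pay on the grid the frontier strategy is the one
#' maximizing the mean net monetary benefit across draws (the expected-value
#' optimum); it is reported together with its own acceptability (CEAC value)
#' at that threshold. Ties in mean NMB go to the comparator.
#'
#' @param psa a `vitd_psa` tibble from [run_psa()].
#' @param wtp_grid ascending willingness-to-pay grid; default as
#'   [ceac_curve()].
#' @return tibble with columns `wtp`, `frontier` (strategy name),
#'   `ceac` (the frontier strategy's acceptability), `mean_nmb`.
#' @export
acceptability_frontier <- function(psa, wtp_grid = seq(0, 60000, by = 500)) {
  stopifnot(inherits(psa, "vitd_psa"))
  if (length(wtp_grid) == 0 || is.unsorted(wtp_grid)) {
    stop("wtp_grid must be a nonempty ascending grid", call. = FALSE)
  }
  ceac <- ceac_curve(psa, wtp_grid)
  purrr::map_dfr(seq_along(wtp_grid), function(i) {
    l <- wtp_grid[i]
    nmb_vitd <- mean(l * psa$qaly_vitd - psa$cost_vitd)
    nmb_none <- mean(l * psa$qaly_no_suppl - psa$cost_no_suppl)
    vitd_opt <- nmb_vitd > nmb_none
    tibble::tibble(
      wtp = as.numeric(l),
      frontier = if (vitd_opt) "vitamin-D" else "no-supplementation",
      ceac = if (vitd_opt) ceac$p_vitd[i] else ceac$p_no_suppl[i],
      mean_nmb = max(nmb_vitd, nmb_none)
    )
  })
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of per-draw incremental QALYs against incremental cost, with the
#' willingness-to-pay line through the origin.
#'
#' @param object a `vitd_psa` tibble from [run_psa()].
#' @param wtp willingness-to-pay line to draw; defaults to the analysis WTP.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot vitd_psa
#' @export
autoplot.vitd_psa <- function(object, wtp = attr(object, "wtp"), ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "incremental QALYs", y = "incremental cost (USD)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("%d draws; dashed line: WTP %g/QALY",
                                     nrow(object), wtp)) +
    ggplot2::theme_minimal()
}

#' Plot an acceptability curve
#'
#' @param object a `vitd_ceac` tibble from [ceac_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot vitd_ceac
#' @export
autoplot.vitd_ceac <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"wtp",
                            names_to = "strategy", values_to = "probability")
  df$strategy <- ifelse(df$strategy == "p_vitd", "vitamin-D",
                        "no-supplementation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "willingness-to-pay (USD/QALY)",
                  y = "probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' One-row summary of a PSA run
#'
#' @param x a `vitd_psa` tibble from [run_psa()].
#' @param ... unused.
#' @return one-row tibble: draw count, seed, capped-draw count, mean outcomes
#'   per strategy, mean increments, probability the intervention is dominant,
#'   and its acceptability at the analysis WTP.
#' @method glance vitd_psa
#' @export
glance.vitd_psa <- function(x, ...) {
  wtp <- attr(x, "wtp")
  tibble::tibble(
    n = attr(x, "n"), seed = attr(x, "seed"), n_capped = attr(x, "n_capped"),
    mean_cost_vitd = mean(x$cost_vitd),
    mean_cost_no_suppl = mean(x$cost_no_suppl),
    mean_qaly_vitd = mean(x$qaly_vitd),
    mean_qaly_no_suppl = mean(x$qaly_no_suppl),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qaly = mean(x$delta_qaly),
    p_dominant = mean(x$delta_cost < 0 & x$delta_qaly > 0),
    p_ce_at_wtp = mean(wtp * x$delta_qaly - x$delta_cost > 0),
    wtp = wtp
  )
}
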