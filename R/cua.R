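#' Base-case cost-utility analysis
#'
#' Builds the two-strategy decision tree at the point values of `params`,
#' rolls both strategies back, and computes the incremental comparison of
#' vitamin D supplementation (intervention) against no supplementation
#' (comparator): signed increments (intervention minus comparator), net
#' monetary benefit per strategy at `params$settings$wtp`, and a dominance /
#' ICER classification via [classify_increment()].
#'
#' When `scale_by_horizon` is on, expected utilities are multiplied by
#' `horizon_days / 365` to express QALYs over the model horizon; by default
#' they are reported as unscaled expected utility weights.
#'
#' @param params a [vitd_parameters()] object.
#' @return an object of class `vitd_cua`. Use [tidy.vitd_cua()] for the
#'   per-strategy table and [glance.vitd_cua()] for the incremental summary.
#' @examples
#' res <- evaluate_base_case(vitd_parameters())
#' tidy(res)
#' glance(res)
#' @export
evaluate_base_case <- function(params) {
  stopifnot(inherits(params, "vitd_params"))
  trees <- build_vitd_tree(params)
  per <- dplyr::bind_rows(rollback(trees$no_suppl), rollback(trees$vitd))
  if (params$settings$scale_by_horizon) {
    per$expected_qaly <- per$expected_qaly * params$settings$horizon_days / 365
  }
  wtp <- params$settings$wtp
  per$nmb <- net_monetary_benefit(per$expected_cost, per$expected_qaly, wtp)

  comp <- per[per$strategy == "no-supplementation", ]
  intv <- per[per$strategy == "vitamin-D", ]
  delta_cost <- intv$expected_cost - comp$expected_cost
  delta_qaly <- intv$expected_qaly - comp$expected_qaly
  cls <- classify_increment(delta_cost, delta_qaly)

  structure(
    list(per_strategy = per,
         delta_cost = delta_cost, delta_qaly = delta_qaly,
         savings = -delta_cost, qaly_gain = delta_qaly,
         incremental_nmb = wtp * delta_qaly - delta_cost,
         wtp = wtp, classification = cls$classification, icer = cls$icer,
         params = params),
    class = "vitd_cua")
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`: the monetary value of the health produced at a
#' willingness-to-pay of `wtp` per QALY, minus the cost of producing it. The
#' strategy maximizing NMB at a given `wtp` is optimal at that threshold.
#' Vectorized over all three arguments.
#'
#' @param cost expected cost, USD.
#' @param qaly expected QALYs (or utility weight).
#' @param wtp willingness-to-pay per QALY, USD; must be >= 0.
#' @return numeric NMB in USD.
#' @examples
#' net_monetary_benefit(1354, 0.99, 19000)
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  stopifnot(is.numeric(cost), is.numeric(qaly), is.numeric(wtp))
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * qaly - cost
}

#' Classify an incremental comparison
#'
#' Signed increments are intervention minus comparator. The intervention is
#' *dominant* when it costs less and yields more QALYs, *dominated* when the
#' reverse holds; with no QALY difference the cheaper strategy dominates by
#' cost; otherwise the trade-off is summarised by the incremental
#' cost-effectiveness ratio `delta_cost / delta_qaly`. Two strategies with
#' identical costs and QALYs carry no decision information and are flagged
#' rather than divided.
#'
#' @param delta_cost incremental cost (intervention - comparator), USD.
#' @param delta_qaly incremental QALYs (intervention - comparator).
#' @return list with `classification` (one of "intervention-dominant",
#'   "intervention-dominated", "dominant-by-cost", "dominated-by-cost",
#'   "icer", "identical-strategies") and `icer` (numeric, `NA` unless
#'   classification is "icer").
#' @examples
#' classify_increment(-594, 0.01)
#' classify_increment(100, 0.01)
#' @export
classify_increment <- function(delta_cost, delta_qaly) {
  stopifnot(is.numeric(delta_cost), length(delta_cost) == 1L,
            is.numeric(delta_qaly), length(delta_qaly) == 1L)
  if (delta_cost == 0 && delta_qaly == 0) {
    return(list(classification = "identical-strategies", icer = NA_real_))
  }
  if (delta_qaly == 0) {
    cls <- if (delta_cost < 0) "dominant-by-cost" else "dominated-by-cost"
    return(list(classification = cls, icer = NA_real_))
  }
  if (delta_cost < 0 && delta_qaly > 0) {
    return(list(classification = "intervention-dominant", icer = NA_real_))
  }
  if (delta_cost > 0 && delta_qaly < 0) {
    return(list(classification = "intervention-dominated", icer = NA_real_))
  }
  list(classification = "icer", icer = delta_cost / delta_qaly)
}

#' Episode cost above which supplementation is cost-saving
#'
#' Closed-form consequence of the tree: the intervention's incremental cost is
#' `c_vitd_day * suppl_days - p_ari * (1 - rr_vitd) * episode_cost`, so it
#' saves money exactly when the per-episode cost exceeds
#' `c_vitd_day * suppl_days / (p_ari * (1 - rr_vitd))`. Useful for judging how
#' robust the cost-saving finding is to the costed episode.
#'
#' @param params a [vitd_parameters()] object with `rr_vitd < 1` and
#'   `p_ari > 0`.
#' @return threshold episode cost in USD, or `NA` with a warning when
#'   `rr_vitd >= 1` (supplementation prevents nothing, so no episode cost can
#'   make it cost-saving).
#' @examples
#' dominance_threshold_episode_cost(vitd_parameters())
#' @export
dominance_threshold_episode_cost <- function(params) {
  stopifnot(inherits(params, "vitd_params"))
  v <- params$values
  if (v[["rr_vitd"]] >= 1) {
    warning("no threshold: rr_vitd >= 1, supplementation cannot be cost-saving",
            call. = FALSE)
    return(NA_real_)
  }
  if (v[["p_ari"]] <= 0) {
    warning("no threshold: p_ari = 0", call. = FALSE)
    return(NA_real_)
  }
  v[["c_vitd_day"]] * params$settings$suppl_days /
    (v[["p_ari"]] * (1 - v[["rr_vitd"]]))
}

#' @export
print.vitd_cua <- function(x, ...) {
  cat("<vitd_cua> base-case cost-utility analysis\n")
  print(tidy(x))
  cat(sprintf("classification: %s", x$classification))
  if (!is.na(x$icer)) cat(sprintf(" (ICER %.2f per QALY)", x$icer))
  cat(sprintf("\nincrements (intervention - comparator): cost %.2f, QALY %.6f\n",
              x$delta_cost, x$delta_qaly))
  cat(sprintf("incremental NMB at WTP %g: %.2f\n", x$wtp, x$incremental_nmb))
  invisible(x)
}

#' Tidy the per-strategy base-case results
#'
#' One row per strategy, shaped like the published cost-effectiveness table:
#' cost, cost difference (savings orientation: comparator minus intervention,
#' printed on the comparator row), QALYs, QALY difference, and NMB.
#'
#' @param x a `vitd_cua` object from [evaluate_base_case()].
#' @param ... unused.
#' @return tibble with columns `strategy`, `cost`, `diff_cost`, `qaly`,
#'   `diff_qaly`, `nmb`.
#' @method tidy vitd_cua
#' @export
tidy.vitd_cua <- function(x, ...) {
  per <- x$per_strategy
  comp_row <- per$strategy == "no-supplementation"
  tibble::tibble(
    strategy = per$strategy,
    cost = per$expected_cost,
    diff_cost = ifelse(comp_row, x$savings, NA_real_),
    qaly = per$expected_qaly,
    diff_qaly = ifelse(comp_row, x$qaly_gain, NA_real_),
    nmb = per$nmb
  )
}

#' One-row summary of the incremental comparison
#'
#' @param x a `vitd_cua` object from [evaluate_base_case()].
#' @param ... unused.
#' @return one-row tibble: `delta_cost`, `delta_qaly`, `incremental_nmb`,
#'   `wtp`, `classification`, `icer`.
#' @method glance vitd_cua
#' @export
glance.vitd_cua <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    incremental_nmb = x$incremental_nmb, wtp = x$wtp,
    classification = x$classification, icer = x$icer
  )
}
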