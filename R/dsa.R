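#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each of the seven uncertain inputs is moved in turn to the low and high
#' ends of its equal-tailed `level` interval (from [interval_bounds()], so the
#' range reflects the same uncertainty the probabilistic analysis samples),
#' all other inputs held at base values, and the base case is re-evaluated.
#' The output metric defaults to the incremental net monetary benefit at the
#' table's willingness-to-pay, which captures both the cost and the QALY
#' channel; `delta_cost` and `delta_qaly` isolate one channel each. Entries
#' are sorted by descending output swing (ties broken by parameter name), the
#' order bars take in a tornado diagram.
#'
#' @param params a [vitd_parameters()] object.
#' @param metric which incremental output to record: `"incremental_nmb"`
#'   (default), `"delta_cost"` or `"delta_qaly"` (intervention minus
#'   comparator).
#' @param level coverage of the one-way interval; default 0.95.
#' @return tibble of class `vitd_tornado`, one row per parameter:
#'   `parameter`, `low_input`, `high_input`, `low_output`, `high_output`,
#'   `range` (= `|high_output - low_output|`), plus attributes `metric`,
#'   `level`, `base_output`.
#' @examples
#' one_way_tornado(vitd_parameters(), metric = "delta_cost")
#' @export
one_way_tornado <- function(params,
                            metric = c("incremental_nmb", "delta_cost",
                                       "delta_qaly"),
                            level = 0.95) {
  stopifnot(inherits(params, "vitd_params"))
  metric <- match.arg(metric)
  pull_metric <- function(p) {
    res <- evaluate_base_case(p)
    switch(metric,
           incremental_nmb = res$incremental_nmb,
           delta_cost = res$delta_cost,
           delta_qaly = res$delta_qaly)
  }
  base_output <- pull_metric(params)

  rows <- purrr::map_dfr(uncertain_parameters(), function(nm) {
    b <- interval_bounds(params$dists[[nm]], level)
    # p_ari * rr_vitd can exceed 1 at an upper bound; clamp to the feasible
    # region so the substituted table still validates
    clamp <- function(x) clamp_substitution(params, nm, x)
    lo <- clamp(b[["low"]])
    hi <- clamp(b[["high"]])
    tibble::tibble(
      parameter = nm,
      low_input = lo, high_input = hi,
      low_output = pull_metric(substitute_value(params, nm, lo)),
      high_output = pull_metric(substitute_value(params, nm, hi))
    )
  })
  rows$range <- abs(rows$high_output - rows$low_output)
  rows <- dplyr::arrange(rows, dplyr::desc(.data$range), .data$parameter)

  structure(rows, class = c("vitd_tornado", class(rows)),
            metric = metric, level = level, base_output = base_output)
}

# keep a one-way substitution inside the joint feasibility region
clamp_substitution <- function(params, name, value) {
  v <- params$values
  if (name == "rr_vitd" && v[["p_ari"]] > 0) {
    value <- min(value, 1 / v[["p_ari"]])
  }
  if (name == "p_ari" && v[["rr_vitd"]] > 0) {
    value <- min(value, min(1, 1 / v[["rr_vitd"]]))
  }
  value
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high output, widest swing on
#' top, with a vertical reference line at the base-case output.
#'
#' @param object a `vitd_tornado` tibble from [one_way_tornado()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot vitd_tornado
#' @export
autoplot.vitd_tornado <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$low_output, xend = .data$high_output,
                   yend = .data$parameter),
      linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_output"),
                        linetype = "dashed") +
    ggplot2::labs(
      x = attr(object, "metric"), y = NULL,
      title = "One-way sensitivity (tornado)",
      subtitle = sprintf("bars span the equal-tailed %g%% interval of each input",
                         100 * attr(object, "level"))) +
    ggplot2::theme_minimal()
}
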