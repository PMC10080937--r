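#' Write an analysis result to CSV or JSON
#'
#' Serializes the package's result objects with a deterministic layout:
#' columns in a fixed order, costs formatted to 2 decimals and
#' probabilities/utilities to 6 decimals in CSV, full precision in JSON.
#' CSV files begin with `#`-prefixed provenance lines (package version and,
#' where the object carries them, seed, draw count and configuration hash);
#' identical inputs therefore produce byte-identical files. Read the CSVs
#' back with `read.csv(..., comment.char = "#")`.
#'
#' @param x a `vitd_cua`, `vitd_tornado`, `vitd_psa`, `vitd_ceac` object, or
#'   any data frame.
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tab <- as_results_table(x)
  if (format == "json") {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
    return(invisible(path))
  }
  header <- c(sprintf("# vitdcea %s",
                      as.character(utils::packageVersion("vitdcea"))))
  for (key in c("seed", "n", "n_capped", "config_hash", "wtp")) {
    val <- attr(x, key, exact = TRUE)
    if (!is.null(val)) header <- c(header, sprintf("# %s: %s", key, val))
  }
  fmt <- vapply(names(tab), function(nm) {
    if (!is.numeric(tab[[nm]])) return("s")
    if (grepl("cost|nmb|wtp|input|output|range|icer", nm)) "money" else "fine"
  }, character(1))
  lines <- paste(names(tab), collapse = ",")
  if (nrow(tab) > 0) {
    cells <- vapply(seq_along(tab), function(j) {
      col <- tab[[j]]
      switch(fmt[j],
             s = as.character(col),
             money = sprintf("%.2f", col),
             fine = sprintf("%.6f", col))
    }, character(nrow(tab)))
    cells <- matrix(cells, nrow = nrow(tab))
    cells[is.na(tab)] <- ""
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

# canonical tabular form of each result type
as_results_table <- function(x) {
  if (inherits(x, "vitd_cua")) return(tidy(x))
  tibble::as_tibble(x)
}

#' Build a run manifest for provenance
#'
#' Records everything needed to reproduce a run: a hash of the configuration,
#' the package version, seed, draw count, the subcommand and output paths,
#' and a timestamp. Identical configuration, seed and draw count imply
#' identical numerical outputs; the timestamp lives only in the manifest, so
#' result files themselves stay byte-identical across reruns.
#'
#' @param params a [vitd_parameters()] object.
#' @param subcommand name of the analysis stage.
#' @param seed,n_draws seed and draw count used (`NA` where not applicable).
#' @param outputs character vector of output paths.
#' @return a list of class `vitd_manifest`.
#' @export
run_manifest <- function(params, subcommand, seed = NA, n_draws = NA,
                         outputs = character(0)) {
  stopifnot(inherits(params, "vitd_params"))
  structure(list(
    config_hash = config_hash(params),
    package_version = as.character(utils::packageVersion("vitdcea")),
    seed = seed, n_draws = n_draws,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    subcommand = subcommand, outputs = outputs
  ), class = "vitd_manifest")
}

#' @export
print.vitd_manifest <- function(x, ...) {
  cat("<vitd_manifest>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

config_hash <- function(params) {
  rlang::hash(list(params$values, params$settings,
                   lapply(params$dists, unclass)))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
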