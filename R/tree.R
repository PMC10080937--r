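#' Decision-tree building blocks
#'
#' A strategy's tree is a recursive structure of chance nodes whose leaves are
#' terminal health states carrying a cost payoff (USD, >= 0) and a utility
#' weight in \[0, 1\]. Branch probabilities at every chance node must sum to 1
#' (tolerance 1e-12, checked by [validate_tree()]).
#'
#' @param label terminal state label (free text; the supplementation model uses
#'   "death-after-ARI", "survival-after-ARI", "survival-without-ARI",
#'   "death-all-causes").
#' @param cost cost payoff accrued on reaching this terminal, USD.
#' @param utility utility weight of the terminal, in \[0, 1\].
#' @return `terminal_node()` returns a `terminal_node`; `chance_node()` a
#'   `chance_node`; `strategy()` a `vitd_strategy`.
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
terminal_node <- function(label, cost, utility) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(cost), length(cost) == 1L,
            is.numeric(utility), length(utility) == 1L)
  structure(list(label = label, cost = cost, utility = utility),
            class = "terminal_node")
}

#' @rdname tree-nodes
#' @param probs numeric vector of branch probabilities.
#' @param children list of child nodes (terminal or chance), same length as
#'   `probs`.
#' @export
chance_node <- function(probs, children) {
  stopifnot(is.numeric(probs), is.list(children),
            length(probs) == length(children), length(probs) >= 1L)
  structure(list(probs = probs, children = children), class = "chance_node")
}

#' @rdname tree-nodes
#' @param name strategy name.
#' @param root the root `chance_node` (or a single `terminal_node` for a
#'   degenerate strategy).
#' @export
strategy <- function(name, root) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(root, "chance_node") || inherits(root, "terminal_node"))
  structure(list(name = name, root = root), class = "vitd_strategy")
}

#' Build the two-strategy vitamin D decision tree
#'
#' Constructs the published model: under "no-supplementation" a child has an
#' ARI with probability `p_ari` and then dies with the ARI case fatality
#' `m_ari` or survives with utility `1 - du_ari`; with probability `1 - p_ari`
#' the child stays ARI-free and dies of any cause with probability `m_all` or
#' survives with utility 1. The "vitamin-D" strategy is structurally identical
#' with ARI probability `p_ari * rr_vitd`, and the supplementation cost
#' `c_vitd_day * suppl_days` added to every terminal (including deaths). ARI
#' terminals (deaths included) accrue the episode cost
#' `c_ari_day * episode_days`; ARI-free terminals accrue no disease cost;
#' deaths have utility 0.
#'
#' @param params a [vitd_parameters()] object.
#' @return named list of two [strategy()] objects, `no_suppl` and `vitd`.
#' @examples
#' trees <- build_vitd_tree(vitd_parameters())
#' rollback(trees$vitd)
#' @export
build_vitd_tree <- function(params) {
  stopifnot(inherits(params, "vitd_params"))
  v <- params$values
  s <- params$settings
  p_ari_suppl <- v[["p_ari"]] * v[["rr_vitd"]]
  if (p_ari_suppl > 1) {
    stop("infeasible probability: p_ari * rr_vitd = ", p_ari_suppl,
         " exceeds 1", call. = FALSE)
  }
  episode_cost <- v[["c_ari_day"]] * s$episode_days
  suppl_cost <- v[["c_vitd_day"]] * s$suppl_days

  arm <- function(p_ari, extra_cost) {
    ari <- chance_node(
      probs = c(v[["m_ari"]], 1 - v[["m_ari"]]),
      children = list(
        terminal_node("death-after-ARI", episode_cost + extra_cost, 0),
        terminal_node("survival-after-ARI", episode_cost + extra_cost,
                      1 - v[["du_ari"]])
      )
    )
    no_ari <- chance_node(
      probs = c(v[["m_all"]], 1 - v[["m_all"]]),
      children = list(
        terminal_node("death-all-causes", extra_cost, 0),
        terminal_node("survival-without-ARI", extra_cost, 1)
      )
    )
    chance_node(probs = c(p_ari, 1 - p_ari), children = list(ari, no_ari))
  }

  list(
    no_suppl = strategy("no-supplementation", arm(v[["p_ari"]], 0)),
    vitd = strategy("vitamin-D", arm(p_ari_suppl, suppl_cost))
  )
}

#' Roll back a strategy to its expected cost and utility
#'
#' Probability-weighted recursion over the tree: at each chance node the
#' expectation is the probability-weighted sum of its children's; at a
#' terminal it is the payoff pair. Agrees with aggregating
#' [enumerate_paths()] to within floating-point error.
#'
#' @param strat a [strategy()] object.
#' @return one-row tibble with columns `strategy`, `expected_cost`,
#'   `expected_qaly`.
#' @export
rollback <- function(strat) {
  stopifnot(inherits(strat, "vitd_strategy"))
  check_tree(strat)
  rec <- function(node) {
    if (inherits(node, "terminal_node")) {
      return(c(node$cost, node$utility))
    }
    vals <- vapply(node$children, rec, numeric(2))
    c(sum(node$probs * vals[1L, ]), sum(node$probs * vals[2L, ]))
  }
  eu <- rec(strat$root)
  tibble::tibble(strategy = strat$name,
                 expected_cost = eu[1L], expected_qaly = eu[2L])
}

#' Enumerate every root-to-leaf path of a strategy
#'
#' Independent of [rollback()]: walks every path, multiplying branch
#' probabilities, and returns one record per terminal reached. Aggregating
#' `sum(probability * cost)` and `sum(probability * utility)` reproduces the
#' roll-back expectations; path probabilities sum to 1.
#'
#' @param strat a [strategy()] object.
#' @return tibble with columns `path` (branch indices, "/"-separated),
#'   `label`, `probability`, `cost`, `utility`.
#' @export
enumerate_paths <- function(strat) {
  stopifnot(inherits(strat, "vitd_strategy"))
  check_tree(strat)
  acc <- list()
  walk <- function(node, prob, trail) {
    if (inherits(node, "terminal_node")) {
      acc[[length(acc) + 1L]] <<- tibble::tibble(
        path = paste(trail, collapse = "/"),
        label = node$label, probability = prob,
        cost = node$cost, utility = node$utility)
      return(invisible(NULL))
    }
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], prob * node$probs[i], c(trail, i))
    }
  }
  walk(strat$root, 1, character(0))
  dplyr::bind_rows(acc)
}

#' Validate a strategy's tree
#'
#' Checks every chance node's branch probabilities (each in \[0, 1\], summing
#' to 1 within 1e-12) and every terminal payoff (cost >= 0, utility in
#' \[0, 1\]). Returns a report instead of erroring, so malformed candidate
#' trees can be inspected.
#'
#' @param strat a [strategy()] object.
#' @return tibble with columns `node` (path from the root), `check`,
#'   `message`; zero rows for a well-formed tree.
#' @export
validate_tree <- function(strat) {
  stopifnot(inherits(strat, "vitd_strategy"))
  acc <- list()
  note <- function(node_path, check, message) {
    acc[[length(acc) + 1L]] <<- tibble::tibble(
      node = node_path, check = check, message = message)
  }
  walk <- function(node, trail) {
    path <- if (length(trail) == 0) "root" else paste(trail, collapse = "/")
    if (inherits(node, "terminal_node")) {
      if (!is.finite(node$cost) || node$cost < 0) {
        note(path, "cost_payoff",
             sprintf("cost payoff %g outside [0, Inf)", node$cost))
      }
      if (!is.finite(node$utility) || node$utility < 0 || node$utility > 1) {
        note(path, "utility_payoff",
             sprintf("utility payoff %g outside [0, 1]", node$utility))
      }
      return(invisible(NULL))
    }
    if (any(!is.finite(node$probs)) || any(node$probs < 0) ||
        any(node$probs > 1)) {
      note(path, "branch_probability", "branch probability outside [0, 1]")
    }
    if (abs(sum(node$probs) - 1) > 1e-12) {
      note(path, "probability_sum",
           sprintf("branch probabilities sum to %.15g, not 1", sum(node$probs)))
    }
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], c(trail, i))
    }
  }
  walk(strat$root, character(0))
  if (length(acc) == 0) {
    tibble::tibble(node = character(0), check = character(0),
                   message = character(0))
  } else {
    dplyr::bind_rows(acc)
  }
}

# error (rather than report) on a malformed tree before evaluation
check_tree <- function(strat) {
  rep <- validate_tree(strat)
  if (nrow(rep) > 0) {
    stop("validation error: malformed tree at ", rep$node[1L], ": ",
         rep$message[1L], call. = FALSE)
  }
  invisible(strat)
}

#' Serialize a strategy tree to JSON (and back)
#'
#' Trees round-trip through a plain JSON document (node type, label,
#' probabilities, payoffs), used by fixtures and the command line's
#' `--dump-tree`.
#'
#' @param strat a [strategy()] object.
#' @param path output path for `write_tree_json()`; input path for
#'   `read_tree_json()`.
#' @return `write_tree_json()` returns `path` invisibly; `read_tree_json()`
#'   the reconstructed [strategy()].
#' @export
write_tree_json <- function(strat, path) {
  stopifnot(inherits(strat, "vitd_strategy"))
  to_list <- function(node) {
    if (inherits(node, "terminal_node")) {
      list(type = "terminal", label = node$label, cost = node$cost,
           utility = node$utility)
    } else {
      list(type = "chance", probs = node$probs,
           children = lapply(node$children, to_list))
    }
  }
  jsonlite::write_json(list(name = strat$name, root = to_list(strat$root)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  from_list <- function(x) {
    if (identical(x$type, "terminal")) {
      terminal_node(x$label, x$cost, x$utility)
    } else {
      chance_node(vapply(x$probs, as.numeric, numeric(1)),
                  lapply(x$children, from_list))
    }
  }
  strategy(doc$name, from_list(doc$root))
}
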