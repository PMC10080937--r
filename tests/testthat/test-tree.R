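test_that("the supplementation tree encodes the four health states per arm", {
  trees <- build_vitd_tree(table1_params())
  for (strat in trees) {
    paths <- enumerate_paths(strat)
    expect_identical(nrow(paths), 4L)
    expect_setequal(paths$label,
                    c("death-after-ARI", "survival-after-ARI",
                      "survival-without-ARI", "death-all-causes"))
    expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  }

  none <- enumerate_paths(trees$no_suppl)
  vitd <- enumerate_paths(trees$vitd)
  # supplemented-arm ARI probability is the baseline times the relative risk
  ari_prob <- function(paths) {
    sum(paths$probability[grepl("after-ARI", paths$label)])
  }
  expect_equal(ari_prob(none), 0.22, tolerance = 1e-12)
  expect_equal(ari_prob(vitd), 0.22 * 0.71, tolerance = 1e-12)
  # ARI terminals in the unsupplemented arm carry the full episode cost
  expect_equal(unique(none$cost[grepl("after-ARI", none$label)]), 8800)
  # every supplemented terminal additionally carries the supplement cost
  expect_equal(sort(vitd$cost - none$cost), rep(0.08 * 182, 4),
               tolerance = 1e-12)
  # deaths have utility zero; ARI survivors carry the disutility
  expect_identical(none$utility[none$label == "death-after-ARI"], 0)
  expect_identical(none$utility[none$label == "survival-after-ARI"], 0.94)
  expect_identical(none$utility[none$label == "survival-without-ARI"], 1)
})

test_that("a null intervention produces two identical trees", {
  params <- vitd_parameters(rr_vitd = 1, c_vitd_day = 0,
                            dists = list(rr_vitd = dist_spec("point", 1),
                                         c_vitd_day = dist_spec("point", 0)))
  trees <- build_vitd_tree(params)
  a <- enumerate_paths(trees$no_suppl)
  b <- enumerate_paths(trees$vitd)
  expect_identical(a$probability, b$probability)
  expect_identical(a$cost, b$cost)
  expect_identical(a$utility, b$utility)
})

test_that("roll-back reproduces the hand-enumerated base-case expectations", {
  trees <- build_vitd_tree(table1_params())
  none <- rollback(trees$no_suppl)
  vitd <- rollback(trees$vitd)
  # frozen from explicit path enumeration:
  # 0.22*0.9999*0.94 + 0.78*0.9992 and the same at ARI probability 0.1562
  expect_equal(none$expected_qaly, 0.98615532, tolerance = 1e-9)
  expect_equal(vitd$expected_qaly, 0.9899382772, tolerance = 1e-9)
  expect_equal(none$expected_cost, 1936.00, tolerance = 1e-9)
  expect_equal(vitd$expected_cost, 0.1562 * 8800 + 14.56, tolerance = 1e-9)
})

test_that("roll-back equals path enumeration on seeded random trees", {
  for (s in 1:300) {
    strat <- random_tree(seed = s, depth = (s %% 3) + 1,
                         branching = 2 + (s %% 2))
    rb <- rollback(strat)
    oracle <- paths_expectation(strat)
    expect_equal(rb$expected_cost, oracle[["cost"]], tolerance = 1e-9)
    expect_equal(rb$expected_qaly, oracle[["utility"]], tolerance = 1e-9)
  }
})

test_that("degenerate single-terminal strategy yields one certain path", {
  strat <- strategy("certain", terminal_node("only", 5, 0.5))
  paths <- enumerate_paths(strat)
  expect_identical(nrow(paths), 1L)
  expect_identical(paths$probability, 1)
  rb <- rollback(strat)
  expect_identical(rb$expected_cost, 5)
  expect_identical(rb$expected_qaly, 0.5)
})

test_that("validate_tree reports probability and payoff violations with paths", {
  good <- build_vitd_tree(table1_params())$vitd
  expect_identical(nrow(validate_tree(good)), 0L)

  bad_probs <- strategy("bad", chance_node(
    c(0.6, 0.6), list(terminal_node("a", 0, 1), terminal_node("b", 0, 1))))
  rep1 <- validate_tree(bad_probs)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$check, "probability_sum")
  expect_identical(rep1$node, "root")

  bad_util <- strategy("bad", chance_node(
    c(0.5, 0.5), list(terminal_node("a", 0, 1.2), terminal_node("b", 0, 1))))
  rep2 <- validate_tree(bad_util)
  expect_identical(rep2$check, "utility_payoff")
  expect_identical(rep2$node, "1")

  # evaluation refuses malformed trees
  expect_error(rollback(bad_probs), "validation error")
  expect_error(enumerate_paths(bad_util), "validation error")
})

test_that("engine increments obey the closed-form identities", {
  for (s in 1:300) {
    params <- random_scenario(seed = 10000 + s)
    res <- evaluate_base_case(params)
    cf <- closed_form_increments(params)
    expect_lt(abs(res$delta_qaly - cf[["delta_qaly"]]), 1e-12)
    expect_lt(abs(res$delta_cost - cf[["delta_cost"]]),
              1e-12 * cost_scale(params))
  }
})

test_that("supplemented-arm outcomes are monotone in the relative risk", {
  rr_grid <- seq(0.4, 1.0, by = 0.05)
  outs <- vapply(rr_grid, function(rr) {
    p <- vitd_parameters(rr_vitd = rr,
                         dists = list(rr_vitd = dist_spec("lognormal", rr, 0.11)))
    rb <- rollback(build_vitd_tree(p)$vitd)
    c(rb$expected_cost, rb$expected_qaly)
  }, numeric(2))
  # higher rr = less prevention: cost rises, utility falls
  # (du*(1-m_ari) > m_all - m_ari holds at base values)
  expect_true(all(diff(outs[1, ]) > 0))
  expect_true(all(diff(outs[2, ]) < 0))
})

test_that("infeasible joint probability is refused at tree construction", {
  expect_error(
    vitd_parameters(p_ari = 0.9, rr_vitd = 1.2,
                    dists = list(rr_vitd = dist_spec("lognormal", 1.2, 0.11))),
    "exceeds 1")
})

test_that("trees round-trip through JSON", {
  strat <- random_tree(seed = 5, depth = 3, branching = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(strat, path)
  back <- read_tree_json(path)
  a <- enumerate_paths(strat)
  b <- enumerate_paths(back)
  expect_identical(b$label, a$label)
  # payoffs survive to within JSON text-serialization precision (~1 ulp)
  expect_equal(b$probability, a$probability, tolerance = 1e-12)
  expect_equal(b$cost, a$cost, tolerance = 1e-12)
  expect_equal(b$utility, a$utility, tolerance = 1e-12)
})
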