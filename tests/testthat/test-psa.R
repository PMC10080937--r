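test_that("identical seed gives bitwise-identical draws; distinct seeds differ", {
  params <- table1_params()
  a <- sample_parameter_draws(params, 500, seed = 7)
  b <- sample_parameter_draws(params, 500, seed = 7)
  expect_identical(a, b)
  c <- sample_parameter_draws(params, 500, seed = 8)
  expect_false(identical(a$p_ari, c$p_ari))
  # every draw respects its support
  expect_true(all(a$p_ari > 0 & a$p_ari < 1))
  expect_true(all(a$rr_vitd > 0))
  expect_true(all(a$c_ari_day > 0))
})

test_that("point distributions reproduce the base table in every draw", {
  v <- table1_params()$values
  frozen <- vitd_parameters(dists = stats::setNames(
    lapply(names(v), function(nm) dist_spec("point", v[[nm]])), names(v)))
  d <- sample_parameter_draws(frozen, 50, seed = 1)
  for (nm in names(v)) expect_identical(unique(d[[nm]]), v[[nm]])
})

test_that("sampling recovers the published moments at n = 10,000", {
  params <- table1_params()
  d <- sample_parameter_draws(params, 10000, seed = 123)
  for (nm in names(params$dists)) {
    spec <- params$dists[[nm]]
    if (spec$family == "lognormal") {
      # median check on the log scale
      z <- (mean(log(d[[nm]])) - log(spec$center)) / (spec$spread / sqrt(10000))
    } else {
      z <- (mean(d[[nm]]) - spec$center) / (spec$spread / sqrt(10000))
    }
    expect_lt(abs(z), 4)
  }
})

test_that("moment_recovery_report flags only a mis-parameterized sampler", {
  expect_false(moment_recovery_report(dist_spec("beta", 0.22, 0.005),
                                      10000, seed = 5)$flagged)
  expect_false(moment_recovery_report(dist_spec("gamma", 880, 222),
                                      10000, seed = 5)$flagged)
  # a sampler whose mean is off by 10 SE must be caught: compare draws from a
  # deliberately shifted distribution against the original target
  shifted <- dist_spec("beta", 0.22 + 10 * 0.005 / sqrt(10000), 0.005)
  rep <- moment_recovery_report(shifted, 10000, seed = 5)
  z_against_original <- (rep$empirical_mean - 0.22) / (0.005 / sqrt(10000))
  expect_gt(abs(z_against_original), 4)
})

test_that("per-draw tree evaluation matches the recursive engine", {
  params <- table1_params()
  psa <- run_psa(params, 200, seed = 31)
  for (i in seq_len(50)) {
    row <- psa[i, ]
    p_i <- vitd_parameters(
      p_ari = row$p_ari, rr_vitd = row$rr_vitd, m_ari = row$m_ari,
      m_all = row$m_all, du_ari = row$du_ari, c_ari_day = row$c_ari_day,
      c_vitd_day = row$c_vitd_day,
      dists = list(
        p_ari = dist_spec("point", row$p_ari),
        rr_vitd = dist_spec("point", row$rr_vitd),
        m_ari = dist_spec("point", row$m_ari),
        m_all = dist_spec("point", row$m_all),
        du_ari = dist_spec("point", row$du_ari),
        c_ari_day = dist_spec("point", row$c_ari_day),
        c_vitd_day = dist_spec("point", row$c_vitd_day)))
    trees <- build_vitd_tree(p_i)
    none <- rollback(trees$no_suppl)
    vitd <- rollback(trees$vitd)
    expect_equal(row$cost_no_suppl, none$expected_cost, tolerance = 1e-12)
    expect_equal(row$qaly_no_suppl, none$expected_qaly, tolerance = 1e-12)
    expect_equal(row$cost_vitd, vitd$expected_cost, tolerance = 1e-12)
    expect_equal(row$qaly_vitd, vitd$expected_qaly, tolerance = 1e-12)
  }
})

test_that("per-draw increments obey the closed-form identities", {
  psa <- run_psa(table1_params(), 2000, seed = 17)
  dq <- psa$p_ari * (1 - psa$rr_vitd) *
    ((1 - psa$m_all) - (1 - psa$m_ari) * (1 - psa$du_ari))
  dc <- psa$c_vitd_day * 182 - psa$p_ari * (1 - psa$rr_vitd) *
    psa$c_ari_day * 10
  uncapped <- psa$p_ari * psa$rr_vitd <= 1
  expect_true(all(abs(psa$delta_qaly - dq)[uncapped] < 1e-12))
  expect_true(all(abs(psa$delta_cost - dc)[uncapped] < 1e-12 * 30000))
})

test_that("null scenario yields exactly zero increments in every draw", {
  psa <- run_psa(null_scenario(), 1000, seed = 3)
  expect_identical(unique(psa$delta_cost), 0)
  expect_identical(unique(psa$delta_qaly), 0)
})

test_that("PSA means agree with the plug-in roll-back within Monte Carlo error", {
  params <- table1_params()
  psa <- run_psa(params, 10000, seed = 77)
  base <- evaluate_base_case(params)
  per <- base$per_strategy
  for (pair in list(c("qaly_vitd", "vitamin-D"),
                    c("qaly_no_suppl", "no-supplementation"))) {
    x <- psa[[pair[1]]]
    plug_in <- per$expected_qaly[per$strategy == pair[2]]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - plug_in), 4 * se)
  }
})

test_that("infeasible p_ari * rr draws are capped and counted", {
  # a scenario where rr draws frequently exceed 1/p_ari
  params <- vitd_parameters(
    p_ari = 0.9, rr_vitd = 1.05,
    dists = list(p_ari = dist_spec("beta", 0.9, 0.02),
                 rr_vitd = dist_spec("lognormal", 1.05, 0.2)))
  psa <- run_psa(params, 2000, seed = 9)
  expect_gt(attr(psa, "n_capped"), 0)
  p_suppl <- pmin(psa$p_ari * psa$rr_vitd, 1)
  expect_true(all(p_suppl <= 1))
  # resampling instead removes them and leaves feasible pairs
  psa2 <- run_psa(params, 2000, seed = 9, resample_infeasible = TRUE)
  expect_identical(attr(psa2, "n_capped"), 0L)
  expect_true(all(psa2$p_ari * psa2$rr_vitd <= 1))
})

test_that("the acceptability curve is a complement pair with comparator ties", {
  psa <- run_psa(table1_params(), 2000, seed = 21)
  grid <- seq(0, 60000, by = 2000)
  ceac <- ceac_curve(psa, grid)
  expect_identical(ceac$wtp, as.numeric(grid))
  expect_true(all(ceac$p_vitd + ceac$p_no_suppl == 1))
  expect_true(all(ceac$p_vitd >= 0 & ceac$p_vitd <= 1))

  # null scenario but with a real supplement cost: every draw has
  # delta NMB = -cost < 0, so the intervention is never preferred
  params0 <- vitd_parameters(
    rr_vitd = 1, dists = list(rr_vitd = dist_spec("point", 1)))
  psa0 <- run_psa(params0, 500, seed = 2)
  ceac0 <- ceac_curve(psa0, grid)
  expect_identical(unique(ceac0$p_vitd), 0)

  # exact ties (all increments zero) go to the comparator
  psa_null <- run_psa(null_scenario(), 200, seed = 2)
  ceac_null <- ceac_curve(psa_null, grid)
  expect_identical(unique(ceac_null$p_vitd), 0)
})

test_that("the acceptability curve is monotone when all draws gain QALYs", {
  psa <- run_psa(table1_params(), 5000, seed = 13)
  keep <- psa$delta_qaly >= 0
  filtered <- psa[keep, ]
  attr(filtered, "wtp") <- attr(psa, "wtp")
  class(filtered) <- class(psa)
  ceac <- ceac_curve(filtered, seq(0, 60000, by = 500))
  expect_true(all(diff(ceac$p_vitd) >= 0))
})

test_that("quadrant shares sum to one and match hand-built cases", {
  params <- table1_params()
  psa <- run_psa(params, 2000, seed = 5)
  qs <- quadrant_shares(psa)
  expect_equal(qs$ne + qs$se + qs$sw + qs$nw, 1, tolerance = 1e-12)
  # below-WTP share is the CEAC value at the same threshold
  ceac <- ceac_curve(psa, attr(psa, "wtp"))
  expect_identical(qs$below_wtp, ceac$p_vitd[1])

  # hand-built: one draw per open quadrant
  hand <- tibble::tibble(
    .draw = 1:4,
    delta_qaly = c(0.01, 0.01, -0.01, -0.01),
    delta_cost = c(100, -100, -100, 100))
  class(hand) <- c("vitd_psa", class(hand))
  attr(hand, "wtp") <- 19000
  qs4 <- quadrant_shares(hand)
  expect_identical(unname(unlist(qs4[c("ne", "se", "sw", "nw")])),
                   rep(0.25, 4))

  # boundary points assigned clockwise
  edge <- tibble::tibble(
    .draw = 1:4,
    delta_qaly = c(0.01, 0, -0.01, 0),
    delta_cost = c(0, -100, 0, 100))
  class(edge) <- c("vitd_psa", class(edge))
  attr(edge, "wtp") <- 19000
  qe <- quadrant_shares(edge)
  expect_identical(unname(unlist(qe[c("se", "sw", "nw", "ne")])),
                   rep(0.25, 4))
})

test_that("a dominant point-mass PSA is accepted at every threshold", {
  v <- table1_params()$values
  frozen <- vitd_parameters(dists = stats::setNames(
    lapply(names(v), function(nm) dist_spec("point", v[[nm]])), names(v)))
  psa <- run_psa(frozen, 100, seed = 1)
  expect_true(all(psa$delta_cost < 0) && all(psa$delta_qaly > 0))
  ceac <- ceac_curve(psa, seq(0, 60000, by = 10000))
  expect_identical(unique(ceac$p_vitd), 1)
  qs <- quadrant_shares(psa)
  expect_identical(qs$se, 1)
})

test_that("the frontier strategy maximizes mean NMB at every grid point", {
  psa <- run_psa(table1_params(), 2000, seed = 41)
  grid <- seq(0, 60000, by = 5000)
  fr <- acceptability_frontier(psa, grid)
  ceac <- ceac_curve(psa, grid)
  for (i in seq_along(grid)) {
    l <- grid[i]
    nmb_vitd <- mean(l * psa$qaly_vitd - psa$cost_vitd)
    nmb_none <- mean(l * psa$qaly_no_suppl - psa$cost_no_suppl)
    expect_equal(fr$mean_nmb[i], max(nmb_vitd, nmb_none), tolerance = 1e-12)
    expect_identical(fr$frontier[i],
                     if (nmb_vitd > nmb_none) "vitamin-D" else "no-supplementation")
    expect_identical(fr$ceac[i],
                     if (nmb_vitd > nmb_none) ceac$p_vitd[i] else ceac$p_no_suppl[i])
  }
  # null scenario with positive supplement cost: comparator everywhere
  params0 <- vitd_parameters(rr_vitd = 1,
                             dists = list(rr_vitd = dist_spec("point", 1)))
  fr0 <- acceptability_frontier(run_psa(params0, 300, seed = 4), grid)
  expect_identical(unique(fr0$frontier), "no-supplementation")
})

test_that("end-to-end PSA pipeline is reproducible under a fixed seed", {
  params <- table1_params()
  run1 <- run_psa(params, 1000, seed = 55)
  run2 <- run_psa(params, 1000, seed = 55)
  expect_identical(tibble::as_tibble(run1), tibble::as_tibble(run2))
  expect_identical(ceac_curve(run1, seq(0, 60000, 500)),
                   ceac_curve(run2, seq(0, 60000, 500)))
  expect_identical(quadrant_shares(run1), quadrant_shares(run2))
})

test_that("PSA plots build", {
  psa <- run_psa(table1_params(), 300, seed = 6)
  expect_s3_class(ggplot2::autoplot(psa), "ggplot")
  expect_s3_class(ggplot2::autoplot(ceac_curve(psa)), "ggplot")
})
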