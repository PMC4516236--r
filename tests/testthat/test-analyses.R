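lt <- test_life_table()
p <- amd_parameters()

test_that("validation metrics degenerate correctly with no disease", {
  v <- validate_model(zero_transition_parameters(), lt)
  expect_equal(v$prevalence_pct, 0)
  expect_equal(v$blindness_pct, 0)
  expect_true(is.na(v$unilateral_pct))
})

test_that("base-case validation metrics are epidemiologically plausible", {
  v <- validate_model(p, lt)
  expect_gt(v$prevalence_pct, 0.5)
  expect_lt(v$prevalence_pct, 3)
  expect_gt(v$unilateral_pct, 70)
  expect_gt(v$blindness_pct, 0.005)
  expect_lt(v$blindness_pct, 0.2)
})

test_that("slowing the fellow eye raises the unilateral proportion", {
  v_base <- validate_model(p, lt)
  # fellow-eye conversion at the (slower) first-eye rate
  v_slow <- validate_model(amd_parameters(list(pm_second = 0.0050)), lt)
  expect_gt(v_slow$unilateral_pct, v_base$unilateral_pct)
})

test_that("blindness reduction: boundaries and the two-age toy example", {
  pr <- amdscreen:::.run_pair(p, lt)
  same <- blindness_reduction(pr$nonscreened, pr$nonscreened, "crude")
  expect_equal(same$reduction_pct, 0)
  fake <- function(blind_flow, alive = rep(1, length(blind_flow))) {
    structure(list(per_age = data.frame(
      age = seq(40, length.out = length(blind_flow)),
      alive = alive, amd = 0, onset_flow = 0, blind_flow = blind_flow)),
      class = "amd_cohort")
  }
  expect_equal(blindness_reduction(fake(c(0, 0)), fake(c(0.01, 0.02)),
                                   "crude")$reduction_pct, 100)
  pop <- structure(data.frame(age = 40:41, weight = c(1, 1)),
                   class = c("amd_population", "data.frame"))
  toy_s <- fake(c(0.01, 0.02)); toy_n <- fake(c(0.02, 0.04))
  expect_equal(blindness_reduction(toy_s, toy_n, "crude")$reduction_pct, 50)
  expect_equal(blindness_reduction(toy_s, toy_n, "age_standardized",
                                   pop)$reduction_pct, 50)
  expect_error(blindness_reduction(fake(c(0, 0)), fake(c(0, 0))),
               "undefined")
})

test_that("screening reduces blindness and both increments are positive", {
  pr <- amdscreen:::.run_pair(p, lt)
  ce <- compare_strategies(pr$screened, pr$nonscreened, p)
  expect_gt(ce$inc_cost, 0)
  expect_gt(ce$inc_qaly, 0)
  expect_lt(pr$screened$tallies$person_blind,
            pr$nonscreened$tallies$person_blind)
  red <- blindness_reduction(pr$screened, pr$nonscreened, "crude")
  expect_gt(red$reduction_pct, 0)
  pop <- synth_population(1e5, "stationary", life_table = lt)
  red2 <- blindness_reduction(pr$screened, pr$nonscreened,
                              "age_standardized", pop)
  expect_gt(red2$reduction_pct, 0)
})

test_that("programme grid: singleton equals the base case, schedules honour
           the end age, increments all positive", {
  g <- grid_search_programs(50, 90, 5, params = p, life_table = lt)
  expect_equal(nrow(g), 1)
  pr <- amdscreen:::.run_pair(p, lt)
  ce <- compare_strategies(pr$screened, pr$nonscreened, p)
  expect_equal(g$icer_jpy, ce$icer_jpy, tolerance = 1e-9)
  small <- grid_search_programs(c(50, 60), c(60, 90), c(5, 6),
                                params = p, life_table = lt)
  expect_true(all(small$inc_cost > 0))
  expect_true(all(small$inc_qaly > 0))
  expect_true(all(small$dominance == "tradeoff"))
  # infeasible start > end combinations are skipped
  g2 <- grid_search_programs(c(50, 70), 60, 5, params = p, life_table = lt)
  expect_equal(nrow(g2), 1)
  expect_error(grid_search_programs(70, 60, 5, params = p, life_table = lt),
               "empty")
})

test_that("tornado: completeness, degenerate ranges, inert parameters", {
  tor <- one_way_sa(p, outcome = "blindness", life_table = lt)
  expect_equal(nrow(tor), length(amdscreen:::.ranged_names(p)))
  expect_true(all(tor$span >= 0))
  expect_true(all(diff(tor$span) <= 1e-12))
  # a zero-width range yields zero span
  expect_equal(tor$span[tor$name == "np_40"], 0)
  # the screening cost cannot move the blindness outcome
  expect_lt(tor$span[tor$name == "c_screen"], 1e-9)
  # utility weights cannot move the blindness outcome either
  expect_lt(max(tor$span[grepl("^u_", tor$name)]), 1e-9)
})

test_that("tornado entries are reproducible from perturb + engine alone", {
  tor <- one_way_sa(p, outcome = "icer", life_table = lt,
                    names = c("pm_50", "suppl_riskred"))
  for (i in seq_len(nrow(tor))) {
    plow <- perturb_parameter(p, tor$name[i], "low")
    pr <- amdscreen:::.run_pair(plow, lt)
    expect_equal(compare_strategies(pr$screened, pr$nonscreened,
                                    plow)$icer_jpy,
                 tor$low[i], tolerance = 1e-9)
  }
})

test_that("PSA: seeded reproducibility, set inclusion, degenerate draws", {
  a <- run_psa(p, n_draws = 10, seed = 5, life_table = lt)
  b <- run_psa(p, n_draws = 10, seed = 5, life_table = lt)
  expect_identical(a$draws, b$draws)
  expect_lte(a$frac_cost_effective, a$frac_positive_qaly)
  # all distributions degenerate at the base: the single draw must fall in
  # the base-case quadrant
  pdeg <- shrink_ranges(p, 0)
  one <- run_psa(pdeg, n_draws = 1, seed = 1, life_table = lt)
  pr <- amdscreen:::.run_pair(p, lt)
  base_dq <- pr$screened$qaly - pr$nonscreened$qaly
  expect_equal(one$frac_positive_qaly, as.numeric(base_dq > 0))
  expect_true(one$frac_cost_effective %in% c(0, 1))
})

test_that("PSA cloud mean tracks the base case as distributions shrink", {
  pr <- amdscreen:::.run_pair(p, lt)
  base_dc <- pr$screened$cost - pr$nonscreened$cost
  dist <- vapply(c(1, 0.4, 0), function(f) {
    psa <- run_psa(shrink_ranges(p, f), n_draws = 12, seed = 9,
                   life_table = lt)
    abs(mean(psa$draws$inc_cost) - base_dc)
  }, 1.0)
  expect_lt(dist[3], 1e-9)            # point mass reproduces the base case
  expect_lt(dist[2], dist[1] + 1e-9)  # shrinkage pulls the cloud inward
})

test_that("population projection is linear and exact for unit weights", {
  res <- run_cohort(screening_strategy(enabled = FALSE), p, lt)
  unit <- structure(data.frame(age = 40:89, weight = as.numeric(40:89 == 60)),
                    class = c("amd_population", "data.frame"))
  pj <- project_to_population(res, unit)
  i <- match(60, res$per_age$age)
  expect_equal(pj$amd, pj$per_age$amd_rate[i])
  uni <- structure(data.frame(age = 40:89, weight = rep(1, 50)),
                   class = c("amd_population", "data.frame"))
  pj1 <- project_to_population(res, uni)
  expect_equal(pj1$amd, sum(pj1$per_age$amd_rate))
  expect_equal(pj1$amd / 50, mean(pj1$per_age$amd_rate))
  dbl <- uni; dbl$weight <- dbl$weight * 2
  pj2 <- project_to_population(res, dbl)
  expect_equal(pj2$blind, 2 * pj1$blind)
  expect_equal(pj2$prodromal, 2 * pj1$prodromal)
})

test_that("scenario presets require an explicit bevacizumab price", {
  expect_error(scenario_parameters("bevacizumab"), "must be supplied")
  pb <- scenario_parameters("bevacizumab", bevacizumab_cost = 50000)
  expect_equal(pb$c_inj, 50000)
  expect_equal(pb$c_suppl_year, p$c_suppl_year)
  pbest <- scenario_parameters("best_case", bevacizumab_cost = 50000)
  expect_equal(pbest$obs_prodromal, 1)
  expect_equal(pbest$c_suppl_year, 0)
})
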