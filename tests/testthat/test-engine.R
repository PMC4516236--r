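lt <- test_life_table()
p <- amd_parameters()

test_that("degenerate cohort reproduces the discounted-annuity closed form", {
  p0 <- zero_transition_parameters()
  res <- run_cohort(screening_strategy(enabled = FALSE), p0,
                    immortal_life_table())
  expect_equal(res$qaly, sum(1.03^-(0:49)), tolerance = 1e-10)
  expect_equal(res$cost, 0)
  r0 <- zero_transition_parameters(discount = 0)
  res0 <- run_cohort(screening_strategy(enabled = FALSE), r0,
                     immortal_life_table())
  expect_equal(res0$qaly, 50)
  # the microsimulation agrees exactly in this deterministic limit
  ms <- run_microsim(screening_strategy(enabled = FALSE), p0,
                     immortal_life_table(), n = 50, seed = 1)
  expect_equal(ms$qaly, sum(1.03^-(0:49)), tolerance = 1e-10)
})

test_that("cohort-mode occupancy mass is conserved to machine precision", {
  for (st in list(screening_strategy(), screening_strategy(enabled = FALSE))) {
    res <- run_cohort(st, p, lt)
    expect_lt(res$mass_leak, 1e-12)
    # occupancy + cumulative deaths account for everyone at every age
    dead <- 1 - res$per_age$alive
    expect_equal(rowSums(res$occupancy) + dead, rep(1, 50),
                 tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce microsimulation results exactly", {
  a <- run_microsim(screening_strategy(), p, lt, n = 1000, seed = 42)
  b <- run_microsim(screening_strategy(), p, lt, n = 1000, seed = 42)
  expect_identical(a, b)
  c <- run_microsim(screening_strategy(), p, lt, n = 1000, seed = 43)
  expect_false(identical(a$cost, c$cost))
})

test_that("disabled screening equals zero-participation screening
           event-for-event under a shared seed", {
  p0 <- amd_parameters(list(p_participation = 0, p_occasional = 0))
  off <- run_microsim(screening_strategy(enabled = FALSE), p0, lt,
                      n = 3000, seed = 7)
  on <- run_microsim(screening_strategy(), p0, lt, n = 3000, seed = 7)
  skip_fields <- "strategy"
  expect_identical(off[setdiff(names(off), skip_fields)],
                   on[setdiff(names(on), skip_fields)])
  # and the cohort engine gives the same expectations
  coff <- run_cohort(screening_strategy(enabled = FALSE), p0, lt)
  con <- run_cohort(screening_strategy(), p0, lt)
  expect_equal(coff$cost, con$cost, tolerance = 1e-12)
  expect_equal(coff$qaly, con$qaly, tolerance = 1e-12)
})

test_that("microsimulation converges to the cohort expectation like 1/sqrt(n)", {
  co <- run_cohort(screening_strategy(), p, lt)
  for (n in c(1000, 10000)) {
    ms <- run_microsim(screening_strategy(), p, lt, n = n, seed = 17)
    z_cost <- (ms$cost - co$cost) / (ms$sd_cost / sqrt(n))
    z_qaly <- (ms$qaly - co$qaly) / (ms$sd_qaly / sqrt(n))
    expect_lt(abs(z_cost), 4)
    expect_lt(abs(z_qaly), 4)
  }
})

test_that("cumulative blindness is monotone in screening sensitivity", {
  blind_at <- function(overrides) {
    run_cohort(screening_strategy(), amd_parameters(overrides),
               lt)$tallies$person_blind
  }
  vals <- vapply(seq(0.6, 1.0, by = 0.1), function(s)
    blind_at(list(sens = s)), 1.0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("self-comparison and cost-only perturbations behave as expected", {
  a <- run_cohort(screening_strategy(), p, lt)
  self <- compare_strategies(a, a, p)
  expect_equal(self$inc_cost, 0)
  expect_equal(self$inc_qaly, 0)
  expect_equal(self$dominance, "undefined")
  # doubling the screening cost raises incremental cost, leaves QALY alone
  p2 <- amd_parameters(list(c_screen = 6000))
  pr <- amdscreen:::.run_pair(p, lt)
  pr2 <- amdscreen:::.run_pair(p2, lt)
  ce <- compare_strategies(pr$screened, pr$nonscreened, p)
  ce2 <- compare_strategies(pr2$screened, pr2$nonscreened, p2)
  expect_gt(ce2$inc_cost, ce$inc_cost)
  expect_equal(ce2$inc_qaly, ce$inc_qaly, tolerance = 1e-12)
  # provenance check
  expect_error(compare_strategies(pr$screened, pr2$nonscreened, p),
               "different parameter")
})

test_that("ledger categories sum to the total cost (no leakage)", {
  for (res in list(run_cohort(screening_strategy(), p, lt),
                   run_microsim(screening_strategy(), p, lt,
                                n = 5000, seed = 3))) {
    expect_equal(sum(res$cost_by_category), res$cost, tolerance = 1e-9)
    expect_true(all(res$cost_by_category >= 0))
    expect_true(all(res$cost_by_category <= res$cost_by_category_undisc +
                      1e-9))
  }
})
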