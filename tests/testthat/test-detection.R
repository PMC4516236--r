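p <- amd_parameters()

test_that("screening schedule arithmetic", {
  base <- screening_strategy()
  expect_true(screening_due(50, base))
  expect_false(screening_due(52, base))
  expect_true(screening_due(90, base))
  s <- screening_strategy(TRUE, 50, 60, 6)
  expect_equal((50:90)[screening_due(50:90, s)], c(50, 56))
  off <- screening_strategy(enabled = FALSE)
  expect_false(any(screening_due(40:90, off)))
  expect_error(screening_strategy(start = 35), ">= 40")
  expect_error(screening_strategy(interval = 0), ">= 1")
})

test_that("screening event tree: forced branches and costs", {
  moderate <- person_state(stages = c(1, 3), type = AMD_TYPES[["TAMD"]])
  p1 <- amd_parameters(list(p_participation = 1, sens = 1, p_detailed = 1))
  out <- screening_event(moderate, p1)
  expect_true(out$detected)
  expect_equal(out$pathway, "screening")
  expect_equal(out$cost, 3000 + 13900)
  expect_true(out$person$detected)
  expect_equal(out$person$ty[2], 1L)   # AMD eye opens a year-1 line
  p0 <- amd_parameters(list(p_participation = 0, p_occasional = 0))
  out0 <- screening_event(moderate, p0)
  expect_false(out0$detected)
  expect_equal(out0$pathway, "none")
  expect_equal(out0$cost, 0)
})

test_that("expected screening cost of a disease-free participant matches
           the outcome-tree expectation", {
  healthy <- person_state()
  pall <- amd_parameters(list(p_participation = 1))
  set.seed(6)
  n <- 2e5
  costs <- vapply(seq_len(n), function(i) screening_event(healthy, pall)$cost,
                  1.0)
  expected <- 3000 + (1 - 0.95) * 0.80 * 13900   # false positives attend
  expect_equal(mean(costs), expected,
               tolerance = 3 * sd(costs) / sqrt(n) / expected)
  # a disease-free person is never detected
  expect_equal(sum(vapply(seq_len(2000), function(i)
    screening_event(healthy, pall)$detected, TRUE)), 0)
})

test_that("coincidental consultation happens only in the onset year", {
  moderate <- person_state(stages = c(2, 3), type = AMD_TYPES[["PCV"]])
  p0 <- amd_parameters(list(presby_incidence = 0))
  expect_false(any(vapply(1:200, function(i)
    coincidental_consultation(moderate, p0)$detected, TRUE)))
  p1 <- amd_parameters(list(presby_incidence = 1, presby_visit = 1))
  out <- coincidental_consultation(moderate, p1)
  expect_true(out$detected)
  expect_equal(out$pathway, "coincidental")
  expect_equal(out$cost, 13900)
  # established presbyopia: the pathway is closed
  est <- person_state(stages = c(2, 3), type = AMD_TYPES[["PCV"]],
                      presbyopia = TRUE)
  expect_false(coincidental_consultation(est, p1)$detected)
  set.seed(7)
  hits <- sum(vapply(seq_len(2e5), function(i)
    coincidental_consultation(moderate, p)$detected, TRUE))
  expect_freq(hits, 2e5, 0.03 * 0.20)
})

test_that("symptom consultation: certain on new blindness, sensor otherwise", {
  nb <- person_state(stages = c(1, 5), type = AMD_TYPES[["TAMD"]],
                     newly_blind = TRUE)
  expect_true(symptom_consultation(nb, p)$detected)
  sev <- person_state(stages = c(1, 4), type = AMD_TYPES[["TAMD"]])
  p0 <- amd_parameters(list(sensor_ms = 0))
  expect_false(any(vapply(1:200, function(i)
    symptom_consultation(sev, p0)$detected, TRUE)))
  set.seed(8)
  hits <- sum(vapply(seq_len(1e5), function(i)
    symptom_consultation(sev, p)$detected, TRUE))
  expect_freq(hits, 1e5, 0.05)
  # prodromal-only persons never trigger the sensor
  prod <- person_state(stages = c(1, 2))
  expect_false(any(vapply(1:200, function(i)
    symptom_consultation(prod, p)$detected, TRUE)))
  # established (not new) blindness alone does not trigger it either
  est <- person_state(stages = c(1, 5), type = AMD_TYPES[["TAMD"]])
  expect_false(any(vapply(1:200, function(i)
    symptom_consultation(est, p)$detected, TRUE)))
})

test_that("cumulative detection is monotone in screening sensitivity", {
  lt <- test_life_table()
  detected_fraction <- function(params) {
    res <- run_cohort(screening_strategy(), params, lt)
    with(res$tallies, det_screen + det_occasional + det_symptom +
           det_coincidental)
  }
  vals <- vapply(c(0.6, 0.8, 1.0), function(s)
    detected_fraction(amd_parameters(list(sens = s))), 1.0)
  expect_true(all(diff(vals) >= -1e-12))
})
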