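p <- amd_parameters()

test_that("injection schedule is 6/4/2 with a closed-form cumulative count", {
  expect_equal(annual_injection_count(1, p), 6)
  expect_equal(annual_injection_count(2, p), 4)
  expect_equal(annual_injection_count(7, p), 2)
  expect_error(annual_injection_count(0, p), ">= 1")
  for (k in 2:10)
    expect_equal(sum(annual_injection_count(1:k, p)), 6 + 4 + 2 * (k - 2))
})

test_that("treatment plans follow stage, subtype and treatment year", {
  sev_pcv <- person_state(stages = c(1, 4), type = AMD_TYPES[["PCV"]],
                          detected = TRUE, ty = c(0, 1))
  plan <- make_plan(sev_pcv, p)
  expect_equal(plan$injections, 6)
  expect_equal(plan$pdt_sessions, 1)
  expect_equal(plan$modality[2], "injections+PDT")
  expect_equal(plan$observations, 12)
  sev_tamd <- person_state(stages = c(1, 4), type = AMD_TYPES[["TAMD"]],
                           detected = TRUE, ty = c(0, 1))
  expect_equal(make_plan(sev_tamd, p)$pdt_sessions, 0)
  # PDT only in treatment year 1
  sev_y2 <- person_state(stages = c(1, 4), type = AMD_TYPES[["PCV"]],
                         detected = TRUE, ty = c(0, 2))
  expect_equal(make_plan(sev_y2, p)$pdt_sessions, 0)
  expect_equal(make_plan(sev_y2, p)$injections, 4)
  blind <- person_state(stages = c(5, 5), type = AMD_TYPES[["TAMD"]],
                        detected = TRUE)
  pb <- make_plan(blind, p)
  expect_equal(pb$injections, 0)
  expect_equal(pb$observations, 12)
  expect_equal(pb$modality, c("observation", "observation"))
  undet <- person_state(stages = c(1, 2))
  expect_error(make_plan(undet, p), "detected")
})

test_that("treated transitions reproduce the published effect rates", {
  M <- EYE_STAGES[["MODERATE"]]; S <- EYE_STAGES[["SEVERE"]]
  set.seed(9)
  y1 <- vapply(seq_len(1e5), function(i) treated_transition(S, 1, p), 1L)
  expect_freq(sum(y1 == M), 1e5, 0.403)
  expect_freq(sum(y1 == EYE_STAGES[["BLIND"]]), 1e5, 0.05)
  y3 <- vapply(seq_len(1e5), function(i) treated_transition(M, 3, p), 1L)
  expect_freq(sum(y3 == S), 1e5, 0.22)
  # identity dynamics when every effect is "maintain"
  pm <- amd_parameters(list(eff_mod_worsen_y1 = 0, eff_mod_worsen_later = 0,
                            eff_sev_improve_y1 = 0, eff_sev_maintain_y1 = 1,
                            eff_sev_blind = 0))
  expect_true(all(vapply(1:100, function(i)
    treated_transition(M, 1, pm), 1L) == M))
  expect_true(all(vapply(1:100, function(i)
    treated_transition(S, 5, pm), 1L) == S))
  expect_error(treated_transition(M, 0, p), ">= 1")
})

test_that("improvement only happens from severe AMD in treatment year 1", {
  set.seed(10)
  for (stage in c(EYE_STAGES[["MODERATE"]], EYE_STAGES[["SEVERE"]]))
    for (year in 1:3) {
      out <- vapply(1:2000, function(i) treated_transition(stage, year, p), 1L)
      if (stage == EYE_STAGES[["SEVERE"]] && year == 1)
        expect_true(any(out < stage))
      else expect_true(all(out >= stage))
    }
})

test_that("supplement uptake, continuation and expected duration", {
  prod <- person_state(stages = c(1, 2), detected = TRUE)
  p0 <- amd_parameters(list(suppl_intake = 0))
  expect_true(all(vapply(1:100, function(i)
    supplement_update(prod, p0)$person$suppl, "") == "stopped"))
  p1 <- amd_parameters(list(suppl_intake = 1, suppl_continuation = 1))
  taker <- supplement_update(prod, p1)$person
  expect_equal(taker$suppl, "taking")
  expect_equal(supplement_update(taker, p1)$cost, 51360)
  expect_equal(supplement_update(taker, p1)$person$suppl, "taking")
  # expected years of intake for a persistently eligible taker: 1/(1-0.9)
  set.seed(11)
  n <- 20000
  years <- 1 + rgeom(n, 1 - p$suppl_continuation)
  expect_equal(mean(years), 10, tolerance = 3 * sd(years) / sqrt(n) / 10)
  # the operation's attrition matches that geometric law
  one_run <- function() {
    person <- taker; k <- 1L
    repeat {
      person <- supplement_update(person, p)$person
      if (person$suppl != "taking") break
      k <- k + 1L
    }
    k
  }
  sim <- vapply(seq_len(5000), function(i) one_run(), 1L)
  expect_equal(mean(sim), 10, tolerance = 3 * sd(sim) / sqrt(5000) / 10)
  # eligibility ends once no eye is prodromal
  bilat <- person_state(stages = c(3, 3), type = AMD_TYPES[["TAMD"]],
                        detected = TRUE, ty = c(1, 1), suppl = "taking")
  expect_equal(supplement_update(bilat, p1)$person$suppl, "stopped")
})

test_that("endophthalmitis counts follow the per-injection risk", {
  expect_equal(endophthalmitis_events(0, p), 0)
  p1 <- amd_parameters(list(endo_per_inj = 1))
  expect_equal(endophthalmitis_events(6, p1), 6)
  set.seed(12)
  expect_freq(endophthalmitis_events(1e7, p), 1e7, 3e-4)
})

test_that("dropout spares the blind and matches the published rates", {
  blind <- person_state(stages = c(3, 5), type = AMD_TYPES[["TAMD"]],
                        detected = TRUE, dty = 2, ty = c(2, 0))
  expect_true(all(vapply(1:200, function(i)
    dropout_update(blind, p)$detected, TRUE)))
  p0 <- amd_parameters(list(dropout_prodromal_y1 = 0,
                            dropout_prodromal_later = 0, dropout_ms = 0))
  prod <- person_state(stages = c(1, 2), detected = TRUE, dty = 1)
  expect_true(all(vapply(1:200, function(i)
    dropout_update(prod, p0)$detected, TRUE)))
  set.seed(13)
  gone <- sum(!vapply(seq_len(1e5), function(i)
    dropout_update(prod, p)$detected, TRUE))
  expect_freq(gone, 1e5, 0.50)
  later <- person_state(stages = c(1, 2), detected = TRUE, dty = 2)
  gone2 <- sum(!vapply(seq_len(1e5), function(i)
    dropout_update(later, p)$detected, TRUE))
  expect_freq(gone2, 1e5, 0.10)
  # no withdrawal in the detection cycle itself
  fresh <- person_state(stages = c(1, 2), detected = TRUE, dty = 0)
  expect_true(all(vapply(1:200, function(i)
    dropout_update(fresh, p)$detected, TRUE)))
})
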