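# Individual-level microsimulation: every person starts at age 40 with two
# normal eyes, undetected, and is followed for 50 annual cycles or until
# death.  All random draws come from fixed per-cycle channels so that two
# strategies with identical event probabilities consume identical
# randomness (common random numbers; strategy-null equivalence is exact).

#' Run the individual-level microsimulation
#'
#' Simulates `n` persons from age 40 to 90 under a screening strategy,
#' applying the per-cycle event order documented in the package vignette:
#' mortality, simultaneous two-eye transitions (with second-eye
#' acceleration and subtype assignment at first onset), symptom/screening/
#' coincidental detection, supplement and dropout updates, treatment
#' delivery and discounted ledger accrual.
#'
#' @param strategy An `amd_strategy` (see [screening_strategy()]).
#' @param params An `amd_params` object.
#' @param life_table An `amd_life_table` covering ages 40-90.
#' @param n Number of simulated persons (>= 1).
#' @param seed Integer seed; identical seeds reproduce results exactly.
#' @return An object of class `amd_cohort`; all monetary/QALY quantities
#'   are per-person means and all event tallies per-person rates, so
#'   microsimulation and cohort-mode results are directly comparable.
#' @seealso [run_cohort()] for the deterministic expectation companion.
#' @export
run_microsim <- function(strategy, params, life_table = synth_life_table(),
                         n = 50000, seed = 1) {
  stopifnot(inherits(strategy, "amd_strategy"), n >= 1)
  validate_parameters(params, strict_utility_order = FALSE)
  set.seed(seed)
  n <- as.integer(n)
  umat <- utility_matrix(params)
  sp <- .subtype_probs(params)
  r <- params$discount

  s1 <- rep(1L, n); s2 <- rep(1L, n)
  ty1 <- integer(n); ty2 <- integer(n)
  type <- integer(n)
  det <- logical(n); dty <- integer(n)
  suppl <- integer(n)             # 0 never, 1 taking, 2 stopped
  presby <- logical(n)
  alive <- rep(TRUE, n)

  cost_i <- numeric(n); qaly_i <- numeric(n)
  cat_disc <- stats::setNames(numeric(7), .cost_categories)
  cat_undisc <- cat_disc
  tal <- list(amd_onset = 0, second_onset = 0, person_blind = 0,
              det_screen = 0, det_occasional = 0, det_symptom = 0,
              det_coincidental = 0, injections = 0, pdt_sessions = 0,
              endophthalmitis = 0, dropouts = 0)
  nc <- .cycles
  per_age <- data.frame(age = 40:89, alive = numeric(nc), amd = numeric(nc),
                        onset_flow = numeric(nc), blind_flow = numeric(nc))
  occupancy <- matrix(0, nc, 15)

  add_cost <- function(idx_amount, category, disc) {
    # idx_amount: numeric vector over persons (0 where nothing accrued)
    cost_i <<- cost_i + idx_amount * disc
    cat_disc[category] <<- cat_disc[category] + sum(idx_amount) * disc
    cat_undisc[category] <<- cat_undisc[category] + sum(idx_amount)
  }

  for (t in 0:(nc - 1L)) {
    age <- 40L + t
    disc <- (1 + r)^(-t)
    q <- .qx_at(life_table, age)

    u_death <- stats::runif(n); u_e1 <- stats::runif(n)
    u_e2 <- stats::runif(n); u_type <- stats::runif(n)
    u_consult <- stats::runif(n); u_part <- stats::runif(n)
    u_occ <- stats::runif(n); u_test <- stats::runif(n)
    u_attend <- stats::runif(n); u_pre_on <- stats::runif(n)
    u_pre_vis <- stats::runif(n); u_cont <- stats::runif(n)
    u_intake <- stats::runif(n); u_drop <- stats::runif(n)

    ## 1. mortality
    alive <- alive & (u_death >= q)

    ## 2. simultaneous eye transitions
    old1 <- s1; old2 <- s2
    taking <- suppl == 1L
    o1 <- .eye_outcome_probs(old1, old2, ty1, det, taking, age, params)
    o2 <- .eye_outcome_probs(old2, old1, ty2, det, taking, age, params)
    imp1 <- u_e1 < o1$imp; wor1 <- u_e1 > 1 - o1$wor
    imp2 <- u_e2 < o2$imp; wor2 <- u_e2 > 1 - o2$wor
    new1 <- old1 + as.integer(alive & wor1) - as.integer(alive & imp1)
    new2 <- old2 + as.integer(alive & wor2) - as.integer(alive & imp2)
    ty1 <- .next_ty(new1, old1, ty1, det)
    ty2 <- .next_ty(new2, old2, ty2, det)
    conv1 <- old1 == 2L & new1 == 3L
    conv2 <- old2 == 2L & new2 == 3L
    had_amd <- old1 >= 3L | old2 >= 3L
    assign <- alive & type == 0L & (conv1 | conv2)
    type[assign] <- 1L + (u_type[assign] >= sp[1]) +
      (u_type[assign] >= sp[1] + sp[2])
    second <- alive & ((had_amd & (conv1 | conv2)) | (!had_amd & conv1 & conv2))
    newly_blind <- alive & ((new1 == 5L & old1 < 5L) | (new2 == 5L & old2 < 5L))
    pblind <- alive & new1 == 5L & new2 == 5L & !(old1 == 5L & old2 == 5L)
    s1 <- new1; s2 <- new2
    tal$amd_onset <- tal$amd_onset + sum(assign)
    tal$second_onset <- tal$second_onset + sum(second)
    tal$person_blind <- tal$person_blind + sum(pblind)
    per_age$onset_flow[t + 1L] <- sum(assign)
    per_age$blind_flow[t + 1L] <- sum(pblind)

    mark_detected <- function(hit) {
      det[hit] <<- TRUE
      dty[hit] <<- 0L
      ty1[hit & s1 %in% c(3L, 4L)] <<- 1L
      ty2[hit & s2 %in% c(3L, 4L)] <<- 1L
    }
    any_ms <- s1 %in% c(3L, 4L) | s2 %in% c(3L, 4L)
    diseased <- s1 >= 2L | s2 >= 2L

    ## 3. symptom consultation
    p_cons <- ifelse(newly_blind, params$consult_blind,
                     ifelse(any_ms, params$sensor_ms, 0))
    hit <- alive & !det & u_consult < p_cons
    mark_detected(hit)
    add_cost(hit * params$c_exam, "exam", disc)
    tal$det_symptom <- tal$det_symptom + sum(hit)

    ## 4. screening (organized + occasional) in screening years
    if (screening_due(age, strategy)) {
      elig <- alive & !det
      part <- elig & u_part < params$p_participation
      occ <- elig & !part & u_occ < params$p_occasional
      scr <- part | occ
      add_cost(scr * params$c_screen, "screening", disc)
      p_pos <- ifelse(diseased, params$sens, 1 - params$spec)
      pos <- scr & u_test < p_pos
      att <- pos & u_attend < params$p_detailed
      add_cost(att * params$c_exam, "exam", disc)
      hit <- att & diseased
      mark_detected(hit)
      tal$det_screen <- tal$det_screen + sum(hit & part)
      tal$det_occasional <- tal$det_occasional + sum(hit & occ)
    }

    ## 5. coincidental consultation (presbyopia onset year)
    onset <- alive & !det & !presby & u_pre_on < params$presby_incidence
    presby <- presby | onset
    hit <- onset & u_pre_vis < params$presby_visit & diseased
    mark_detected(hit)
    add_cost(hit * params$c_exam, "exam", disc)
    tal$det_coincidental <- tal$det_coincidental + sum(hit)

    ## 6. supplements and dropout
    d <- alive & det
    elig_s <- s1 == 2L | s2 == 2L
    stop_taking <- d & suppl == 1L &
      (!elig_s | u_cont >= params$suppl_continuation)
    suppl[stop_taking] <- 2L
    offer <- d & suppl == 0L & elig_s
    start <- offer & u_intake < params$suppl_intake
    suppl[start] <- 1L
    suppl[offer & !start] <- 2L
    any_blind <- s1 == 5L | s2 == 5L
    rate <- ifelse(any_blind, params$dropout_blind,
                   ifelse(any_ms, params$dropout_ms,
                          ifelse(dty == 1L, params$dropout_prodromal_y1,
                                 params$dropout_prodromal_later)))
    drop <- d & dty >= 1L & u_drop < rate
    det[drop] <- FALSE; dty[drop] <- 0L
    ty1[drop] <- 0L; ty2[drop] <- 0L
    suppl[drop & suppl == 1L] <- 2L
    tal$dropouts <- tal$dropouts + sum(drop)

    ## 7. treatment delivery
    d <- alive & det
    any_ms <- s1 %in% c(3L, 4L) | s2 %in% c(3L, 4L)
    any_blind <- s1 == 5L | s2 == 5L
    any_prod <- s1 == 2L | s2 == 2L
    obs <- d * .obs_per_year(any_ms, any_blind, any_prod, params)
    add_cost(obs * params$c_obs, "observation", disc)
    inj <- d * ((s1 %in% c(3L, 4L)) *
                  annual_injection_count(pmax(ty1, 1L), params) +
                (s2 %in% c(3L, 4L)) *
                  annual_injection_count(pmax(ty2, 1L), params))
    add_cost(inj * params$c_inj, "injections", disc)
    pdt_type <- type %in% c(2L, 3L)
    pdt_eyes <- d * ((s1 == 4L & pdt_type & ty1 == 1L) +
                     (s2 == 4L & pdt_type & ty2 == 1L))
    pdt_cost <- ifelse(pdt_eyes >= 2L, params$pdt_y1 * params$c_pdt_both,
                       ifelse(pdt_eyes == 1L, params$pdt_y1 * params$c_pdt_one,
                              0))
    add_cost(pdt_cost, "pdt", disc)
    endo <- stats::rbinom(n, inj, params$endo_per_inj)
    add_cost(endo * params$c_endo, "endophthalmitis", disc)
    add_cost((d & suppl == 1L) * params$c_suppl_year, "supplements", disc)
    tal$injections <- tal$injections + sum(inj)
    tal$pdt_sessions <- tal$pdt_sessions + params$pdt_y1 * sum(pdt_eyes)
    tal$endophthalmitis <- tal$endophthalmitis + sum(endo)

    ## 8. utility accrual and bookkeeping
    u <- umat[cbind(pmin(s1, s2), pmax(s1, s2))]
    qaly_i <- qaly_i + ifelse(alive, u, 0) * disc
    per_age$alive[t + 1L] <- sum(alive)
    per_age$amd[t + 1L] <- sum(alive & (s1 >= 3L | s2 >= 3L))
    pair <- .pair_category(s1, s2)
    occupancy[t + 1L, ] <- tabulate(pair[alive], nbins = 15)
    dty[alive & det] <- pmin(dty[alive & det] + 1L, 2L)
  }

  .new_cohort_result(
    mode = "microsim", n = n, strategy = strategy, params = params,
    cost = mean(cost_i), qaly = mean(qaly_i),
    sd_cost = stats::sd(cost_i), sd_qaly = stats::sd(qaly_i),
    cost_by_category = cat_disc / n, cost_by_category_undisc = cat_undisc / n,
    tallies = lapply(tal, function(z) z / n),
    per_age = within(per_age, {
      alive <- alive / n; amd <- amd / n
      onset_flow <- onset_flow / n; blind_flow <- blind_flow / n
    }),
    occupancy = occupancy / n,
    pt_prevalence = sum(per_age$amd) / sum(per_age$alive),
    sd_blind = sqrt(max(tal$person_blind / n * (1 - tal$person_blind / n), 0) / n))
}

# 15 unordered stage-pair categories, row-major over (better, worse)
.pair_category <- function(s1, s2) {
  b <- pmin(s1, s2); w <- pmax(s1, s2)
  # index into upper triangle: offsets 0,5,9,12,14 for b=1..5
  c(0L, 5L, 9L, 12L, 14L)[b] + (w - b + 1L)
}

.pair_category_names <- function() {
  nm <- character(15)
  k <- 0
  ab <- c("N", "P", "M", "S", "B")
  for (b in 1:5) for (w in b:5) {
    k <- k + 1
    nm[k] <- paste0(ab[b], "/", ab[w])
  }
  nm
}

.new_cohort_result <- function(mode, n, strategy, params, cost, qaly,
                               cost_by_category, cost_by_category_undisc,
                               tallies, per_age, occupancy, pt_prevalence,
                               sd_cost = NA_real_, sd_qaly = NA_real_,
                               sd_blind = NA_real_) {
  colnames(occupancy) <- .pair_category_names()
  structure(list(mode = mode, n = n, strategy = strategy,
                 param_values = unlist(params),
                 cost = cost, qaly = qaly,
                 sd_cost = sd_cost, sd_qaly = sd_qaly, sd_blind = sd_blind,
                 cost_by_category = cost_by_category,
                 cost_by_category_undisc = cost_by_category_undisc,
                 tallies = tallies, per_age = per_age,
                 occupancy = occupancy, pt_prevalence = pt_prevalence),
            class = "amd_cohort")
}

#' @export
print.amd_cohort <- function(x, ...) {
  cat("Two-eye AMD model run (", x$mode,
      if (x$mode == "microsim") paste0(", n = ", x$n) else "", ")\n", sep = "")
  print(x$strategy)
  cat(sprintf("  mean discounted cost: %.0f JPY\n", x$cost))
  cat(sprintf("  mean discounted QALY: %.4f\n", x$qaly))
  cat(sprintf("  cumulative AMD onset: %.4f per person\n", x$tallies$amd_onset))
  cat(sprintf("  cumulative bilateral blindness: %.6f per person\n",
              x$tallies$person_blind))
  invisible(x)
}

#' @export
summary.amd_cohort <- function(object, ...) {
  cat_summary <- rbind(discounted = object$cost_by_category,
                       undiscounted = object$cost_by_category_undisc)
  out <- list(mode = object$mode, n = object$n, cost = object$cost,
              qaly = object$qaly, cost_by_category = cat_summary,
              tallies = unlist(object$tallies),
              pt_prevalence = object$pt_prevalence)
  class(out) <- "summary.amd_cohort"
  out
}

#' @export
print.summary.amd_cohort <- function(x, ...) {
  cat("Mode:", x$mode, if (x$mode == "microsim") paste0("(n = ", x$n, ")"),
      "\n")
  cat(sprintf("Mean discounted cost %0.f JPY, QALY %.4f\n", x$cost, x$qaly))
  cat("Cost by category (JPY per person):\n")
  print(round(x$cost_by_category, 1))
  cat("Event tallies (per person):\n")
  print(round(x$tallies, 6))
  cat(sprintf("Person-time AMD prevalence: %.4f%%\n", 100 * x$pt_prevalence))
  invisible(x)
}
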