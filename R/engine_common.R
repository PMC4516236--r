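# Rules shared verbatim by the microsimulation and the deterministic cohort
# engine, so the two modes cannot drift apart: per-eye annual outcome
# probabilities and the treatment-year bookkeeping.
#
# Per-cycle event order (annual cycle, ages 40..89, 50 cycles):
#   1. background mortality (decedents accrue nothing that cycle)
#   2. simultaneous per-eye stage transitions (treated rules if under
#      medical control, untreated otherwise; second-eye acceleration via
#      the fellow eye's start-of-cycle stage), subtype assignment at first
#      AMD onset, treatment-year counter update
#   3. symptom consultation (certain on new blindness; sensor rate for
#      moderate/severe) for undetected persons
#   4. organized + occasional screening, in screening years
#   5. coincidental consultation via presbyopia onset
#   6. supplement continuation/offer and dropout (from first anniversary)
#   7. treatment delivery and costing (observations, injections, PDT,
#      endophthalmitis, supplements)
#   8. utility accrual, discounted at (1+r)^(-t)
# Detection during a cycle (events 3-5) takes effect for treatment delivery
# the same cycle and for transition rules from the next cycle.

# probability of improving / worsening one stage for each eye, vectorized
# over persons/states; `taking` is person-level supplement intake
.eye_outcome_probs <- function(s, fellow, ty, det, taking, age, params) {
  n <- length(s)
  pImp <- numeric(n)
  pWor <- numeric(n)
  i <- s == 1L
  if (any(i)) pWor[i] <- onset_prodromal_prob(age, params)
  i <- s == 2L
  if (any(i)) pWor[i] <- prodromal_to_amd_prob(age, fellow[i] >= 3L,
                                               taking[i], params)
  pWor[s == 3L & !det] <- params$ms_untreated
  pWor[s == 3L & det & ty == 1L] <- params$eff_mod_worsen_y1
  pWor[s == 3L & det & ty >= 2L] <- params$eff_mod_worsen_later
  pWor[s == 4L & !det] <- params$sb_untreated
  sev <- c(params$eff_sev_improve_y1, params$eff_sev_maintain_y1,
           params$eff_sev_blind)
  sev <- sev / sum(sev)
  i <- s == 4L & det & ty == 1L
  pImp[i] <- sev[1]
  pWor[i] <- sev[3]
  pWor[s == 4L & det & ty >= 2L] <- params$eff_sev_blind
  list(imp = pImp, wor = pWor)
}

# treatment-year counter after a transition: reset to 1 on any stage
# change into moderate/severe, advance (cap 3 = "year 3+") when staying,
# 0 outside active treatment
.next_ty <- function(new_s, old_s, ty, det) {
  out <- integer(length(new_s))
  active <- det & new_s %in% c(3L, 4L)
  out[active & new_s != old_s] <- 1L
  adv <- active & new_s == old_s
  out[adv] <- pmin(ty[adv] + 1L, 3L)
  out
}

# observation visits per year for a detected person, by worst need present
.obs_per_year <- function(any_ms, any_blind, any_prodromal, params) {
  ifelse(any_ms, params$obs_amd,
         ifelse(any_blind, params$obs_blind,
                ifelse(any_prodromal, params$obs_prodromal, 0)))
}

# age-band index for the transition-probability variants (normal->prodromal
# bands x the age-50 prodromal->moderate switch)
.age_band <- function(age) {
  findInterval(age, c(40, 45, 50, 55, 65, 75, 91))
}
.band_ages <- c(40, 45, 50, 55, 65, 75)  # representative age per band

.cycles <- 50L
.cost_categories <- c("screening", "exam", "observation", "supplements",
                      "injections", "pdt", "endophthalmitis")
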