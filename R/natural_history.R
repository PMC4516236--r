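# Per-eye disease stages and untreated (undetected) annual transition rules.
#
# Stages are an ordinal scale per eye; death is person-level and handled by
# the engine.  Stage codes are integers 1..5 with printable names.

#' Eye stage codes
#'
#' Integer codes for the per-eye disease scale: `NORMAL = 1`,
#' `PRODROMAL = 2`, `MODERATE = 3` (moderate AMD, VA 0.5-0.9),
#' `SEVERE = 4` (severe AMD, VA 0.1-0.4), `BLIND = 5` (VA < 0.1).
#' @format Named integer vector of length 5.
#' @export
EYE_STAGES <- c(NORMAL = 1L, PRODROMAL = 2L, MODERATE = 3L,
                SEVERE = 4L, BLIND = 5L)

#' AMD subtype codes
#'
#' `NONE = 0` (no eye has reached moderate AMD), `TAMD = 1` (typical
#' neovascular AMD), `PCV = 2` (polypoidal choroidal vasculopathy),
#' `RAP = 3` (retinal angiomatous proliferation).  The subtype is assigned
#' once, when the first eye develops AMD, and the second eye shares it.
#' @format Named integer vector of length 4.
#' @export
AMD_TYPES <- c(NONE = 0L, TAMD = 1L, PCV = 2L, RAP = 3L)

#' Annual probability of prodromal onset in a normal eye
#'
#' Piecewise-constant in age: 0 for ages 40-44, then the age-band values of
#' the parameter set (45-54, 55-64, 65-74, 75+).
#'
#' @param age Age(s) in years, within 40-90.
#' @param params An `amd_params` object.
#' @return Annual transition probability, vectorized over `age`.
#' @export
onset_prodromal_prob <- function(age, params) {
  if (any(age < 40 | age > 90)) stop("age out of model range [40, 90]")
  cuts <- c(40, 45, 55, 65, 75, 91)
  v <- c(params$np_40, params$np_45, params$np_55, params$np_65, params$np_75)
  v[findInterval(age, cuts)]
}

#' Annual probability a prodromal eye develops moderate AMD
#'
#' The fellow eye drives the rate: once the fellow eye has AMD (moderate or
#' worse), the second-eye probability applies regardless of age; otherwise
#' the first-eye age-band value (0 below age 50) applies.  While the person
#' is taking supplements the probability is multiplied by one minus the
#' supplement risk reduction.
#'
#' @param age Age(s) in years.
#' @param fellow_has_amd Logical; fellow eye at moderate AMD or worse.
#' @param taking_supplements Logical.
#' @param params An `amd_params` object.
#' @return Annual transition probability (vectorized).
#' @export
prodromal_to_amd_prob <- function(age, fellow_has_amd, taking_supplements,
                                  params) {
  if (any(age < 40 | age > 90)) stop("age out of model range [40, 90]")
  base <- ifelse(fellow_has_amd, params$pm_second,
                 ifelse(age < 50, params$pm_40, params$pm_50))
  base * ifelse(taking_supplements, 1 - params$suppl_riskred, 1)
}

# renormalized subtype probability vector (tAMD, PCV, RAP)
.subtype_probs <- function(params) {
  p <- c(params$type_tamd, params$type_pcv, params$type_rap)
  p / sum(p)
}

#' Draw the AMD subtype at first-eye onset
#'
#' Draws tAMD / PCV / RAP with the (renormalized) subtype probabilities.
#' Must only be called when no subtype has been assigned yet; the second
#' eye always shares the first eye's subtype.
#'
#' @param params An `amd_params` object.
#' @param current_type Current subtype code; must be `AMD_TYPES["NONE"]`.
#' @return A subtype code (1 = tAMD, 2 = PCV, 3 = RAP).
#' @export
assign_amd_type <- function(params, current_type = AMD_TYPES[["NONE"]]) {
  if (current_type != AMD_TYPES[["NONE"]])
    stop("AMD subtype already assigned; the second eye shares it")
  sample.int(3L, 1L, prob = .subtype_probs(params))
}

# stay/worsen probability of an untreated moderate or severe eye
.untreated_worsen_prob <- function(stage, params) {
  ifelse(stage == EYE_STAGES[["MODERATE"]], params$ms_untreated,
         ifelse(stage == EYE_STAGES[["SEVERE"]], params$sb_untreated, 0))
}

#' One untreated annual transition of a moderate or severe eye
#'
#' Moderate AMD worsens to severe with the untreated annual probability,
#' severe worsens to blindness likewise; blindness is absorbing and no
#' spontaneous improvement occurs.  Prodromal onset and conversion are
#' handled by [onset_prodromal_prob()] and [prodromal_to_amd_prob()].
#'
#' @param stage Eye stage code (see [EYE_STAGES]).
#' @param params An `amd_params` object.
#' @return The next stage code (random).
#' @export
untreated_transition <- function(stage, params) {
  w <- .untreated_worsen_prob(stage, params)
  if (stats::runif(1) < w) stage + 1L else stage
}
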