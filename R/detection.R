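# Detection pathways: organized/occasional screening, coincidental
# consultation (presbyopia), and symptom-driven consultation.
#
# These scalar per-person operations define the event semantics; the
# engines apply the same rules vectorized (microsimulation) or as exact
# branch probabilities (cohort mode).

#' Screening strategy
#'
#' Organized screening occurs at ages `start, start + interval, ...` not
#' exceeding `end`.  The base case screens every 5 years from age 50 to 90.
#'
#' @param enabled Logical on/off flag.
#' @param start First screening age (>= 40).
#' @param end Last eligible age (<= 90).
#' @param interval Years between screenings (>= 1).
#' @return An object of class `amd_strategy`.
#' @examples
#' base_strategy <- screening_strategy()
#' no_screening <- screening_strategy(enabled = FALSE)
#' @export
screening_strategy <- function(enabled = TRUE, start = 50, end = 90,
                               interval = 5) {
  if (start < 40) stop("screening start age must be >= 40")
  if (end > 90) stop("screening end age must be <= 90")
  if (interval < 1) stop("screening interval must be >= 1")
  structure(list(enabled = isTRUE(enabled), start = start, end = end,
                 interval = interval),
            class = "amd_strategy")
}

#' @export
print.amd_strategy <- function(x, ...) {
  if (!x$enabled) cat("Screening strategy: no screening\n")
  else cat(sprintf(
    "Screening strategy: every %d year(s) from age %d to %d (screens at %s)\n",
    x$interval, x$start, x$end,
    paste(seq(x$start, x$end, by = x$interval), collapse = ", ")))
  invisible(x)
}

#' Is organized screening due at an age?
#'
#' @param age Age(s) in years; vectorized.
#' @param strategy An `amd_strategy`.
#' @return Logical: screening occurs at this age.
#' @export
screening_due <- function(age, strategy) {
  if (!strategy$enabled) return(rep(FALSE, length(age)))
  age >= strategy$start & age <= strategy$end &
    (age - strategy$start) %% strategy$interval == 0
}

#' Person state constructor
#'
#' The joint two-eye state of one simulated person: per-eye stages and
#' treatment-year counters, AMD subtype, detection (under medical control)
#' with years since detection, supplement and presbyopia status, and a flag
#' marking blindness onset in the current cycle (drives the certain
#' consultation).
#'
#' @param age Age in years.
#' @param stages Integer vector of two eye stage codes (see [EYE_STAGES]).
#' @param type AMD subtype code (see [AMD_TYPES]).
#' @param detected Logical; under medical control.
#' @param dty Years since detection (0 = detected this cycle).
#' @param ty Integer vector of two per-eye treatment-year counters
#'   (0 = no active treatment line; counters cap at 3 = "year 3+").
#' @param suppl Supplement status: `"never"`, `"taking"` or `"stopped"`.
#' @param presbyopia Logical; established presbyopia.
#' @param newly_blind Logical; an eye reached blindness this cycle.
#' @param alive Logical.
#' @return A list of class `amd_person`.
#' @export
person_state <- function(age = 40, stages = c(1L, 1L),
                         type = AMD_TYPES[["NONE"]],
                         detected = FALSE, dty = 0L, ty = c(0L, 0L),
                         suppl = c("never", "taking", "stopped"),
                         presbyopia = FALSE, newly_blind = FALSE,
                         alive = TRUE) {
  suppl <- match.arg(suppl)
  stopifnot(length(stages) == 2, all(stages %in% 1:5), length(ty) == 2)
  if (suppl == "taking" && !detected)
    stop("supplements can only be taken under medical control")
  if (any(ty > 0) && !detected)
    stop("treatment-year counters require detected status")
  if (type == AMD_TYPES[["NONE"]] && any(stages >= EYE_STAGES[["MODERATE"]]))
    stop("an AMD subtype must be assigned once either eye has AMD")
  if (type != AMD_TYPES[["NONE"]] && all(stages < EYE_STAGES[["MODERATE"]]))
    stop("subtype assigned but neither eye has AMD")
  structure(list(age = age, stages = as.integer(stages), type = type,
                 detected = detected, dty = as.integer(dty),
                 ty = as.integer(ty), suppl = suppl,
                 presbyopia = presbyopia, newly_blind = newly_blind,
                 alive = alive),
            class = "amd_person")
}

# mark a person detected: medical control starts, AMD eyes open a year-1
# treatment line
.detect_person <- function(person) {
  person$detected <- TRUE
  person$dty <- 0L
  amd_eye <- person$stages %in% c(EYE_STAGES[["MODERATE"]], EYE_STAGES[["SEVERE"]])
  person$ty[amd_eye] <- 1L
  person
}

.outcome <- function(person, detected, pathway, cost) {
  list(person = person, detected = detected, pathway = pathway, cost = cost)
}

#' Screening-year detection event
#'
#' For an undetected person in a screening year: participation in the
#' organized programme is drawn (60% base case); non-participants may
#' instead undergo an occasional (opportunistic) screening (20%).  Screened
#' persons pay the screening cost; any eye at prodromal stage or worse tests
#' positive with the screening sensitivity, disease-free persons test
#' false-positive with one minus specificity.  Positives attend the detailed
#' examination with the attendance probability and pay its cost; attending
#' true positives come under medical control.
#'
#' @param person An `amd_person` (not detected).
#' @param params An `amd_params` object.
#' @return A list: updated `person`, `detected` flag, `pathway`
#'   (`"screening"`, `"occasional"` or `"none"`), `cost` in JPY.
#' @export
screening_event <- function(person, params) {
  stopifnot(!person$detected)
  pathway <- "none"
  if (stats::runif(1) < params$p_participation) pathway <- "screening"
  else if (stats::runif(1) < params$p_occasional) pathway <- "occasional"
  if (pathway == "none") return(.outcome(person, FALSE, "none", 0))
  cost <- params$c_screen
  diseased <- any(person$stages >= EYE_STAGES[["PRODROMAL"]])
  p_pos <- if (diseased) params$sens else 1 - params$spec
  if (stats::runif(1) < p_pos && stats::runif(1) < params$p_detailed) {
    cost <- cost + params$c_exam
    if (diseased) return(.outcome(.detect_person(person), TRUE, pathway, cost))
  }
  .outcome(person, FALSE, "none", cost)
}

#' Coincidental consultation (presbyopia pathway)
#'
#' Presbyopia onset is drawn among persons without it; only in the onset
#' year may a clinic visit occur, and a visit detects any eye at prodromal
#' stage or worse (clinic examination taken as fully sensitive), applying
#' the detailed-examination cost.
#'
#' @inheritParams screening_event
#' @return As [screening_event()]; pathway `"coincidental"` on detection.
#' @export
coincidental_consultation <- function(person, params) {
  stopifnot(!person$detected)
  if (person$presbyopia) return(.outcome(person, FALSE, "none", 0))
  if (stats::runif(1) >= params$presby_incidence)
    return(.outcome(person, FALSE, "none", 0))
  person$presbyopia <- TRUE
  if (stats::runif(1) < params$presby_visit &&
      any(person$stages >= EYE_STAGES[["PRODROMAL"]]))
    return(.outcome(.detect_person(person), TRUE, "coincidental",
                    params$c_exam))
  .outcome(person, FALSE, "none", 0)
}

#' Symptom-driven consultation
#'
#' An eye that became blind this cycle triggers a consultation with
#' certainty; otherwise a person with any moderate or severe eye consults
#' with the annual symptom "sensor" rate (5% base case).  Prodromal-only
#' persons never consult via symptoms.  Consultation detects the disease
#' and applies the detailed-examination cost.
#'
#' @inheritParams screening_event
#' @return As [screening_event()]; pathway `"symptom"` on detection.
#' @export
symptom_consultation <- function(person, params) {
  stopifnot(!person$detected)
  p <- if (person$newly_blind) params$consult_blind
       else if (any(person$stages %in%
                    c(EYE_STAGES[["MODERATE"]], EYE_STAGES[["SEVERE"]])))
         params$sensor_ms
       else 0
  if (stats::runif(1) < p)
    .outcome(.detect_person(person), TRUE, "symptom", params$c_exam)
  else .outcome(person, FALSE, "none", 0)
}
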