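# Management of detected patients: supplements, anti-VEGF injections, PDT,
# treated transitions, endophthalmitis and dropout.

#' Injections per treatment year
#'
#' The anti-VEGF schedule: 6 injections in the first year of a treatment
#' line, 4 in the second, 2 in the third and every subsequent year (base
#' case).  The treatment-year counter resets when an eye changes stage.
#'
#' @param treatment_year Year of the current treatment line (>= 1);
#'   vectorized.
#' @param params An `amd_params` object.
#' @return Number of injections for that year.
#' @export
annual_injection_count <- function(treatment_year, params = amd_parameters()) {
  if (any(treatment_year < 1)) stop("treatment year must be >= 1")
  ifelse(treatment_year == 1, params$inj_y1,
         ifelse(treatment_year == 2, params$inj_y2, params$inj_later))
}

# treated annual transition distribution of one eye as a probability vector
# over (improve, maintain, worsen); year_one = first year of the line
.treated_dist <- function(stage, year_one, params) {
  if (stage == EYE_STAGES[["MODERATE"]]) {
    w <- if (year_one) params$eff_mod_worsen_y1 else params$eff_mod_worsen_later
    c(improve = 0, maintain = 1 - w, worsen = w)
  } else if (stage == EYE_STAGES[["SEVERE"]]) {
    if (year_one) {
      p <- c(params$eff_sev_improve_y1, params$eff_sev_maintain_y1,
             params$eff_sev_blind)
      p <- p / sum(p)
      c(improve = p[1], maintain = p[2], worsen = p[3])
    } else c(improve = 0, maintain = 1 - params$eff_sev_blind,
             worsen = params$eff_sev_blind)
  } else c(improve = 0, maintain = 1, worsen = 0)
}

#' One treated annual transition of a moderate or severe eye
#'
#' Under active treatment, a moderate eye maintains or worsens (5% in the
#' first treatment year, 22% thereafter, base case); a severe eye in its
#' first treatment year may improve to moderate (40.3%), maintain (54.7%)
#' or worsen to blindness (5%), and thereafter maintains (95%) or worsens
#' to blindness (5%).  Improvement is possible only from the severe stage
#' and only in treatment year 1.
#'
#' @param stage Eye stage code.
#' @param treatment_year Current treatment year (>= 1).
#' @param params An `amd_params` object.
#' @return The next stage code (random).
#' @export
treated_transition <- function(stage, treatment_year, params) {
  if (treatment_year < 1) stop("treatment year must be >= 1")
  d <- .treated_dist(stage, treatment_year == 1, params)
  stage + c(-1L, 0L, 1L)[sample.int(3L, 1L, prob = d)]
}

#' Annual treatment plan for a detected person
#'
#' Prodromal eyes are offered supplements with quarterly observation;
#' moderate and severe eyes receive anti-VEGF injections (6/4/2 schedule)
#' with monthly observation; severe PCV/RAP eyes additionally receive PDT
#' in treatment year 1 only; blind eyes are observed monthly without
#' treatment.  Observation visits are person-level: the most demanding
#' stage present sets the visit count.
#'
#' @param person An `amd_person`, detected.
#' @param params An `amd_params` object.
#' @return A list of class `amd_plan`: `modality` (two per-eye strings),
#'   `injections` (total this year), `pdt_sessions`, `pdt_eyes`,
#'   `observations`.
#' @export
make_plan <- function(person, params) {
  if (!person$detected) stop("treatment plans require a detected person")
  M <- EYE_STAGES[["MODERATE"]]; S <- EYE_STAGES[["SEVERE"]]
  B <- EYE_STAGES[["BLIND"]]; P <- EYE_STAGES[["PRODROMAL"]]
  pdt_type <- person$type %in% c(AMD_TYPES[["PCV"]], AMD_TYPES[["RAP"]])
  modality <- character(2)
  inj <- 0
  pdt_eyes <- 0L
  for (e in 1:2) {
    s <- person$stages[e]
    if (s == P) modality[e] <- "supplements"
    else if (s %in% c(M, S)) {
      gets_pdt <- s == S && pdt_type && person$ty[e] == 1L
      modality[e] <- if (gets_pdt) "injections+PDT" else "injections"
      inj <- inj + annual_injection_count(max(person$ty[e], 1L), params)
      if (gets_pdt) pdt_eyes <- pdt_eyes + 1L
    } else if (s == B) modality[e] <- "observation"
    else modality[e] <- "none"
  }
  obs <- if (any(person$stages %in% c(M, S))) params$obs_amd
         else if (any(person$stages == B)) params$obs_blind
         else if (any(person$stages == P)) params$obs_prodromal
         else 0
  structure(list(modality = modality, injections = inj,
                 pdt_sessions = if (pdt_eyes > 0) params$pdt_y1 else 0,
                 pdt_eyes = pdt_eyes, observations = obs),
            class = "amd_plan")
}

# cost of the PDT sessions of one cycle: the both-eyes session price applies
# when both eyes are treated in the same year
.pdt_cost <- function(pdt_sessions, pdt_eyes, params) {
  if (pdt_eyes == 0 || pdt_sessions == 0) return(0)
  per_session <- if (pdt_eyes >= 2) params$c_pdt_both else params$c_pdt_one
  pdt_sessions * per_session
}

#' Supplement status update
#'
#' Persons under medical control with a prodromal eye are offered
#' supplements once: they start with the intake rate (50% base case).
#' Current takers continue each year with the continuation rate (90%), and
#' stop for good once no eye is prodromal (both eyes with AMD no longer
#' benefit from prophylaxis).  Takers accrue the annual supplement cost;
#' the AMD risk reduction applies only while taking.
#'
#' @param person An `amd_person`, detected.
#' @param params An `amd_params` object.
#' @return A list: updated `person` and `cost` (supplement cost this year).
#' @export
supplement_update <- function(person, params) {
  stopifnot(person$detected)
  eligible <- any(person$stages == EYE_STAGES[["PRODROMAL"]])
  if (person$suppl == "taking") {
    if (!eligible || stats::runif(1) >= params$suppl_continuation)
      person$suppl <- "stopped"
  } else if (person$suppl == "never" && eligible) {
    person$suppl <- if (stats::runif(1) < params$suppl_intake) "taking"
                    else "stopped"
  }
  list(person = person,
       cost = if (person$suppl == "taking") params$c_suppl_year else 0)
}

#' Endophthalmitis events for a year of injections
#'
#' Each injection independently causes an endophthalmitis episode with the
#' per-injection probability (0.03% base case); each episode adds the
#' episode cost but no stage or utility penalty.
#'
#' @param total_injections Number of injections (>= 0).
#' @param params An `amd_params` object.
#' @return Integer event count (random).
#' @export
endophthalmitis_events <- function(total_injections, params) {
  stopifnot(total_injections >= 0)
  stats::rbinom(1, total_injections, params$endo_per_inj)
}

#' Dropout from medical control
#'
#' Applied from the first anniversary of detection: prodromal-only patients
#' withdraw with 50% in the first year of therapy and 10% thereafter;
#' moderate/severe patients with 5% per year; patients with any blind eye
#' never withdraw.  A withdrawn person reverts to undetected status and
#' untreated dynamics (supplements stop), and remains eligible for
#' re-detection through every pathway.
#'
#' @param person An `amd_person`, detected.
#' @param params An `amd_params` object.
#' @return The updated `amd_person` (random).
#' @export
dropout_update <- function(person, params) {
  stopifnot(person$detected)
  if (person$dty < 1) return(person)   # detection cycle: therapy starts
  B <- EYE_STAGES[["BLIND"]]
  rate <-
    if (any(person$stages == B)) params$dropout_blind
    else if (any(person$stages %in%
                 c(EYE_STAGES[["MODERATE"]], EYE_STAGES[["SEVERE"]])))
      params$dropout_ms
    else if (person$dty == 1L) params$dropout_prodromal_y1
    else params$dropout_prodromal_later
  if (stats::runif(1) < rate) {
    person$detected <- FALSE
    person$dty <- 0L
    person$ty <- c(0L, 0L)
    if (person$suppl == "taking") person$suppl <- "stopped"
  }
  person
}
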