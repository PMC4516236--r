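# Deterministic cohort engine: exact propagation of probability mass over
# the finite joint state space of one person, under the same per-cycle
# event order as the microsimulation.  Each event is a sparse transition
# matrix (built from vectorized branch enumeration) plus expected-cost and
# event-count vectors evaluated on the pre-event mass.
#
# Per-eye codes couple stage and treatment-year counter:
#   1 N, 2 P, 3 M(untreated), 4 S(untreated), 5 B,
#   6/7/8 M in treatment year 1/2/3+, 9/10/11 S in treatment year 1/2/3+.
# Person state = canonical unordered eye pair x subtype x detection status
# (0 undetected, 1/2 detected one / two-plus cycles ago, 3 detected this
# cycle, transient) x supplement status x presbyopia flag.

.amdscreen_cache <- new.env(parent = emptyenv())

.eye_code_s <- c(1L, 2L, 3L, 4L, 5L, 3L, 3L, 3L, 4L, 4L, 4L)
.eye_code_ty <- c(0L, 0L, 0L, 0L, 0L, 1L, 2L, 3L, 1L, 2L, 3L)
# code for (stage, ty): .code_of[stage, ty + 1]
.code_of <- local({
  m <- matrix(NA_integer_, 5, 4)
  for (k in 1:11) m[.eye_code_s[k], .eye_code_ty[k] + 1L] <- k
  m
})
# eye code after detection (AMD eyes open a year-1 line)
.detect_code <- c(1L, 2L, 6L, 9L, 5L, 6L, 7L, 8L, 9L, 10L, 11L)
# eye code after dropout (treatment lines close)
.drop_code <- c(1L, 2L, 3L, 4L, 5L, 3L, 3L, 3L, 4L, 4L, 4L)

.cohort_space <- function() {
  if (!is.null(.amdscreen_cache$space)) return(.amdscreen_cache$space)
  pairs <- which(upper.tri(matrix(0, 11, 11), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  grid <- expand.grid(pr = seq_len(nrow(pairs)), type = 0:3, dst = 0:3,
                      suppl = 0:2, presby = 0:1)
  g <- data.frame(
    eA = pairs[grid$pr, 1], eB = pairs[grid$pr, 2],
    type = grid$type, dst = grid$dst, suppl = grid$suppl,
    presby = grid$presby)
  g$sA <- .eye_code_s[g$eA]; g$tyA <- .eye_code_ty[g$eA]
  g$sB <- .eye_code_s[g$eB]; g$tyB <- .eye_code_ty[g$eB]
  N <- nrow(g)
  L <- array(NA_integer_, dim = c(11, 11, 4, 4, 3, 2))
  L[cbind(g$eA, g$eB, g$type + 1L, g$dst + 1L, g$suppl + 1L,
          g$presby + 1L)] <- seq_len(N)
  space <- list(grid = g, N = N, lookup = L,
                idx0 = L[1, 1, 1, 1, 1, 1],
                paircat = .pair_category(.eye_code_s[g$eA],
                                         .eye_code_s[g$eB]),
                amd_mask = .eye_code_s[g$eA] >= 3 | .eye_code_s[g$eB] >= 3)
  .amdscreen_cache$space <- space
  space
}

# canonical state index from attribute vectors
.idx_of <- function(space, eA, eB, type, dst, suppl, presby) {
  a <- pmin(eA, eB); b <- pmax(eA, eB)
  idx <- space$lookup[cbind(a, b, type + 1L, dst + 1L, suppl + 1L,
                            presby + 1L)]
  if (anyNA(idx)) stop("internal error: unindexed destination state")
  idx
}

# triplet collector for sparse matrix assembly
.new_collector <- function() {
  e <- new.env(parent = emptyenv())
  e$i <- list(); e$j <- list(); e$x <- list(); e$k <- 0L
  e
}
.add_triplets <- function(col, i, j, x) {
  keep <- x > 0
  if (!any(keep)) return(invisible())
  col$k <- col$k + 1L
  col$i[[col$k]] <- i[keep]; col$j[[col$k]] <- j[keep]
  col$x[[col$k]] <- x[keep]
  invisible()
}
.as_matrix <- function(col, N) {
  Matrix::sparseMatrix(i = unlist(col$i), j = unlist(col$j),
                       x = unlist(col$x), dims = c(N, N))
}

# event 2+3: simultaneous eye transitions, subtype assignment, treatment-
# year update, then symptom consultation for the undetected
.build_e23 <- function(space, params, age) {
  g <- space$grid; N <- space$N
  det <- g$dst >= 1L
  taking <- g$suppl == 1L
  oA <- .eye_outcome_probs(g$sA, g$sB, g$tyA, det, taking, age, params)
  oB <- .eye_outcome_probs(g$sB, g$sA, g$tyB, det, taking, age, params)
  pA <- list(oA$imp, 1 - oA$imp - oA$wor, oA$wor)
  pB <- list(oB$imp, 1 - oB$imp - oB$wor, oB$wor)
  sp <- .subtype_probs(params)
  col <- .new_collector()
  ce_exam <- numeric(N)
  tly <- list(amd_onset = numeric(N), second_onset = numeric(N),
              person_blind = numeric(N), det_symptom = numeric(N))

  emit_leaf <- function(src, p, ecA, ecB, type2) {
    # split on symptom consultation for undetected source states
    und <- g$dst[src] == 0L
    nsA <- .eye_code_s[ecA]; nsB <- .eye_code_s[ecB]
    nb <- (nsA == 5L & g$sA[src] < 5L) | (nsB == 5L & g$sB[src] < 5L)
    any_ms <- nsA %in% c(3L, 4L) | nsB %in% c(3L, 4L)
    pc <- ifelse(und & nb, params$consult_blind,
                 ifelse(und & any_ms, params$sensor_ms, 0))
    .add_triplets(col,
                  .idx_of(space, ecA, ecB, type2, g$dst[src], g$suppl[src],
                          g$presby[src]),
                  src, p * (1 - pc))
    w <- which(pc > 0)
    if (length(w)) {
      .add_triplets(col,
                    .idx_of(space, .detect_code[ecA[w]], .detect_code[ecB[w]],
                            type2[w], 3L, g$suppl[src][w], g$presby[src][w]),
                    src[w], (p * pc)[w])
      ce_exam[src[w]] <<- ce_exam[src[w]] + (p * pc)[w] * params$c_exam
      tly$det_symptom[src[w]] <<- tly$det_symptom[src[w]] + (p * pc)[w]
    }
  }

  for (da in -1:1) for (db in -1:1) {
    p0 <- pA[[da + 2L]] * pB[[db + 2L]]
    src <- which(p0 > 0)
    if (!length(src)) next
    p0 <- p0[src]
    sA0 <- g$sA[src]; sB0 <- g$sB[src]
    nsA <- sA0 + da; nsB <- sB0 + db
    ntyA <- .next_ty(nsA, sA0, g$tyA[src], det[src])
    ntyB <- .next_ty(nsB, sB0, g$tyB[src], det[src])
    ecA <- .code_of[cbind(nsA, ntyA + 1L)]
    ecB <- .code_of[cbind(nsB, ntyB + 1L)]
    convA <- da == 1L & sA0 == 2L
    convB <- db == 1L & sB0 == 2L
    had <- sA0 >= 3L | sB0 >= 3L
    n2 <- ifelse(had, convA + convB, as.numeric(convA & convB))
    both_new_blind <- nsA == 5L & nsB == 5L & !(sA0 == 5L & sB0 == 5L)
    tly$second_onset[src] <- tly$second_onset[src] + p0 * n2
    tly$person_blind[src] <- tly$person_blind[src] + p0 * both_new_blind
    assign <- g$type[src] == 0L & (convA | convB)
    tly$amd_onset[src] <- tly$amd_onset[src] + p0 * assign
    wk <- which(!assign)
    if (length(wk))
      emit_leaf(src[wk], p0[wk], ecA[wk], ecB[wk], g$type[src][wk])
    wa <- which(assign)
    if (length(wa))
      for (k in 1:3)
        emit_leaf(src[wa], p0[wa] * sp[k], ecA[wa], ecB[wa],
                  rep(k, length(wa)))
  }
  list(M = .as_matrix(col, N), cost = list(exam = ce_exam), tallies = tly)
}

# event 4: organized + occasional screening in a screening year
.build_e4 <- function(space, params) {
  g <- space$grid; N <- space$N
  und <- g$dst == 0L
  diseased <- g$sA >= 2L | g$sB >= 2L
  p_scr <- ifelse(und, params$p_participation +
                    (1 - params$p_participation) * params$p_occasional, 0)
  p_org <- ifelse(und, params$p_participation, 0)
  p_pos <- ifelse(diseased, params$sens, 1 - params$spec)
  p_hit <- ifelse(diseased, params$sens * params$p_detailed, 0)
  pdet_org <- p_org * p_hit
  pdet <- p_scr * p_hit
  col <- .new_collector()
  src <- seq_len(N)
  .add_triplets(col, src, src, 1 - pdet)
  w <- which(pdet > 0)
  .add_triplets(col,
                .idx_of(space, .detect_code[g$eA[w]], .detect_code[g$eB[w]],
                        g$type[w], 3L, g$suppl[w], g$presby[w]),
                w, pdet[w])
  list(M = .as_matrix(col, N),
       cost = list(screening = p_scr * params$c_screen,
                   exam = p_scr * p_pos * params$p_detailed * params$c_exam),
       tallies = list(det_screen = pdet_org,
                      det_occasional = pdet - pdet_org))
}

# event 5: coincidental consultation in the presbyopia onset year
.build_e5 <- function(space, params) {
  g <- space$grid; N <- space$N
  appl <- g$dst == 0L & g$presby == 0L
  diseased <- g$sA >= 2L | g$sB >= 2L
  p_on <- ifelse(appl, params$presby_incidence, 0)
  p_det <- p_on * params$presby_visit * diseased
  col <- .new_collector()
  src <- seq_len(N)
  .add_triplets(col, src, src, 1 - p_on)
  w <- which(p_on > 0)
  .add_triplets(col,
                .idx_of(space, g$eA[w], g$eB[w], g$type[w], g$dst[w],
                        g$suppl[w], 1L),
                w, (p_on - p_det)[w])
  w <- which(p_det > 0)
  .add_triplets(col,
                .idx_of(space, .detect_code[g$eA[w]], .detect_code[g$eB[w]],
                        g$type[w], 3L, g$suppl[w], 1L),
                w, p_det[w])
  list(M = .as_matrix(col, N),
       cost = list(exam = p_det * params$c_exam),
       tallies = list(det_coincidental = p_det))
}

# event 6: supplement continuation/offer, then dropout
.build_e6 <- function(space, params) {
  g <- space$grid; N <- space$N
  detst <- g$dst >= 1L
  eligS <- g$sA == 2L | g$sB == 2L
  s0 <- g$suppl
  # distribution over next supplement status (0 never, 1 taking, 2 stopped)
  p_take <- ifelse(detst & eligS & s0 == 1L, params$suppl_continuation,
                   ifelse(detst & eligS & s0 == 0L, params$suppl_intake, 0))
  p_stop <- ifelse(detst & s0 == 1L, 1 - eligS * params$suppl_continuation,
                   ifelse(detst & eligS & s0 == 0L, 1 - params$suppl_intake,
                          ifelse(detst & s0 == 2L, 1, 0)))
  p_keep0 <- ifelse(detst & s0 == 0L & !eligS, 1, 0)
  p_keep_nondet <- ifelse(!detst, 1, 0)  # undetected keep current status
  any_b <- g$sA == 5L | g$sB == 5L
  any_ms <- g$sA %in% c(3L, 4L) | g$sB %in% c(3L, 4L)
  r <- ifelse(g$dst %in% 1:2,
              ifelse(any_b, params$dropout_blind,
                     ifelse(any_ms, params$dropout_ms,
                            ifelse(g$dst == 1L, params$dropout_prodromal_y1,
                                   params$dropout_prodromal_later))), 0)
  col <- .new_collector()
  src <- seq_len(N)
  emit6 <- function(p_suppl, suppl2) {
    w <- which(p_suppl > 0)
    if (!length(w)) return(invisible())
    s2 <- if (length(suppl2) == 1L) rep(suppl2, length(w)) else suppl2[w]
    # keep (no dropout)
    .add_triplets(col,
                  .idx_of(space, g$eA[w], g$eB[w], g$type[w], g$dst[w],
                          s2, g$presby[w]),
                  w, p_suppl[w] * (1 - r[w]))
    # dropout: revert to undetected, treatment lines close, takers stop
    wd <- which(p_suppl > 0 & r > 0)
    if (length(wd)) {
      s2d <- if (length(suppl2) == 1L) rep(suppl2, length(wd)) else suppl2[wd]
      s2d <- ifelse(s2d == 1L, 2L, s2d)
      .add_triplets(col,
                    .idx_of(space, .drop_code[g$eA[wd]], .drop_code[g$eB[wd]],
                            g$type[wd], 0L, s2d, g$presby[wd]),
                    wd, p_suppl[wd] * r[wd])
    }
  }
  emit6(p_take, 1L)
  emit6(p_stop, 2L)
  emit6(p_keep0, 0L)
  emit6(p_keep_nondet, g$suppl)
  list(M = .as_matrix(col, N), cost = list(),
       tallies = list(dropouts = r))
}

# event 7: treatment delivery cost/count vectors on the post-event-6 state
.build_e7 <- function(space, params) {
  g <- space$grid
  detst <- g$dst >= 1L
  any_ms <- g$sA %in% c(3L, 4L) | g$sB %in% c(3L, 4L)
  any_b <- g$sA == 5L | g$sB == 5L
  any_p <- g$sA == 2L | g$sB == 2L
  obs <- detst * .obs_per_year(any_ms, any_b, any_p, params)
  inj <- detst * ((g$sA %in% c(3L, 4L)) *
                    annual_injection_count(pmax(g$tyA, 1L), params) +
                  (g$sB %in% c(3L, 4L)) *
                    annual_injection_count(pmax(g$tyB, 1L), params))
  pdt_type <- g$type %in% c(2L, 3L)
  pdt_eyes <- detst * ((g$sA == 4L & pdt_type & g$tyA == 1L) +
                       (g$sB == 4L & pdt_type & g$tyB == 1L))
  pdt_cost <- ifelse(pdt_eyes >= 2, params$pdt_y1 * params$c_pdt_both,
                     ifelse(pdt_eyes == 1, params$pdt_y1 * params$c_pdt_one,
                            0))
  suppl_cost <- detst * (g$suppl == 1L) * params$c_suppl_year
  list(cost = list(observation = obs * params$c_obs,
                   injections = inj * params$c_inj,
                   pdt = pdt_cost,
                   endophthalmitis = inj * params$endo_per_inj *
                     params$c_endo,
                   supplements = suppl_cost),
       tallies = list(injections = inj,
                      pdt_sessions = params$pdt_y1 * pdt_eyes,
                      endophthalmitis = inj * params$endo_per_inj))
}

# end-of-cycle relabeling: newly detected (3) age to 1, 1 ages to 2
.build_relabel <- function(space) {
  g <- space$grid
  dst2 <- c(0L, 2L, 2L, 1L)[g$dst + 1L]
  dest <- .idx_of(space, g$eA, g$eB, g$type, dst2, g$suppl, g$presby)
  Matrix::sparseMatrix(i = dest, j = seq_len(space$N), x = 1,
                       dims = c(space$N, space$N))
}

# assemble all transition matrices and accrual vectors for one parameter set
.build_cohort_model <- function(params, space = .cohort_space()) {
  list(e23 = lapply(.band_ages, function(a) .build_e23(space, params, a)),
       e4 = .build_e4(space, params),
       e5 = .build_e5(space, params),
       e6 = .build_e6(space, params),
       e7 = .build_e7(space, params),
       relabel = if (is.null(.amdscreen_cache$relabel))
                   (.amdscreen_cache$relabel <- .build_relabel(space))
                 else .amdscreen_cache$relabel,
       u = utility_value(space$grid$sA, space$grid$sB, params))
}

#' Run the deterministic cohort (expected-value) model
#'
#' Propagates exact probability mass through the same per-cycle event order
#' as [run_microsim()] over the finite joint state space (canonical
#' two-eye stage/treatment-year pairs x subtype x detection x supplement x
#' presbyopia attributes).  Occupancy mass is conserved to machine
#' precision; results are the exact expectations that the microsimulation
#' estimates, which makes this mode the engine of choice for sensitivity
#' analyses.
#'
#' @inheritParams run_microsim
#' @param model Prebuilt event-matrix model from the internal builder;
#'   lets several strategies share one parameter-set build (used by the
#'   grid search and the sensitivity analyses).
#' @return An `amd_cohort` object with per-person expected values; `n` is
#'   `Inf` (no Monte-Carlo error).
#' @export
run_cohort <- function(strategy, params, life_table = synth_life_table(),
                       model = NULL) {
  stopifnot(inherits(strategy, "amd_strategy"))
  validate_parameters(params, strict_utility_order = FALSE)
  space <- .cohort_space()
  mod <- if (is.null(model)) .build_cohort_model(params, space) else model
  N <- space$N
  r <- params$discount
  mass <- numeric(N)
  mass[space$idx0] <- 1
  dead <- 0
  cat_disc <- stats::setNames(numeric(7), .cost_categories)
  cat_undisc <- cat_disc
  tal <- list(amd_onset = 0, second_onset = 0, person_blind = 0,
              det_screen = 0, det_occasional = 0, det_symptom = 0,
              det_coincidental = 0, injections = 0, pdt_sessions = 0,
              endophthalmitis = 0, dropouts = 0)
  qaly <- 0
  nc <- .cycles
  per_age <- data.frame(age = 40:89, alive = numeric(nc), amd = numeric(nc),
                        onset_flow = numeric(nc), blind_flow = numeric(nc))
  occupancy <- matrix(0, nc, 15)
  max_leak <- 0

  accrue <- function(ev, m, disc) {
    for (nm in names(ev$cost)) {
      amt <- sum(m * ev$cost[[nm]])
      cat_disc[nm] <<- cat_disc[nm] + amt * disc
      cat_undisc[nm] <<- cat_undisc[nm] + amt
    }
    for (nm in names(ev$tallies))
      tal[[nm]] <<- tal[[nm]] + sum(m * ev$tallies[[nm]])
  }

  for (t in 0:(nc - 1L)) {
    age <- 40L + t
    disc <- (1 + r)^(-t)
    q <- .qx_at(life_table, age)
    dead <- dead + q * sum(mass)
    mass <- mass * (1 - q)
    e23 <- mod$e23[[.age_band(age)]]
    accrue(e23, mass, disc)
    per_age$onset_flow[t + 1L] <- sum(mass * e23$tallies$amd_onset)
    per_age$blind_flow[t + 1L] <- sum(mass * e23$tallies$person_blind)
    mass <- as.numeric(e23$M %*% mass)
    if (screening_due(age, strategy)) {
      accrue(mod$e4, mass, disc)
      mass <- as.numeric(mod$e4$M %*% mass)
    }
    accrue(mod$e5, mass, disc)
    mass <- as.numeric(mod$e5$M %*% mass)
    accrue(mod$e6, mass, disc)
    mass <- as.numeric(mod$e6$M %*% mass)
    accrue(mod$e7, mass, disc)
    qaly <- qaly + sum(mass * mod$u) * disc
    per_age$alive[t + 1L] <- sum(mass)
    per_age$amd[t + 1L] <- sum(mass[space$amd_mask])
    occupancy[t + 1L, ] <- as.numeric(
      rowsum(mass, space$paircat, reorder = TRUE))
    mass <- as.numeric(mod$relabel %*% mass)
    max_leak <- max(max_leak, abs(sum(mass) + dead - 1))
  }

  res <- .new_cohort_result(
    mode = "cohort", n = Inf, strategy = strategy, params = params,
    cost = sum(cat_disc), qaly = qaly,
    cost_by_category = cat_disc, cost_by_category_undisc = cat_undisc,
    tallies = tal, per_age = per_age, occupancy = occupancy,
    pt_prevalence = sum(per_age$amd) / sum(per_age$alive))
  res$mass_leak <- max_leak
  res
}
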