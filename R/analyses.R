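# Strategy comparison and the headline analyses: model validation,
# blindness reduction, screening-programme grid search, one-way (tornado)
# sensitivity analysis, probabilistic sensitivity analysis and population
# projection.

#' Compare a screened with a non-screened run
#'
#' Computes the incremental cost, incremental QALY and ICER of the screened
#' strategy versus the comparator, and attaches the clinical-effectiveness
#' deltas (cumulative bilateral blindness and AMD onset per person).  Both
#' runs must come from the same parameter set.
#'
#' @param screened,nonscreened `amd_cohort` results from [run_cohort()] or
#'   [run_microsim()] under identical parameters.
#' @param params The `amd_params` used for both runs (for the exchange
#'   rate).
#' @return An `amd_cea` object with elements `blind_screened`,
#'   `blind_nonscreened`, `amd_screened`, `amd_nonscreened` added.
#' @export
compare_strategies <- function(screened, nonscreened, params) {
  stopifnot(inherits(screened, "amd_cohort"),
            inherits(nonscreened, "amd_cohort"))
  if (!isTRUE(all.equal(screened$param_values, nonscreened$param_values)))
    stop("runs were made under different parameter sets")
  res <- icer(screened$cost, screened$qaly,
              nonscreened$cost, nonscreened$qaly,
              exchange_rate = params$exchange_rate)
  res$blind_screened <- screened$tallies$person_blind
  res$blind_nonscreened <- nonscreened$tallies$person_blind
  res$amd_screened <- screened$tallies$amd_onset
  res$amd_nonscreened <- nonscreened$tallies$amd_onset
  res
}

# run both arms off one model build (cohort mode); used by the analyses
.run_pair <- function(params, life_table, strategy = screening_strategy()) {
  model <- .build_cohort_model(params)
  list(screened = run_cohort(strategy, params, life_table, model = model),
       nonscreened = run_cohort(screening_strategy(enabled = FALSE),
                                params, life_table, model = model))
}

#' External-validation metrics of the natural-history model
#'
#' Runs the non-screened strategy and returns the three quantities used to
#' check the model against published epidemiology: person-time-weighted
#' prevalence of AMD among living persons aged 40+, the proportion of AMD
#' patients with only one affected eye (ever), and the cumulative
#' incidence of person-level (bilateral) blindness.
#'
#' @param params An `amd_params` object.
#' @param life_table An `amd_life_table`.
#' @param n Number of persons for microsimulation mode; `NULL` (default)
#'   uses the deterministic cohort mode.
#' @param seed Seed for microsimulation mode.
#' @return A list: `prevalence_pct`, `unilateral_pct`, `blindness_pct`
#'   (all in percent; `unilateral_pct` is `NA` if no AMD ever occurs).
#' @export
validate_model <- function(params, life_table = synth_life_table(),
                           n = NULL, seed = 1) {
  ns <- screening_strategy(enabled = FALSE)
  res <- if (is.null(n)) run_cohort(ns, params, life_table)
         else run_microsim(ns, params, life_table, n = n, seed = seed)
  f1 <- res$tallies$amd_onset
  f2 <- res$tallies$second_onset
  list(prevalence_pct = 100 * res$pt_prevalence,
       unilateral_pct = if (f1 > 0) 100 * (1 - f2 / f1) else NA_real_,
       blindness_pct = 100 * res$tallies$person_blind)
}

#' Reduction in blindness from screening
#'
#' Crude mode compares the cumulative person-level blindness of the two
#' runs directly; age-standardized mode weights the per-age blindness
#' incidence rates (new bilateral blindness per living person) by a
#' reference population before comparing (direct standardization).
#'
#' @param screened,nonscreened Matched `amd_cohort` results.
#' @param mode `"crude"` or `"age_standardized"`.
#' @param population An `amd_population` (required for standardization).
#' @return An object of class `amd_reduction`: `reduction_pct`, `mode`,
#'   and a `per_age` data frame with the cumulative-blindness curves and
#'   the per-age reduction.
#' @export
blindness_reduction <- function(screened, nonscreened,
                                mode = c("crude", "age_standardized"),
                                population = NULL) {
  mode <- match.arg(mode)
  s <- screened$per_age; ns <- nonscreened$per_age
  if (sum(ns$blind_flow) <= 0)
    stop("no blindness in the comparator run; reduction undefined")
  if (mode == "crude") {
    red <- 1 - sum(s$blind_flow) / sum(ns$blind_flow)
  } else {
    if (is.null(population)) stop("age standardization needs a population")
    w <- population$weight[match(s$age, population$age)]
    if (anyNA(w)) stop("population does not cover the model ages")
    rs <- ifelse(s$alive > 0, s$blind_flow / s$alive, 0)
    rn <- ifelse(ns$alive > 0, ns$blind_flow / ns$alive, 0)
    red <- 1 - sum(w * rs) / sum(w * rn)
  }
  per_age <- data.frame(
    age = s$age,
    cum_blind_screened = cumsum(s$blind_flow),
    cum_blind_nonscreened = cumsum(ns$blind_flow),
    cum_amd_screened = cumsum(s$onset_flow),
    cum_amd_nonscreened = cumsum(ns$onset_flow))
  per_age$reduction_pct <- ifelse(
    per_age$cum_blind_nonscreened > 0,
    100 * (1 - per_age$cum_blind_screened / per_age$cum_blind_nonscreened),
    NA_real_)
  structure(list(reduction_pct = 100 * red, mode = mode, per_age = per_age),
            class = "amd_reduction")
}

#' @export
print.amd_reduction <- function(x, ...) {
  cat(sprintf("Blindness reduction (%s): %.1f%%\n", x$mode, x$reduction_pct))
  invisible(x)
}

#' Grid search over screening programmes
#'
#' Evaluates every feasible combination of screening start age, end age and
#' interval against no screening (cohort mode) and reports incremental cost,
#' incremental QALY, ICER and crude blindness reduction per programme.
#' Infeasible combinations (start > end) are skipped.
#'
#' @param start_ages,end_ages,intervals Numeric grids; defaults are the
#'   programme ranges of the parameter table (starts 40/50/60/70, ends
#'   60/70/80/90, intervals 1-10).
#' @param params An `amd_params` object.
#' @param life_table An `amd_life_table`.
#' @param progress Print progress lines.
#' @return An object of class `amd_grid`: data frame with one row per
#'   programme, sorted by ICER; the no-screening reference run is attached
#'   as attribute `reference`.
#' @export
grid_search_programs <- function(start_ages = c(40, 50, 60, 70),
                                 end_ages = c(60, 70, 80, 90),
                                 intervals = 1:10,
                                 params = amd_parameters(),
                                 life_table = synth_life_table(),
                                 progress = FALSE) {
  combos <- expand.grid(start = start_ages, end = end_ages,
                        interval = intervals)
  combos <- combos[combos$start <= combos$end, , drop = FALSE]
  if (!nrow(combos)) stop("empty programme grid")
  model <- .build_cohort_model(params)
  ref <- run_cohort(screening_strategy(enabled = FALSE), params, life_table,
                    model = model)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    st <- screening_strategy(TRUE, combos$start[i], combos$end[i],
                             combos$interval[i])
    res <- run_cohort(st, params, life_table, model = model)
    ce <- compare_strategies(res, ref, params)
    if (progress)
      message(sprintf("programme (%d, %d, %d): ICER %.0f JPY/QALY",
                      combos$start[i], combos$end[i], combos$interval[i],
                      ce$icer_jpy))
    data.frame(start = combos$start[i], end = combos$end[i],
               interval = combos$interval[i],
               inc_cost = ce$inc_cost, inc_qaly = ce$inc_qaly,
               icer_jpy = ce$icer_jpy, icer_usd = ce$icer_usd,
               dominance = ce$dominance,
               blind_reduction_pct =
                 100 * (1 - res$tallies$person_blind /
                          ref$tallies$person_blind))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$icer_jpy), ]
  rownames(out) <- NULL
  structure(out, reference = ref, class = c("amd_grid", "data.frame"))
}

#' One-way sensitivity analysis (tornado)
#'
#' For every parameter with a sensitivity range, sets it to its low and
#' high bound in turn (all else at base), re-evaluates the screened versus
#' non-screened comparison in cohort mode, and reports the outcome at each
#' bound with the absolute span, sorted descending.
#'
#' @param params An `amd_params` object.
#' @param outcome `"icer"` (JPY/QALY) or `"blindness"` (crude reduction,
#'   percent).
#' @param strategy Screening strategy (base case by default).
#' @param life_table An `amd_life_table`.
#' @param names Optional subset of parameter names (default: all ranged).
#' @param progress Print progress lines.
#' @return An object of class `amd_tornado`: data frame with columns
#'   `name`, `label`, `low`, `high` (outcome at each bound), `span`;
#'   attribute `base_outcome` has the unperturbed value.
#' @export
one_way_sa <- function(params, outcome = c("icer", "blindness"),
                       strategy = screening_strategy(),
                       life_table = synth_life_table(),
                       names = NULL, progress = FALSE) {
  outcome <- match.arg(outcome)
  eval_outcome <- function(p) {
    pr <- .run_pair(p, life_table, strategy)
    if (outcome == "icer")
      compare_strategies(pr$screened, pr$nonscreened, p)$icer_jpy
    else blindness_reduction(pr$screened, pr$nonscreened,
                             "crude")$reduction_pct
  }
  base_outcome <- eval_outcome(params)
  nms <- if (is.null(names)) .ranged_names(params) else names
  tab <- attr(params, "ranges")
  rows <- lapply(nms, function(nm) {
    lo <- eval_outcome(perturb_parameter(params, nm, "low"))
    hi <- eval_outcome(perturb_parameter(params, nm, "high"))
    if (progress) message(sprintf("%s: [%.4g, %.4g]", nm, lo, hi))
    data.frame(name = nm, label = tab$label[match(nm, tab$name)],
               low = lo, high = hi, span = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, base_outcome = base_outcome, outcome = outcome,
            class = c("amd_tornado", "data.frame"))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets with [sample_psa_parameters()], evaluates
#' screened versus non-screened in cohort mode for each, and summarizes the
#' incremental cost-effectiveness cloud: the fraction of draws in which
#' screening yields positive incremental QALYs, and the fraction in the
#' cost-effective region (positive QALY gain with ICER below the
#' willingness-to-pay threshold).
#'
#' @param params Base `amd_params` object.
#' @param n_draws Number of Monte Carlo parameter draws (>= 1).
#' @param wtp Willingness-to-pay threshold, JPY/QALY (default 5,000,000).
#' @param seed Integer seed (reproducible).
#' @param life_table An `amd_life_table`.
#' @param strategy Screening strategy (base case by default).
#' @param progress Print a progress line every 50 draws.
#' @return An object of class `amd_psa`: `draws` data frame
#'   (`inc_cost`, `inc_qaly`), `frac_positive_qaly`,
#'   `frac_cost_effective`, `wtp`.
#' @export
run_psa <- function(params, n_draws = 500, wtp = 5e6, seed = 1,
                    life_table = synth_life_table(),
                    strategy = screening_strategy(), progress = FALSE) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  dc <- numeric(n_draws); dq <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    p <- sample_psa_parameters(params)
    pr <- .run_pair(p, life_table, strategy)
    dc[i] <- pr$screened$cost - pr$nonscreened$cost
    dq[i] <- pr$screened$qaly - pr$nonscreened$qaly
    if (progress && i %% 50 == 0) message("PSA draw ", i, "/", n_draws)
  }
  ce <- dq > 0 & dc / dq < wtp
  structure(list(draws = data.frame(inc_cost = dc, inc_qaly = dq),
                 frac_positive_qaly = mean(dq > 0),
                 frac_cost_effective = mean(ce), wtp = wtp,
                 n_draws = n_draws),
            class = "amd_psa")
}

#' @export
print.amd_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis (%d draws)\n", x$n_draws))
  cat(sprintf("  positive incremental QALY: %.1f%%\n",
              100 * x$frac_positive_qaly))
  cat(sprintf("  cost-effective at WTP %.0f JPY/QALY: %.1f%%\n",
              x$wtp, 100 * x$frac_cost_effective))
  invisible(x)
}

#' Project cohort rates onto a population age structure
#'
#' Multiplies the model's per-age prevalence rates (per living person) by
#' the reference population weights and sums, giving expected population
#' counts of persons in the prodromal state (no AMD, at least one
#' prodromal eye), with AMD (any eye moderate or worse), and with
#' bilateral blindness.
#'
#' @param cohort_result An `amd_cohort`.
#' @param population An `amd_population` covering ages 40-89.
#' @return A list: `prodromal`, `amd`, `blind` (projected counts) and a
#'   `per_age` data frame of the rates used.
#' @export
project_to_population <- function(cohort_result, population) {
  pa <- cohort_result$per_age
  occ <- cohort_result$occupancy
  w <- population$weight[match(pa$age, population$age)]
  if (anyNA(w)) stop("population does not cover the model ages 40-89")
  nm <- colnames(occ)
  prodromal_cat <- nm %in% c("N/P", "P/P")
  amd_cat <- grepl("M|S|B", nm)
  blind_cat <- nm == "B/B"
  alive <- pa$alive
  rate <- function(mask) ifelse(alive > 0, rowSums(occ[, mask, drop = FALSE])
                                / alive, 0)
  per_age <- data.frame(age = pa$age, prodromal_rate = rate(prodromal_cat),
                        amd_rate = rate(amd_cat), blind_rate = rate(blind_cat))
  list(prodromal = sum(w * per_age$prodromal_rate),
       amd = sum(w * per_age$amd_rate),
       blind = sum(w * per_age$blind_rate),
       per_age = per_age)
}

#' Scenario parameter presets
#'
#' Named variants of the base case: `"bevacizumab"` swaps the injection
#' cost for a user-supplied bevacizumab unit cost with identical efficacy;
#' `"best_case"` additionally follows up prodromal patients once a year
#' and sets the supplement cost to zero.  No default bevacizumab price is
#' assumed; it must be supplied.
#'
#' @param scenario `"bevacizumab"` or `"best_case"`.
#' @param bevacizumab_cost Cost per bevacizumab injection, JPY (required).
#' @param params Base `amd_params` to modify.
#' @return An `amd_params` object.
#' @export
scenario_parameters <- function(scenario = c("bevacizumab", "best_case"),
                                bevacizumab_cost,
                                params = amd_parameters()) {
  scenario <- match.arg(scenario)
  if (missing(bevacizumab_cost))
    stop("bevacizumab_cost must be supplied; no published unit price is bundled")
  params$c_inj <- bevacizumab_cost
  if (scenario == "best_case") {
    params$obs_prodromal <- 1
    params$c_suppl_year <- 0
  }
  validate_parameters(params, strict_utility_order = FALSE)
}
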