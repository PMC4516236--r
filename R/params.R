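# Model parameters: base-case values and univariate sensitivity ranges.
#
# Every tunable quantity of the model lives in a flat named list of class
# "amd_params".  The accompanying range table (attribute "ranges") drives
# one-way and probabilistic sensitivity analysis.  Relative "+/-50%" ranges
# are resolved multiplicatively around the base value at construction time.

# row helper for the parameter metadata table
.pr <- function(name, base, low, high, kind, block, label) {
  data.frame(name = name, base = base, low = low, high = high,
             kind = kind, block = block, label = label,
             stringsAsFactors = FALSE)
}

# rel = TRUE resolves low/high as multiples of base
.pr50 <- function(name, base, kind, block, label) {
  .pr(name, base, 0.5 * base, 1.5 * base, kind, block, label)
}

.param_table <- function() {
  rbind(
    ## annual transition probabilities (untreated natural history)
    .pr50("np_40", 0.0000, "prob", "transition", "normal to prodromal, ages 40-44"),
    .pr50("np_45", 0.0095, "prob", "transition", "normal to prodromal, ages 45-54"),
    .pr50("np_55", 0.0013, "prob", "transition", "normal to prodromal, ages 55-64"),
    .pr50("np_65", 0.0076, "prob", "transition", "normal to prodromal, ages 65-74"),
    .pr50("np_75", 0.0140, "prob", "transition", "normal to prodromal, ages 75+"),
    .pr50("pm_40", 0.0000, "prob", "transition", "prodromal to moderate AMD, ages 40-49"),
    .pr50("pm_50", 0.0050, "prob", "transition", "prodromal to moderate AMD, ages 50+"),
    .pr("pm_second", 0.0259, 0.0020, 0.0498, "prob", "transition",
        "prodromal to moderate AMD, second eye"),
    .pr50("ms_untreated", 0.3749, "prob", "transition", "moderate to severe AMD, untreated"),
    .pr50("sb_untreated", 0.1907, "prob", "transition", "severe AMD to blindness, untreated"),
    ## epidemiology
    .pr("type_tamd", 0.408, 0.352, 0.453, "prob", "epidemiology", "AMD subtype: tAMD"),
    .pr("type_pcv",  0.547, 0.489, 0.604, "prob", "epidemiology", "AMD subtype: PCV"),
    .pr("type_rap",  0.045, NA, NA, "prob", "epidemiology", "AMD subtype: RAP"),
    ## screening and detection pathways
    .pr("p_participation", 0.60, 0.30, 1.00, "prob", "screening", "screening participation rate"),
    .pr("p_detailed",      0.80, 0.30, 1.00, "prob", "screening", "detailed-examination attendance"),
    .pr("p_occasional",    0.20, 0.10, 0.50, "prob", "screening", "occasional (irregular) screening"),
    .pr("presby_incidence", 0.03, 0.01, 0.05, "prob", "screening", "annual incidence of presbyopia"),
    .pr("presby_visit",     0.20, NA, NA, "prob", "screening",
        "clinic visit in presbyopia onset year"),
    .pr("consult_blind", 1.00, NA, NA, "prob", "screening",
        "consultation on new blindness in either eye"),
    .pr("sensor_ms",    0.05, 0.00, 0.50, "prob", "screening",
        "annual symptom consultation, moderate/severe AMD"),
    .pr("sensor_blind", 0.00, NA, NA, "prob", "screening", "symptom sensor, established blindness"),
    .pr("sens", 0.80, 0.60, 1.00, "prob", "screening", "screening sensitivity (fundus photograph)"),
    .pr("spec", 0.95, 0.80, 1.00, "prob", "screening", "screening specificity"),
    ## utilities by (better eye, worse eye) stage pair
    .pr("u_nn", 1.00, NA, NA, "utility", "utility", "utility normal/normal"),
    .pr("u_np", 1.00, NA, NA, "utility", "utility", "utility normal/prodromal"),
    .pr("u_nm", 0.92, 0.87, 0.97, "utility", "utility", "utility normal/moderate"),
    .pr("u_ns", 0.90, 0.83, 0.92, "utility", "utility", "utility normal/severe"),
    .pr("u_nb", 0.88, 0.81, 0.92, "utility", "utility", "utility normal/blindness"),
    .pr("u_pp", 0.97, 0.92, 1.00, "utility", "utility", "utility prodromal/prodromal"),
    .pr("u_pm", 0.92, 0.87, 0.97, "utility", "utility", "utility prodromal/moderate"),
    .pr("u_ps", 0.90, 0.83, 0.92, "utility", "utility", "utility prodromal/severe"),
    .pr("u_pb", 0.88, 0.81, 0.92, "utility", "utility", "utility prodromal/blindness"),
    .pr("u_mm", 0.85, 0.73, 0.96, "utility", "utility", "utility moderate/moderate"),
    .pr("u_ms", 0.83, 0.73, 0.85, "utility", "utility", "utility moderate/severe"),
    .pr("u_mb", 0.81, 0.71, 0.85, "utility", "utility", "utility moderate/blindness"),
    .pr("u_ss", 0.57, 0.46, 0.85, "utility", "utility", "utility severe/severe"),
    .pr("u_sb", 0.55, 0.46, 0.57, "utility", "utility", "utility severe/blindness"),
    .pr("u_bb", 0.46, 0.35, 0.57, "utility", "utility", "utility blindness/blindness"),
    ## direct medical costs, JPY
    .pr50("c_screen",     3000,   "cost", "cost", "screening (fundus photograph)"),
    .pr50("c_exam",       13900,  "cost", "cost", "detailed examination"),
    .pr50("c_obs",        4420,   "cost", "cost", "observation visit"),
    .pr50("c_suppl_year", 51360,  "cost", "cost", "supplements, one year"),
    .pr50("c_inj",        182035, "cost", "cost", "ranibizumab, one injection one eye"),
    .pr50("c_pdt_one",    363450, "cost", "cost", "PDT, one session one eye"),
    .pr50("c_pdt_both",   540000, "cost", "cost", "PDT, one session both eyes"),
    .pr50("c_endo",       1052750, "cost", "cost", "endophthalmitis episode"),
    .pr("discount", 0.03, 0.00, 0.05, "rate", "economics", "annual discount rate"),
    .pr("exchange_rate", 105.74, NA, NA, "other", "economics", "JPY per USD"),
    ## treatment of detected patients
    .pr("suppl_intake",       0.50, 0.00, 1.00, "prob", "treatment", "supplement intake rate"),
    .pr("suppl_continuation", 0.90, 0.50, 1.00, "prob", "treatment",
        "annual continuation of supplement intake"),
    .pr("suppl_riskred",      0.25, 0.00, 0.50, "prob", "treatment",
        "AMD risk reduction while taking supplements"),
    .pr("obs_prodromal", 4, 2, 6, "count", "treatment", "observations/year, prodromal"),
    .pr("obs_amd",      12, 6, 12, "count", "treatment", "observations/year, moderate/severe AMD"),
    .pr("obs_blind",    12, 6, 12, "count", "treatment", "observations/year, blind patient"),
    .pr("inj_y1",    6, 3, 12, "count", "treatment", "injections/year, treatment year 1"),
    .pr("inj_y2",    4, 2, 8,  "count", "treatment", "injections/year, treatment year 2"),
    .pr("inj_later", 2, 1, 3,  "count", "treatment", "injections/year, year 3 onward"),
    .pr("pdt_y1", 1, 1, 6, "count", "treatment", "PDT sessions in treatment year 1 (PCV/RAP)"),
    .pr("eff_mod_worsen_y1", 0.05, 0.01, 0.10, "prob", "treatment",
        "treated moderate to severe, year 1"),
    .pr("eff_mod_worsen_later", 0.22, 0.05, 0.40, "prob", "treatment",
        "treated moderate to severe, after year 1"),
    .pr("eff_sev_improve_y1", 0.403, 0.322, 0.485, "prob", "treatment",
        "treated severe to moderate, year 1"),
    .pr("eff_sev_maintain_y1", 0.547, NA, NA, "prob", "treatment",
        "treated severe maintained, year 1"),
    .pr("eff_sev_blind", 0.05, 0.01, 0.10, "prob", "treatment",
        "treated severe to blindness (any year)"),
    .pr("endo_per_inj", 0.0003, 0.0001, 0.0005, "prob", "treatment",
        "endophthalmitis per injection"),
    ## dropout from medical control (no ranges tabulated)
    .pr("dropout_prodromal_y1",    0.50, NA, NA, "prob", "dropout",
        "withdrawal, prodromal-only, first year"),
    .pr("dropout_prodromal_later", 0.10, NA, NA, "prob", "dropout",
        "withdrawal, prodromal-only, later years"),
    .pr("dropout_ms",    0.05, NA, NA, "prob", "dropout", "withdrawal, moderate/severe AMD"),
    .pr("dropout_blind", 0.00, NA, NA, "prob", "dropout", "withdrawal, any-eye blindness")
  )
}

#' Base-case model parameters
#'
#' Returns the complete base-case parameter set of the two-eye AMD screening
#' model: untreated and treated annual transition probabilities, AMD subtype
#' mix (typical neovascular AMD / polypoidal choroidal vasculopathy / retinal
#' angiomatous proliferation), screening and consultation detection rates,
#' better/worse-eye utility weights, direct medical costs in JPY, treatment
#' schedules, dropout rates, the annual discount rate and the JPY/USD
#' exchange rate.  Each parameter carries the interval used for univariate
#' sensitivity analysis where one is defined ("+/-50%" intervals are resolved
#' multiplicatively around the base value).
#'
#' @param overrides Optional named list (or named vector) of parameter values
#'   overriding the defaults.  Unknown names are an error; the resulting set
#'   is re-validated.
#' @return An object of class `amd_params`: a named list of parameter values
#'   with the range table in `attr(, "ranges")`.
#' @examples
#' p <- amd_parameters()
#' p$c_inj          # ranibizumab cost per injection, JPY
#' p$discount       # annual discount rate
#' p2 <- amd_parameters(list(discount = 0))
#' @seealso [perturb_parameter()], [sample_psa_parameters()],
#'   [parameter_ranges()]
#' @export
amd_parameters <- function(overrides = NULL) {
  tab <- .param_table()
  p <- as.list(stats::setNames(tab$base, tab$name))
  if (!is.null(overrides) && length(overrides)) {
    overrides <- as.list(overrides)
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) p[[nm]] <- as.numeric(overrides[[nm]])
  }
  structure(p, ranges = tab, class = "amd_params")
}

#' Parameter range table
#'
#' @param params An `amd_params` object.
#' @return Data frame with columns `name`, `base`, `low`, `high`, `kind`,
#'   `block`, `label`.  `low`/`high` are `NA` for parameters without a
#'   tabulated sensitivity range.
#' @export
parameter_ranges <- function(params = amd_parameters()) {
  stopifnot(inherits(params, "amd_params"))
  attr(params, "ranges")
}

# names of parameters with a non-degenerate or degenerate (zero-width) range
.ranged_names <- function(params) {
  tab <- attr(params, "ranges")
  tab$name[!is.na(tab$low) & !is.na(tab$high)]
}

#' Validate a parameter set
#'
#' Checks that probabilities, rates and utilities lie in \[0, 1\], costs and
#' counts are non-negative, the AMD subtype probabilities sum to ~1 (they are
#' renormalized at use), and — optionally — that the utility surface is
#' non-increasing as either eye's stage worsens.  Strict utility ordering is
#' required of the base case and of PSA draws, but not of one-way-SA
#' perturbations, whose published ranges overlap across adjacent stage pairs.
#'
#' @param params An `amd_params` object.
#' @param strict_utility_order Require monotone utilities (default `TRUE`).
#' @return `params`, invisibly; errors name the offending parameter.
#' @export
validate_parameters <- function(params, strict_utility_order = TRUE) {
  stopifnot(inherits(params, "amd_params"))
  tab <- attr(params, "ranges")
  v <- unlist(params[tab$name])
  if (any(!is.finite(v)))
    stop("non-finite value for: ", paste(tab$name[!is.finite(v)], collapse = ", "))
  pk <- tab$kind %in% c("prob", "utility", "rate")
  bad <- pk & (v < 0 | v > 1)
  if (any(bad))
    stop("probability/utility out of [0, 1]: ",
         paste(sprintf("%s = %g", tab$name[bad], v[bad]), collapse = ", "))
  ck <- tab$kind %in% c("cost", "count")
  bad <- ck & v < 0
  if (any(bad))
    stop("negative cost/count: ", paste(tab$name[bad], collapse = ", "))
  if (params$exchange_rate <= 0) stop("exchange_rate must be positive")
  tsum <- params$type_tamd + params$type_pcv + params$type_rap
  if (tsum <= 0) stop("AMD subtype probabilities sum to zero")
  if (strict_utility_order) {
    u <- utility_matrix(params)
    # non-increasing along each row (worse eye worsens) and column (better eye)
    for (i in 1:5) {
      r <- u[i, i:5]
      if (any(diff(r) > 1e-12))
        stop("utilities increase as the worse eye worsens (better stage ", i, ")")
    }
    for (j in 1:5) {
      cl <- u[1:j, j]
      if (any(diff(cl) > 1e-12))
        stop("utilities increase as the better eye worsens (worse stage ", j, ")")
    }
  }
  invisible(params)
}

#' One-way sensitivity perturbation
#'
#' Sets a single ranged parameter to its low or high bound, leaving all other
#' parameters at their current values.  Perturbing one of the AMD subtype
#' probabilities rescales the other two so the mix still sums to one.
#'
#' @param params An `amd_params` object.
#' @param name Parameter name (see [parameter_ranges()]).
#' @param direction `"low"` or `"high"`.
#' @return A new `amd_params` object.
#' @export
perturb_parameter <- function(params, name, direction = c("low", "high")) {
  direction <- match.arg(direction)
  tab <- attr(params, "ranges")
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  if (is.na(tab$low[i])) stop("parameter has no sensitivity range: ", name)
  params[[name]] <- if (direction == "low") tab$low[i] else tab$high[i]
  if (name %in% c("type_tamd", "type_pcv", "type_rap")) {
    others <- setdiff(c("type_tamd", "type_pcv", "type_rap"), name)
    rest <- 1 - params[[name]]
    osum <- params[[others[1]]] + params[[others[2]]]
    if (osum > 0 && rest >= 0) {
      params[[others[1]]] <- params[[others[1]]] / osum * rest
      params[[others[2]]] <- params[[others[2]]] / osum * rest
    }
  }
  validate_parameters(params, strict_utility_order = FALSE)
}

# moment-matched scaled-beta draw on [low, high] with mean `base`; the
# printed range is treated as an approximate 95% interval
.draw_scaled_beta <- function(n, base, low, high) {
  w <- high - low
  if (w <= 0) return(rep(base, n))
  mu <- (base - low) / w
  sd <- 1 / 3.92
  if (mu <= 0 || mu >= 1) return(rep(base, n))
  vmax <- mu * (1 - mu)
  if (sd^2 >= vmax) sd <- sqrt(vmax) / 2
  k <- vmax / sd^2 - 1
  low + w * stats::rbeta(n, mu * k, (1 - mu) * k)
}

.draw_gamma <- function(n, base, low, high) {
  if (high <= low || base <= 0) return(rep(base, n))
  sd <- (high - low) / 3.92
  shape <- (base / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / base)
}

# clip the utility surface to be non-increasing in either eye's severity,
# scanning stage pairs in severity order
.repair_utility_order <- function(params) {
  ord <- c("u_nn", "u_np", "u_nm", "u_ns", "u_nb",
           "u_pp", "u_pm", "u_ps", "u_pb",
           "u_mm", "u_ms", "u_mb", "u_ss", "u_sb", "u_bb")
  # parents of each pair: worse eye one stage better / better eye one better
  parents <- list(
    u_np = "u_nn", u_nm = "u_np", u_ns = "u_nm", u_nb = "u_ns",
    u_pp = "u_np", u_pm = c("u_pp", "u_nm"), u_ps = c("u_pm", "u_ns"),
    u_pb = c("u_ps", "u_nb"),
    u_mm = "u_pm", u_ms = c("u_mm", "u_ps"), u_mb = c("u_ms", "u_pb"),
    u_ss = "u_ms", u_sb = c("u_ss", "u_mb"), u_bb = "u_sb")
  for (nm in ord[-1]) {
    cap <- min(unlist(params[parents[[nm]]]))
    if (params[[nm]] > cap) params[[nm]] <- cap
  }
  params
}

#' Random parameter draw for probabilistic sensitivity analysis
#'
#' Draws every ranged parameter independently from an assigned distribution:
#' scaled beta on the printed interval (mean at the base value) for
#' probabilities, utilities and the discount rate; gamma (mean at the base
#' value, printed range as ~95% interval) for costs; integer uniform for
#' counts.  The AMD subtype mix is renormalized and the utility surface is
#' clipped to restore better/worse-eye monotonicity after the independent
#' draws, so every draw passes [validate_parameters()].
#'
#' @param params Base `amd_params` object.
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return A new `amd_params` object.
#' @export
sample_psa_parameters <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- attr(params, "ranges")
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$low[i]) || is.na(tab$high[i])) next
    if (tab$low[i] == tab$high[i]) next
    nm <- tab$name[i]
    params[[nm]] <- switch(
      tab$kind[i],
      cost = .draw_gamma(1, tab$base[i], tab$low[i], tab$high[i]),
      count = sample(seq(tab$low[i], tab$high[i]), 1),
      .draw_scaled_beta(1, tab$base[i], tab$low[i], tab$high[i]))
  }
  tsum <- params$type_tamd + params$type_pcv + params$type_rap
  params$type_tamd <- params$type_tamd / tsum
  params$type_pcv <- params$type_pcv / tsum
  params$type_rap <- params$type_rap / tsum
  params <- .repair_utility_order(params)
  validate_parameters(params, strict_utility_order = TRUE)
}

#' Write / read a parameter configuration
#'
#' Plain-text key/value (YAML-like) serialization; [read_parameters()] feeds
#' the values back through [amd_parameters()] so unknown keys are rejected
#' and invariants re-checked.
#'
#' @param params An `amd_params` object.
#' @param file Path to a text file.
#' @return `read_parameters()` returns an `amd_params` object.
#' @export
write_parameters <- function(params, file) {
  stopifnot(inherits(params, "amd_params"))
  lines <- sprintf("%s: %.17g", names(params), unlist(params))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed line(s): ", paste(lines[bad], collapse = "; "))
  vals <- as.list(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  p <- amd_parameters(vals)
  validate_parameters(p, strict_utility_order = FALSE)
}

#' @export
print.amd_params <- function(x, ...) {
  tab <- attr(x, "ranges")
  cat("Two-eye AMD screening model parameters (", nrow(tab), " parameters, ",
      length(.ranged_names(x)), " with sensitivity ranges)\n", sep = "")
  cur <- unlist(x[tab$name])
  ch <- which(abs(cur - tab$base) > 1e-12)
  if (length(ch)) {
    cat("Modified from base case:\n")
    for (i in ch)
      cat(sprintf("  %-22s %g (base %g)\n", tab$name[i], cur[i], tab$base[i]))
  } else cat("All parameters at base-case values.\n")
  invisible(x)
}
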