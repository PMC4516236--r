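# Background mortality and reference population structures.
#
# The model needs an age-indexed annual probability of death covering ages
# 40-90.  A reader for real abridged life tables (CSV, columns age,qx) is
# provided together with a synthetic Gompertz generator so the whole
# pipeline runs without external data.

#' Synthetic Gompertz life table
#'
#' Annual probability of death at age a is `1 - exp(-level * exp(shape * a))`,
#' clipped to \[0, 1\] — a Gompertz hazard integrated over one year of age.
#' The default coefficients give a survival from age 40 to 90 of roughly
#' 38%, in the vicinity of a contemporary Japanese adult cohort; a real
#' abridged life table can be supplied via [read_life_table()].
#'
#' @param level Level coefficient of the Gompertz hazard (>= 0).
#' @param shape Shape (log-slope) coefficient (>= 0).
#' @param ages Integer ages covered (default 40:90).
#' @return An object of class `amd_life_table`: data frame with columns
#'   `age` and `qx` (annual death probability).
#' @examples
#' lt <- synth_life_table()
#' plot(lt$age, lt$qx, type = "l")
#' @export
synth_life_table <- function(level = 1.8e-5, shape = 0.095, ages = 40:90) {
  if (level < 0 || shape < 0) stop("Gompertz coefficients must be non-negative")
  qx <- pmin(pmax(1 - exp(-level * exp(shape * ages)), 0), 1)
  structure(data.frame(age = as.integer(ages), qx = qx),
            class = c("amd_life_table", "data.frame"))
}

#' Read an abridged life table from CSV
#'
#' Expects a header `age,qx` with one row per integer age; the table must
#' cover every age in 40-90 without gaps and all probabilities must lie in
#' \[0, 1\].
#'
#' @param file Path to a CSV file.
#' @return An `amd_life_table` object.
#' @export
read_life_table <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("age", "qx") %in% names(d)))
    stop("life table must have columns 'age' and 'qx'")
  d <- d[order(d$age), c("age", "qx")]
  as_life_table(d)
}

#' Coerce a data frame to a validated life table
#'
#' @param d Data frame with columns `age`, `qx`.
#' @return An `amd_life_table` object.
#' @export
as_life_table <- function(d) {
  missing_ages <- setdiff(40:90, d$age)
  if (length(missing_ages))
    stop("life table missing age(s): ", paste(missing_ages, collapse = ", "))
  if (anyDuplicated(d$age)) stop("duplicated ages in life table")
  if (any(!is.finite(d$qx)) || any(d$qx < 0 | d$qx > 1))
    stop("life-table probabilities must lie in [0, 1]")
  structure(data.frame(age = as.integer(d$age), qx = as.numeric(d$qx)),
            class = c("amd_life_table", "data.frame"))
}

# annual death probability at (integer) ages, vectorized
.qx_at <- function(life_table, ages) {
  i <- match(ages, life_table$age)
  if (anyNA(i)) stop("life table does not cover age(s): ",
                     paste(unique(ages[is.na(i)]), collapse = ", "))
  life_table$qx[i]
}

#' Survival probability between two ages
#'
#' Chains `1 - qx` over `[from, to)`.
#'
#' @param life_table An `amd_life_table`.
#' @param from,to Integer ages, `from < to`.
#' @return Probability of surviving from `from` to `to`.
#' @export
survival_probability <- function(life_table, from = 40, to = 90) {
  stopifnot(from < to)
  prod(1 - .qx_at(life_table, from:(to - 1)))
}

#' Synthetic reference population structure
#'
#' Builds an age-indexed weight table used for age-controlled (direct)
#' standardization and for projecting cohort rates onto a population.
#' `shape = "uniform"` spreads the total evenly over the ages;
#' `shape = "stationary"` weights each age by the life-table survivorship
#' from age 40, emulating a stationary population consistent with the
#' background mortality.
#'
#' @param total Total population size (> 0).
#' @param shape `"uniform"` or `"stationary"`.
#' @param ages Integer ages covered (default 40:90).
#' @param life_table Life table used for `shape = "stationary"`.
#' @return An object of class `amd_population`: data frame with columns
#'   `age` and `weight`, weights summing to `total`.
#' @export
synth_population <- function(total, shape = c("uniform", "stationary"),
                             ages = 40:90, life_table = synth_life_table()) {
  shape <- match.arg(shape)
  if (total <= 0) stop("total must be positive")
  w <- switch(shape,
    uniform = rep(1, length(ages)),
    stationary = vapply(ages, function(a)
      if (a == 40) 1 else survival_probability(life_table, 40, a), 1.0))
  w <- w / sum(w) * total
  structure(data.frame(age = as.integer(ages), weight = w),
            class = c("amd_population", "data.frame"))
}
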