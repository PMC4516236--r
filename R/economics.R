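# Utilities, discounting and incremental cost-effectiveness.

#' Utility lookup matrix
#'
#' 5x5 upper-triangular matrix of quality-of-life weights indexed by
#' (better eye stage, worse eye stage); the lower triangle is `NA` (the
#' arguments of [utility_value()] are sorted before lookup).
#'
#' @param params An `amd_params` object.
#' @return Numeric 5x5 matrix, rows = better eye, columns = worse eye.
#' @export
utility_matrix <- function(params) {
  u <- matrix(NA_real_, 5, 5,
              dimnames = list(names(EYE_STAGES), names(EYE_STAGES)))
  u[1, ] <- c(params$u_nn, params$u_np, params$u_nm, params$u_ns, params$u_nb)
  u[2, 2:5] <- c(params$u_pp, params$u_pm, params$u_ps, params$u_pb)
  u[3, 3:5] <- c(params$u_mm, params$u_ms, params$u_mb)
  u[4, 4:5] <- c(params$u_ss, params$u_sb)
  u[5, 5] <- params$u_bb
  u
}

#' Quality-of-life weight for a pair of eye stages
#'
#' Symmetric in its arguments: the stages are sorted into (better, worse)
#' before lookup, so the better-seeing eye dominates with a decrement for
#' the worse-seeing eye.
#'
#' @param stage_a,stage_b Eye stage codes (see [EYE_STAGES]); vectorized.
#' @param params An `amd_params` object.
#' @return Utility value(s) in \[0, 1\].
#' @export
utility_value <- function(stage_a, stage_b, params) {
  u <- utility_matrix(params)
  b <- pmin(stage_a, stage_b)
  w <- pmax(stage_a, stage_b)
  u[cbind(b, w)]
}

#' Discount factor for an annual cycle
#'
#' `(1 + rate)^(-cycle)`, with cycle 0 (age 40) undiscounted; costs and
#' utilities are accrued at the start of each annual cycle (no half-cycle
#' correction).
#'
#' @param cycle Cycle index (years since model start, >= 0); vectorized.
#' @param rate Annual discount rate.
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle, rate) {
  if (any(cycle < 0)) stop("cycle index must be non-negative")
  (1 + rate)^(-cycle)
}

#' Convert JPY to USD
#'
#' @param jpy Amount(s) in Japanese yen.
#' @param exchange_rate JPY per USD (> 0); the model's base rate is 105.74.
#' @param round Round to the nearest whole dollar (default `TRUE`, the
#'   reporting convention).
#' @return Amount(s) in USD.
#' @export
jpy_to_usd <- function(jpy, exchange_rate = 105.74, round = TRUE) {
  if (exchange_rate <= 0) stop("exchange rate must be positive")
  usd <- jpy / exchange_rate
  if (round) round(usd) else usd
}

#' Incremental cost-effectiveness ratio
#'
#' ICER = incremental cost / QALY gained.  Dominance is encoded rather than
#' raised: `"dominant"` when the new strategy costs less and yields more
#' QALYs, `"dominated"` when it costs more and yields fewer, `"tradeoff"`
#' otherwise; the ratio is reported only for trade-offs with non-zero QALY
#' gain (`"undefined"` when the QALY difference is zero).
#'
#' @param cost_new,qaly_new Mean discounted cost (JPY) and QALY of the
#'   evaluated strategy.
#' @param cost_ref,qaly_ref Same for the comparator.
#' @param exchange_rate JPY per USD for the USD-denominated ICER.
#' @return An object of class `amd_cea` (list): `inc_cost`, `inc_qaly`,
#'   `icer_jpy`, `icer_usd`, `dominance`, plus the four inputs.
#' @export
icer <- function(cost_new, qaly_new, cost_ref, qaly_ref,
                 exchange_rate = 105.74) {
  stopifnot(is.finite(cost_new), is.finite(qaly_new),
            is.finite(cost_ref), is.finite(qaly_ref))
  dc <- cost_new - cost_ref
  dq <- qaly_new - qaly_ref
  dominance <-
    if (dq == 0) "undefined"
    else if (dc <= 0 && dq > 0) "dominant"
    else if (dc >= 0 && dq < 0) "dominated"
    else "tradeoff"
  ratio <- if (dominance == "tradeoff") dc / dq else NA_real_
  structure(list(cost_new = cost_new, qaly_new = qaly_new,
                 cost_ref = cost_ref, qaly_ref = qaly_ref,
                 inc_cost = dc, inc_qaly = dq,
                 icer_jpy = ratio,
                 icer_usd = if (is.na(ratio)) NA_real_
                            else jpy_to_usd(ratio, exchange_rate, round = FALSE),
                 dominance = dominance),
            class = "amd_cea")
}

#' @export
print.amd_cea <- function(x, ...) {
  cat("Incremental cost-effectiveness\n")
  cat(sprintf("  cost:  %12.0f vs %12.0f JPY  (delta %+.0f)\n",
              x$cost_new, x$cost_ref, x$inc_cost))
  cat(sprintf("  QALY:  %12.4f vs %12.4f      (delta %+.5f)\n",
              x$qaly_new, x$qaly_ref, x$inc_qaly))
  if (x$dominance == "tradeoff")
    cat("  ICER: ", format(round(x$icer_jpy), big.mark = ","), " JPY/QALY (",
        format(round(x$icer_usd), big.mark = ","), " USD/QALY)\n", sep = "")
  else cat("  dominance:", x$dominance, "\n")
  invisible(x)
}
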