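# Shared fixtures, all built in code.

# immortal life table: isolates disease dynamics from mortality
immortal_life_table <- function() {
  as_life_table(data.frame(age = 40:90, qx = 0))
}

# parameters with every disease transition switched off: the cohort stays
# entirely normal forever
zero_transition_parameters <- function(...) {
  amd_parameters(c(list(np_40 = 0, np_45 = 0, np_55 = 0, np_65 = 0,
                        np_75 = 0, pm_40 = 0, pm_50 = 0, pm_second = 0,
                        ms_untreated = 0, sb_untreated = 0), list(...)))
}

# small shared life table for engine tests
test_life_table <- function() synth_life_table()

# empirical frequency within 3 standard errors of a target proportion
expect_freq <- function(successes, n, p, label = NULL) {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(successes / n - p), 3 * se + 1e-12, label = label)
}

# degenerate-range copy of a parameter set: every sensitivity interval is
# shrunk toward the base value by `factor` (0 = point mass at base)
shrink_ranges <- function(params, factor) {
  tab <- attr(params, "ranges")
  ok <- !is.na(tab$low)
  tab$low[ok] <- tab$base[ok] + factor * (tab$low[ok] - tab$base[ok])
  tab$high[ok] <- tab$base[ok] + factor * (tab$high[ok] - tab$base[ok])
  attr(params, "ranges") <- tab
  params
}
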