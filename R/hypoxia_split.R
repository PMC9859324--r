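# Descriptive stage: 140 mmHg hypoxia dichotomization, normality-routed
# summaries, Mann-Whitney group comparisons.

#' Split regions at the hypoxia oxygen cut-off
#'
#' Ambient oxygen below about 140 mmHg corresponds to terrestrial elevations
#' over roughly 1500 m, where ambient hypoxia becomes physiologically
#' relevant. Regions at or above the cut-off form the high-oxygen group A,
#' the rest group B.
#'
#' @param regions Region data frame with an `oxygen` column (mmHg).
#' @param cutoff Cut-off in mmHg (default 140); a value exactly at the
#'   cut-off goes to the high-oxygen group.
#' @return List with data frames `high` (oxygen >= cutoff) and `low`; a
#'   warning is raised when either group is empty.
#' @export
split_by_oxygen <- function(regions, cutoff = 140) {
  if (!"oxygen" %in% names(regions) || anyNA(regions$oxygen)) {
    abort_input("oxygen must be present for all regions")
  }
  high <- regions[regions$oxygen >= cutoff, , drop = FALSE]
  low <- regions[regions$oxygen < cutoff, , drop = FALSE]
  if (nrow(high) == 0 || nrow(low) == 0) {
    warning(sprintf("one side of the %g mmHg split is empty; group comparison will be skipped",
                    cutoff))
  }
  list(high = high, low = low)
}

#' Mann-Whitney U test reporting both orientations
#'
#' `U_a` counts pairs where the group-A value exceeds the group-B value
#' (ties count one half); `U_b = n_a * n_b - U_a`, so either orientation of
#' the statistic can be read off (published tables differ in which side they
#' print, most visibly under complete separation where one is 0 and the
#' other `n_a * n_b`). The two-sided p-value is exact (distribution-based)
#' when `n_a + n_b <= 20` and there are no ties, otherwise a normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `u_a`, `u_b`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) abort_input("both groups must be non-empty")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (n_a + n_b <= 20) && !has_ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE,
                alternative = "two.sided")$p.value
  )
  list(u_a = u_a, u_b = n_a * n_b - u_a, p_value = p,
       n_a = n_a, n_b = n_b,
       method = if (exact) "exact" else "normal approximation")
}

#' Normality-routed descriptive summary
#'
#' Continuous data that pass a Shapiro-Wilk normality test (p >= alpha) are
#' summarized as mean +/- SD (SD with the n-1 denominator); otherwise as
#' median (P25-P75), quartiles by linear interpolation (quantile type 7).
#' Fewer than 3 values cannot be tested: the raw values are echoed.
#'
#' @param values Numeric vector.
#' @param alpha Normality-test level (default 0.05).
#' @return List with `route` ("normal", "nonnormal" or "raw"), the summary
#'   numbers and a `formatted` string.
#' @export
describe <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    return(list(route = "raw", values = values,
                formatted = paste(signif(values, 4), collapse = ", ")))
  }
  sw_p <- shapiro.test(values)$p.value
  if (sw_p >= alpha) {
    m <- mean(values); s <- sd(values)
    list(route = "normal", mean = m, sd = s, shapiro_p = sw_p,
         formatted = sprintf("%.2f (±%.2f)", m, s))
  } else {
    q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(route = "nonnormal", median = q[2], p25 = q[1], p75 = q[3],
         shapiro_p = sw_p,
         formatted = sprintf("%.2f (%.2f–%.2f)", q[2], q[1], q[3]))
  }
}

#' Compare variables between the oxygen groups
#'
#' The table-shaped descriptive comparison: one row per variable with the
#' normality-routed summary of each oxygen group and the Mann-Whitney U test
#' between them (both U orientations reported).
#'
#' @param regions Region data frame with `oxygen` and the variables.
#' @param variables Character vector of numeric columns to compare (default:
#'   all numeric columns except coordinates).
#' @param cutoff Oxygen cut-off in mmHg, default 140.
#' @return Data frame with columns `variable`, `n_high`, `n_low`,
#'   `summary_high`, `summary_low`, `u_high`, `u_low`, `p_value`.
#' @export
compare_oxygen_groups <- function(regions, variables = NULL, cutoff = 140) {
  groups <- split_by_oxygen(regions, cutoff)
  if (nrow(groups$high) == 0 || nrow(groups$low) == 0) {
    return(data.frame())
  }
  if (is.null(variables)) {
    numcols <- names(regions)[vapply(regions, is.numeric, logical(1))]
    variables <- setdiff(numcols, c("lon", "lat"))
  }
  rows <- lapply(variables, function(v) {
    a <- groups$high[[v]]; b <- groups$low[[v]]
    mw <- mann_whitney_u(a, b)
    data.frame(variable = v, n_high = mw$n_a, n_low = mw$n_b,
               summary_high = describe(a)$formatted,
               summary_low = describe(b)$formatted,
               u_high = mw$u_a, u_low = mw$u_b, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
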