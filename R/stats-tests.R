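# Classical two-group machinery used in the analysis layer. These wrap the
# standard stats/nortest implementations; the package-specific layer (rank
# mixed models, containment df) lives in rank-model.R.

skill_test <- function(statistic, df, p_value, estimate = NA_real_, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 estimate = estimate, method = method),
            class = "skill_test")
}

#' @exportS3Method print skill_test
print.skill_test <- function(x, ...) {
  dfs <- if (length(x$df) == 2) sprintf("(%g, %g)", x$df[1], x$df[2])
         else if (!is.na(x$df[1])) sprintf("(%g)", x$df[1]) else ""
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g\n", x$method, dfs,
              x$statistic, x$p_value))
  invisible(x)
}

#' Independent-samples t-test
#'
#' Pooled-variance Student t by default (df = n1 + n2 - 2, matching the
#' df = 23 reported for 13 vs 12 participants); Welch's correction with
#' `pooled = FALSE`. Two-sided.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param pooled Use the pooled-variance (equal-variances) statistic.
#' @return A `"skill_test"` with `statistic` (t), `df`, `p_value` and
#'   `estimate` (mean difference x - y). Zero pooled variance with unequal
#'   means yields an infinite t with p = 0.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, df = 4
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(skill_test(0, length(x) + length(y) - 2, 1, 0, "Two-sample t (pooled)"))
    return(skill_test(sign(mean(x) - mean(y)) * Inf,
                      length(x) + length(y) - 2, 0, mean(x) - mean(y),
                      "Two-sample t (pooled; degenerate variance)"))
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  skill_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
             mean(x) - mean(y),
             if (pooled) "Two-sample t (pooled)" else "Welch two-sample t")
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon two-sample test with mid-ranks for ties: exact
#' p-value when both samples are small and untied, otherwise the normal
#' approximation with continuity correction (the `stats::wilcox.test`
#' conventions). The reported statistic W counts pairs `(i, j)` with
#' `x[i] > y[j]` (ties as 1/2), i.e. the rank sum of `x` minus its minimum.
#'
#' @param x,y Numeric samples (n >= 1 each).
#' @return A `"skill_test"` with `statistic` (W) and `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  skill_test(unname(ht$statistic), NA_real_, min(ht$p.value, 1),
             method = "Wilcoxon rank-sum")
}

#' Kolmogorov-Smirnov normality check (Lilliefors)
#'
#' Tests a sample against a normal distribution with estimated mean and SD;
#' the p-value uses the Lilliefors correction for the estimation. When
#' p < 0.05 the result flags that rank-based modeling is recommended.
#'
#' @param x Numeric sample (n >= 4, non-constant).
#' @return A `"skill_test"` with `statistic` (D), `p_value`, and an extra
#'   element `recommend_rank_based`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 4) stop("Lilliefors test needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) sample: normality is undefined", call. = FALSE)
  ht <- nortest::lillie.test(x)
  out <- skill_test(unname(ht$statistic), NA_real_, ht$p.value,
                    method = "Lilliefors (Kolmogorov-Smirnov) normality")
  out$recommend_rank_based <- ht$p.value < 0.05
  out
}

#' Sample size for a two-group comparison
#'
#' Smallest per-group n such that a two-sided pooled t-test at level `alpha`
#' attains the requested power for a true mean difference `mean_diff` with
#' common standard deviation `sd` (noncentral-t solution via
#' `stats::power.t.test`).
#'
#' @param mean_diff True difference in means (non-zero).
#' @param sd Common standard deviation (> 0).
#' @param power Target power in (0, 1) (default 0.8).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Integer n per group.
#' @examples
#' sample_size_two_groups(1, 1) # 17 per group
#' @export
sample_size_two_groups <- function(mean_diff, sd, power = 0.8, alpha = 0.05) {
  stopifnot(sd > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  if (mean_diff == 0)
    stop("zero effect size: required sample size is unbounded", call. = FALSE)
  n <- stats::power.t.test(delta = abs(mean_diff), sd = sd, power = power,
                           sig.level = alpha, type = "two.sample",
                           alternative = "two.sided")$n
  as.integer(ceiling(n - 1e-9))
}

#' Group summaries of a participant-table column
#'
#' Arithmetic mean and sample SD of a numeric column, by group (or for one
#' group). Single-row groups return `NA` SD with a warning.
#'
#' @param records A participant table (e.g. [load_table1()]).
#' @param field Column name.
#' @param group Optional single group level to restrict to.
#' @return A tibble with `group`, `n`, `mean`, `sd`.
#' @examples
#' table1_summary(load_table1(), "iet_hrmax")
#' @export
table1_summary <- function(records, field, group = NULL) {
  if (!field %in% names(records)) stop("unknown field: ", field, call. = FALSE)
  if (!is.numeric(records[[field]])) stop("field is not numeric: ", field, call. = FALSE)
  if (!is.null(group)) records <- records[records$group %in% group, , drop = FALSE]
  sp <- split(records[[field]], records$group)
  out <- tibble::tibble(
    group = names(sp),
    n = unname(vapply(sp, length, 0L)),
    mean = unname(vapply(sp, mean, 0)),
    sd = unname(vapply(sp, function(v)
      if (length(v) < 2) NA_real_ else stats::sd(v), 0))
  )
  if (any(out$n < 2)) warning("group with a single row: SD undefined")
  out
}
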