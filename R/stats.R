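# Statistical comparisons across conditions and time points: two-sided
# Mann-Whitney U (the primary test for all metric populations), the pooled
# two-sample t test used for M1-vs-M2 comparisons, and the star labels of
# the significance captions.

#' Two-sided Mann-Whitney U test
#'
#' Computes the U statistic of the first sample and a two-sided p-value:
#' exact (distribution of U under the null, via [stats::wilcox.test()])
#' when the pooled sample size is at most 16 and there are no ties, and the
#' normal approximation with tie-corrected variance and continuity
#' correction otherwise. The method actually used is recorded.
#'
#' @param x,y numeric samples (each nonempty).
#' @return list with `u` (U statistic of `x`), `p` (two-sided),
#'   `method` (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be nonempty")
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # complete ties: zero rank variance, no evidence
  list(u = unname(wt$statistic), p = min(1, p),
       method = if (exact) "exact" else "normal_approx",
       n_x = length(x), n_y = length(y))
}

#' Two-sided pooled-variance Student's t test
#'
#' Used to compare the per-FOV M1 and M2 colocalization populations. When
#' the pooled variance is zero the test degenerates: equal means give
#' `p = 1`, unequal means give `p = 0` with the `degenerate` flag set.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return list with `t`, `p` (two-sided), `df`, `degenerate`.
#' @export
students_t_two_sided <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 values")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    same <- mean(x) == mean(y)
    return(list(t = if (same) 0 else Inf, p = if (same) 1 else 0,
                df = df, degenerate = TRUE))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df,
       degenerate = FALSE)
}

#' Significance star label for a p-value
#'
#' The caption mapping: `ns` if p > 0.05; `*` if 0.01 < p <= 0.05; `**` if
#' 0.001 < p <= 0.01; `***` if 0.0001 < p <= 0.001; `****` if p <= 0.0001.
#' Boundaries are inclusive on the more significant side (p = 0.05 earns
#' `*`).
#'
#' @param p p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  if (p > 0.05) "ns"
  else if (p > 0.01) "*"
  else if (p > 0.001) "**"
  else if (p > 0.0001) "***"
  else "****"
}

#' Time-course statistics over a long-format metrics table
#'
#' For every metric: (i) control-vs-TIS Mann-Whitney tests at each time
#' point, and (ii) within-group tests of each later time point against the
#' baseline time point. Groups with fewer than `min_n` values are skipped
#' with a reason. Also returns per-group mean and SD summaries.
#'
#' @param table long-format data frame with columns `condition`,
#'   `time_point`, `metric`, `value` (extra key columns are ignored).
#' @param baseline baseline time point label (default `"0h"`).
#' @param min_n minimum group size for a test (default 3).
#' @param time_levels optional ordering of time points; defaults to their
#'   order of appearance.
#' @return list with `tests` (data frame: metric, comparison, group_a,
#'   group_b, time_point, u, p, stars, n_a, n_b, skipped, reason) and
#'   `summary` (metric x condition x time_point mean/sd/n).
#' @export
timecourse_report <- function(table, baseline = "0h", min_n = 3L,
                              time_levels = NULL) {
  need <- c("condition", "time_point", "metric", "value")
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("metrics table is empty")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (length(unique(table$condition)) < 2L &&
      length(unique(table$time_point)) < 2L)
    stop("need at least two groups (conditions or time points) to compare")
  if (is.null(time_levels)) time_levels <- unique(table$time_point)
  table <- table[is.finite(table$value), , drop = FALSE]

  rows <- list()
  add_test <- function(metric, comparison, ga, gb, tp, va, vb) {
    if (length(va) < min_n || length(vb) < min_n) {
      rows[[length(rows) + 1L]] <<- data.frame(
        metric = metric, comparison = comparison, group_a = ga, group_b = gb,
        time_point = tp, u = NA_real_, p = NA_real_, stars = NA_character_,
        n_a = length(va), n_b = length(vb), skipped = TRUE,
        reason = sprintf("group size below %d", min_n),
        stringsAsFactors = FALSE)
      return(invisible())
    }
    mw <- mann_whitney_u(va, vb)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, comparison = comparison, group_a = ga, group_b = gb,
      time_point = tp, u = mw$u, p = mw$p, stars = significance_stars(mw$p),
      n_a = mw$n_x, n_b = mw$n_y, skipped = FALSE, reason = "",
      stringsAsFactors = FALSE)
  }

  for (metric in unique(table$metric)) {
    mt <- table[table$metric == metric, , drop = FALSE]
    # control vs TIS at each time point
    for (tp in intersect(time_levels, unique(mt$time_point))) {
      va <- mt$value[mt$condition == "control" & mt$time_point == tp]
      vb <- mt$value[mt$condition == "TIS" & mt$time_point == tp]
      if (length(va) && length(vb))
        add_test(metric, "control_vs_TIS", "control", "TIS", tp, va, vb)
    }
    # within-group: baseline vs each later time point
    for (cond in unique(mt$condition)) {
      vb0 <- mt$value[mt$condition == cond & mt$time_point == baseline]
      if (!length(vb0)) next
      for (tp in setdiff(intersect(time_levels, unique(mt$time_point)), baseline)) {
        va <- mt$value[mt$condition == cond & mt$time_point == tp]
        if (length(va))
          add_test(metric, paste0("within_", cond, "_vs_", baseline),
                   cond, cond, tp, vb0, va)
      }
    }
  }
  tests <- do.call(rbind, rows)

  agg <- stats::aggregate(value ~ metric + condition + time_point, data = table,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  summary <- cbind(agg[, c("metric", "condition", "time_point")],
                   as.data.frame(agg$value))
  list(tests = tests, summary = summary)
}
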