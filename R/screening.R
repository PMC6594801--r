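# Cohort screening: tea-frequency composite score, group assignment, and
# the classical demographic comparison statistics.

tea_scale_fields <- c(
  "green_45", "oolong_45", "black_45",
  "green_now", "oolong_now", "black_now"
)

check_scale <- function(value, field) {
  if (is.null(value) || length(value) != 1L || is.na(value)) {
    stop_teanet("frequency scale '", field, "' is missing")
  }
  if (!is.numeric(value) || value != round(value) || value < 1 || value > 6) {
    stop_teanet("frequency scale '", field, "' must be an integer in [1, 6], got ", value)
  }
  as.numeric(value)
}

#' Tea-drinking frequency composite score
#'
#' Drinking frequency of green, oolong and black tea is recorded on a 1-6
#' categorical scale (1 = never/rarely ... 6 = three or more times a day),
#' once recalled for age around 45 and once for the present. The composite
#' score sums the three tea scales within each age and averages the two
#' sums. Coffee frequency, though collected, never enters the score. The
#' attainable range is \[3, 18\].
#'
#' @param record a list or one-row data frame with fields `green_45`,
#'   `oolong_45`, `black_45`, `green_now`, `oolong_now`, `black_now`
#'   (integers in 1..6). Coffee fields may be present and are ignored.
#' @return the composite score (numeric scalar).
#' @examples
#' composite_tea_score(list(green_45 = 1, oolong_45 = 1, black_45 = 1,
#'                          green_now = 1, oolong_now = 1, black_now = 1)) # 3
#' @export
composite_tea_score <- function(record) {
  record <- as.list(record)
  vals <- vapply(tea_scale_fields, function(f) check_scale(record[[f]], f),
                 numeric(1))
  sum_45 <- sum(vals[c("green_45", "oolong_45", "black_45")])
  sum_now <- sum(vals[c("green_now", "oolong_now", "black_now")])
  (sum_45 + sum_now) / 2
}

#' Assign screening group from a composite tea score
#'
#' Scores of 8 or more define the tea-drinking group (`"T"`); the minimum
#' score of exactly 3 (never/rarely drank any kind of tea at either age)
#' defines the non-tea-drinking group (`"NT"`); everything in between is
#' `"excluded"` from analysis.
#'
#' @param score composite score from [composite_tea_score()].
#' @return `"T"`, `"NT"` or `"excluded"`.
#' @export
assign_group <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score)) {
    stop_teanet("score must be a finite numeric scalar")
  }
  if (score < 3) stop_teanet("score ", score, " is below the attainable minimum of 3")
  if (score >= 8) "T" else if (score == 3) "NT" else "excluded"
}

#' Pooled-variance two-sample t statistic from summary statistics
#'
#' Student's t with pooled variance and `df = n_a + n_b - 2`; the sign
#' convention is (a - b).
#'
#' @param mean_a,sd_a,n_a summary statistics of group a.
#' @param mean_b,sd_b,n_b summary statistics of group b.
#' @return list with elements `t` and `df`.
#' @export
two_sample_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop_teanet("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop_teanet("standard deviations must be >= 0")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- if (se == 0) {
    if (mean_a == mean_b) 0 else stop_teanet("zero pooled variance with unequal means")
  } else {
    (mean_a - mean_b) / se
  }
  list(t = t, df = df)
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction):
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = category.
#' @return list with elements `chi2` and `df`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_teanet("cell counts must be nonnegative integers")
  }
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop_teanet("chi-square undefined: zero marginal total")
  chi2 <- n * (a * d - b * c)^2 / prod(marg)
  list(chi2 = chi2, df = 1L)
}

#' Screen a cohort table
#'
#' Computes the tea composite score and group label for every subject and
#' returns the table with `tea_score` and `group` columns appended.
#'
#' @param cohort data frame with one row per subject containing the six tea
#'   frequency columns (see [composite_tea_score()]); other columns pass
#'   through untouched.
#' @return the cohort with `tea_score` and `group` columns.
#' @export
screen_cohort <- function(cohort) {
  missing_cols <- setdiff(tea_scale_fields, names(cohort))
  if (length(missing_cols)) {
    stop_teanet("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  cohort$tea_score <- vapply(seq_len(nrow(cohort)), function(i) {
    composite_tea_score(cohort[i, tea_scale_fields, drop = FALSE])
  }, numeric(1))
  cohort$group <- vapply(cohort$tea_score, assign_group, character(1))
  cohort
}

#' Demographic group-comparison report
#'
#' Classical statistics comparing the tea (`T`) and non-tea (`NT`) groups:
#' pooled two-sample t for continuous columns, uncorrected Pearson
#' chi-square for binary columns.
#'
#' @param cohort screened cohort (must have a `group` column).
#' @param continuous names of numeric columns to compare by t-test.
#' @param binary names of two-level columns to compare by chi-square.
#' @return data frame with one row per variable: `variable`, `statistic`
#'   (`"t"` or `"chi2"`), `value`, `df`.
#' @export
demographic_table <- function(cohort,
                              continuous = c("age", "education"),
                              binary = c("sex", "handedness")) {
  t_grp <- cohort$group == "T"
  nt_grp <- cohort$group == "NT"
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]][t_grp]; y <- cohort[[v]][nt_grp]
    r <- two_sample_t_summary(mean(x), stats::sd(x), length(x),
                              mean(y), stats::sd(y), length(y))
    rows[[v]] <- data.frame(variable = v, statistic = "t",
                            value = r$t, df = r$df)
  }
  for (v in binary) {
    lev <- sort(unique(as.character(cohort[[v]])))
    if (length(lev) > 2) stop_teanet("column '", v, "' has more than two levels")
    if (length(lev) < 2) {
      # degenerate one-level column: statistic undefined, report NA
      rows[[v]] <- data.frame(variable = v, statistic = "chi2",
                              value = NA_real_, df = 1L)
      next
    }
    x1 <- sum(cohort[[v]][t_grp] == lev[1]); x2 <- sum(t_grp) - x1
    y1 <- sum(cohort[[v]][nt_grp] == lev[1]); y2 <- sum(nt_grp) - y1
    r <- chi_square_2x2(x1, x2, y1, y2)
    rows[[v]] <- data.frame(variable = v, statistic = "chi2",
                            value = r$chi2, df = r$df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
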