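# Descriptive cohort summaries and carrier vs non-carrier comparisons.
# Categorical variables use the exact test (the in-package 2x2 Fisher;
# stats::fisher.test for r x 2 tables with more than two levels);
# continuous variables use Welch's unequal-variance two-sample test.

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

PATIENT_CONT_VARS <- c("age", "age_menarche")

#' Per-group descriptive summary of a patient table
#'
#' @param patients Data frame with a `group` column and any mix of
#'   numeric and categorical columns (see [generate_cohort()] for the
#'   schema the synthetic generator emits).
#' @param variables Which columns to summarize (default: all except
#'   `group` and `id`).
#' @return A list with `n` (named group sizes), `continuous` (variable,
#'   group, n, mean, sd, min, max; groups of size one report sd 0 with
#'   `sd_undefined = TRUE`) and `categorical` (variable, level, group,
#'   n, pct with percentages rounded half-up to integers). Empty groups
#'   are omitted with a warning.
#' @export
summarize_cohort <- function(patients, variables = NULL) {
  stopifnot("group" %in% names(patients))
  if (!nrow(patients)) stop("empty patient set")
  if (is.null(variables)) variables <- setdiff(names(patients), c("group", "id"))
  groups <- unique(patients$group)
  empty <- setdiff(unique(patients$group), groups)
  cont <- list(); cate <- list()
  for (v in variables) {
    col <- patients[[v]]
    if (is.numeric(col)) {
      for (g in groups) {
        x <- col[patients$group == g]
        x <- x[!is.na(x)]
        if (!length(x)) {
          warning("no data for ", v, " in group ", g)
          next
        }
        cont[[length(cont) + 1L]] <- data.frame(
          variable = v, group = g, n = length(x),
          mean = mean(x),
          sd = if (length(x) > 1L) stats::sd(x) else 0,
          sd_undefined = length(x) == 1L,
          min = min(x), max = max(x), stringsAsFactors = FALSE)
      }
    } else {
      col <- as.character(col)
      for (g in groups) {
        x <- col[patients$group == g]
        x <- x[!is.na(x)]
        if (!length(x)) next
        tab <- table(x)
        cate[[length(cate) + 1L]] <- data.frame(
          variable = v, level = names(tab), group = g,
          n = as.integer(tab),
          pct = round_half_up(100 * as.integer(tab) / length(x)),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(n = table(patients$group),
       continuous = do.call(rbind, cont),
       categorical = do.call(rbind, cate))
}

#' Exact test on stratified counts
#'
#' Helper used by [compare_by_carrier()] and directly testable against
#' printed contingency tables: `k_pos`/`n_pos` vs `k_neg`/`n_neg` for a
#' binary variable, or level-count vectors for an r x 2 table.
#'
#' @param pos,neg Integer vectors of per-level counts for the two
#'   strata (length 2 for a binary variable).
#' @return Two-sided exact p-value. Binary tables go through
#'   [fisher_exact2()]; larger tables through [stats::fisher.test()].
#' @export
#' @examples
#' compare_counts(c(4, 10), c(6, 96))   # 29% vs 6% overweight
compare_counts <- function(pos, neg) {
  stopifnot(length(pos) == length(neg), length(pos) >= 2L)
  if (sum(pos) == 0L || sum(neg) == 0L) stop("each stratum needs at least one observation")
  keep <- pos + neg > 0L
  pos <- pos[keep]; neg <- neg[keep]
  if (length(pos) < 2L) return(1)  # degenerate: all observations share one level
  if (length(pos) == 2L) {
    fisher_exact2(pos[1], sum(pos), neg[1], sum(neg))$p_value
  } else {
    stats::fisher.test(cbind(pos, neg))$p.value
  }
}

#' Compare a variable between carriers and non-carriers
#'
#' @param patients Data frame with a logical `carrier` column.
#' @param variable Column name to compare.
#' @param group Optional value of `patients$group` to restrict to (the
#'   published comparisons stratify by cancer type).
#' @return A list with `variable`, per-stratum summaries and
#'   `p_value`: Welch's t-test for numeric variables, the exact test of
#'   [compare_counts()] for categorical ones (per-stratum proportions
#'   reported as integers, display style of the source tables).
#'   Degenerate tables (a single observed level) give p = 1.
#' @export
compare_by_carrier <- function(patients, variable, group = NULL) {
  stopifnot(all(c("carrier", variable) %in% names(patients)))
  if (!is.null(group)) patients <- patients[patients$group %in% group, , drop = FALSE]
  pos <- patients[patients$carrier, , drop = FALSE]
  neg <- patients[!patients$carrier, , drop = FALSE]
  if (!nrow(pos) || !nrow(neg)) stop("need at least one patient per stratum")
  col_pos <- pos[[variable]]; col_neg <- neg[[variable]]
  if (is.numeric(col_pos)) {
    if (length(unique(c(col_pos, col_neg))) == 1L) {
      p <- 1
    } else {
      p <- stats::t.test(col_pos, col_neg)$p.value
    }
    list(variable = variable, type = "continuous",
         mean_positive = mean(col_pos), sd_positive = stats::sd(col_pos),
         mean_negative = mean(col_neg), sd_negative = stats::sd(col_neg),
         p_value = p)
  } else {
    col_pos <- as.character(col_pos); col_neg <- as.character(col_neg)
    levels <- sort(unique(c(col_pos, col_neg)))
    cpos <- as.integer(table(factor(col_pos, levels = levels)))
    cneg <- as.integer(table(factor(col_neg, levels = levels)))
    p <- if (length(levels) < 2L) 1 else compare_counts(cpos, cneg)
    list(variable = variable, type = "categorical", levels = levels,
         counts_positive = cpos, counts_negative = cneg,
         pct_positive = round_half_up(100 * cpos / sum(cpos)),
         pct_negative = round_half_up(100 * cneg / sum(cneg)),
         p_value = p)
  }
}
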