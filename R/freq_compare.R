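# Two-sided Fisher exact comparison of carrier counts between a cohort
# and reference populations, and cohort carrier-frequency computation.
#
# The two-sided p-value is the classic construction: the sum of the
# hypergeometric point probabilities (over all 2x2 tables with the
# observed margins) that do not exceed the observed table's probability,
# with a 1 + 1e-7 relative slack absorbing floating-point ties. All
# probabilities are computed in log space via lchoose() so allele
# denominators in the millions are exact.

fisher2_one <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  N <- n1 + n2
  support <- max(0L, K - n2):min(K, n1)
  logp <- lchoose(n1, support) + lchoose(n2, K - support) - lchoose(N, K)
  obs <- logp[support == k1]
  p <- sum(exp(logp[logp <= obs + log1p(1e-7)]))
  min(max(p, exp(obs)), 1)
}

#' Two-sided Fisher exact test on two carrier counts
#'
#' Compares `k1` carriers out of `n1` against `k2` out of `n2`
#' (vectorized; arguments recycle).
#'
#' @param k1,n1,k2,n2 Non-negative integer counts, `0 <= k <= n`,
#'   `n >= 1`.
#' @return A data frame with the counts, `prop1`, `prop2`, `odds_ratio`
#'   (unconditional cross-product ratio; `Inf` when the denominator is
#'   zero, `NaN` for 0/0) and `p_value` in (0, 1].
#' @export
#' @examples
#' fisher_exact2(1, 140, 1, 78578)
fisher_exact2 <- function(k1, n1, k2, n2) {
  n <- max(length(k1), length(n1), length(k2), length(n2))
  k1 <- rep_len(as.numeric(k1), n); n1 <- rep_len(as.numeric(n1), n)
  k2 <- rep_len(as.numeric(k2), n); n2 <- rep_len(as.numeric(n2), n)
  if (any(n1 < 1) || any(n2 < 1)) stop("denominators must be >= 1")
  if (any(k1 < 0) || any(k2 < 0) || any(k1 > n1) || any(k2 > n2)) {
    stop("counts must satisfy 0 <= k <= n")
  }
  p <- vapply(seq_len(n), function(i) fisher2_one(k1[i], n1[i], k2[i], n2[i]),
              numeric(1))
  num <- k1 * (n2 - k2)
  den <- (n1 - k1) * k2
  or <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  data.frame(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
             prop1 = k1 / n1, prop2 = k2 / n2,
             odds_ratio = or, p_value = p)
}

format_p <- function(p) ifelse(p < 0.0001, "<0.0001", sprintf("%.4f", p))

#' Read a reference-count table from TSV
#'
#' Columns: `variant_key`, `source_label`, `k2`, `n2`, `kind`
#' (`"cohort"` for published case series, `"database"` for allele counts
#' from population databases such as gnomAD/dbSNP).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those columns, counts as integers.
#' @export
read_reference_counts <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("variant_key", "source_label", "k2", "n2", "kind")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("reference file missing column(s): ",
                            paste(missing, collapse = ", "))
  raw$k2 <- as.integer(raw$k2)
  raw$n2 <- as.integer(raw$n2)
  if (!all(raw$kind %in% c("cohort", "database"))) {
    stop("kind must be 'cohort' or 'database'")
  }
  raw
}

#' Compare cohort carrier counts against reference populations
#'
#' One comparison per reference row: the cohort side uses the variant's
#' total carriers over the total cohort size (patients), the reference
#' side the counts as tabulated by their source (cohort carriers, or
#' database allele counts over allele numbers -- the unit mismatch is
#' deliberate and annotated by the `kind` column).
#'
#' @param vt A [variant_table()].
#' @param references Data frame from [read_reference_counts()].
#' @return A data frame with one row per matched (variant, reference)
#'   pair: key, source, kind, counts, percent frequencies, odds ratio,
#'   `p_value` and fixed-format `p_display` (4 decimals, `<0.0001`
#'   below). Reference rows whose key is absent from the table are
#'   skipped with a warning.
#' @export
#' @examples
#' vt <- read_variant_table(brca2_example("variants"))
#' refs <- read_reference_counts(brca2_example("references"))
#' head(compare_frequencies(vt, refs))
compare_frequencies <- function(vt, references) {
  stopifnot(inherits(vt, "variant_table"))
  rec <- vt$records
  idx <- match(references$variant_key, rec$key)
  if (anyNA(idx)) {
    warning("skipping reference row(s) with unmatched variant key: ",
            paste(unique(references$variant_key[is.na(idx)]), collapse = ", "))
    references <- references[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (!nrow(references)) {
    return(data.frame(key = character(0), source_label = character(0),
                      kind = character(0), k1 = integer(0), n1 = integer(0),
                      k2 = integer(0), n2 = integer(0), freq1_pct = numeric(0),
                      freq2_pct = numeric(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_display = character(0),
                      stringsAsFactors = FALSE))
  }
  k1 <- rec$carriers_bc[idx] + rec$carriers_oc[idx]
  n1 <- vt$cohort_sizes$total
  ft <- fisher_exact2(k1, n1, references$k2, references$n2)
  data.frame(
    key = references$variant_key,
    source_label = references$source_label,
    kind = references$kind,
    k1 = as.integer(k1), n1 = as.integer(n1),
    k2 = references$k2, n2 = references$n2,
    freq1_pct = round(100 * ft$prop1, 2),
    freq2_pct = round(100 * ft$prop2, 6),
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value,
    p_display = format_p(ft$p_value),
    stringsAsFactors = FALSE
  )
}

#' Cohort carrier frequency
#'
#' Proportion of patients in a group carrying at least one catalogued
#' variant: the sum of the group's carrier counts over the group size.
#'
#' @param vt A [variant_table()].
#' @param group `"all"` (denominator = total cohort), `"BC"` or `"OC"`.
#' @return A list with `numerator`, `denominator`, `proportion` and
#'   `percent` (rounded to 2 decimals).
#' @export
#' @examples
#' carrier_frequency(read_variant_table(brca2_example("variants")), "all")
carrier_frequency <- function(vt, group = c("all", "BC", "OC")) {
  stopifnot(inherits(vt, "variant_table"))
  group <- match.arg(group)
  num <- switch(group,
                all = sum(vt$records$carriers_bc) + sum(vt$records$carriers_oc),
                BC = sum(vt$records$carriers_bc),
                OC = sum(vt$records$carriers_oc))
  den <- switch(group,
                all = vt$cohort_sizes$total,
                BC = vt$cohort_sizes$bc,
                OC = vt$cohort_sizes$oc)
  if (den == 0) stop("zero denominator for group ", group)
  list(numerator = as.integer(num), denominator = as.integer(den),
       proportion = num / den, percent = round(100 * num / den, 2))
}
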