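# In-silico predictor scores (SIFT, PolyPhen-2) supplied as data and
# turned into categorical calls at fixed cutoffs. SIFT <= cutoff is
# "deleterious" (default 0.05); PolyPhen >= cutoff is "damaging"
# (default 0.85). Scores exist only for missense variants; absent scores
# give "unknown" calls that contribute no rubric evidence.

#' Read a predictor-score table from TSV
#'
#' Columns: `variant_key`, `sift_score`, `polyphen_score`; empty cells
#' mean "no score". Keys not present in a variant table are retained for
#' a later join.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `key`, `sift_score`, `polyphen_score`
#'   (numeric, `NA` when absent).
#' @export
#' @examples
#' read_predictions(brca2_example("predictions"))
read_predictions <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("variant_key", "sift_score", "polyphen_score")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("predictions file missing column(s): ",
                            paste(missing, collapse = ", "))
  to_num <- function(x, label) {
    v <- suppressWarnings(as.numeric(ifelse(trimws(x) == "", NA, x)))
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop(label, " score outside [0,1] at row ", paste(bad, collapse = ", "))
    }
    nonnum <- which(trimws(x) != "" & is.na(v))
    if (length(nonnum)) {
      stop("non-numeric ", label, " score at row ", paste(nonnum, collapse = ", "))
    }
    v
  }
  data.frame(key = raw$variant_key,
             sift_score = to_num(raw$sift_score, "SIFT"),
             polyphen_score = to_num(raw$polyphen_score, "PolyPhen"),
             stringsAsFactors = FALSE)
}

#' Categorical calls at the score cutoffs
#'
#' @param scores Data frame with columns `sift_score` and
#'   `polyphen_score` (and optionally `key`), as from
#'   [read_predictions()].
#' @param sift_cutoff SIFT scores at or below this value are called
#'   deleterious (default 0.05, boundary inclusive).
#' @param polyphen_cutoff PolyPhen scores at or above this value are
#'   called damaging (default 0.85, boundary inclusive).
#' @return The input with added columns `sift_call`
#'   (`deleterious`/`tolerated`/`unknown`), `polyphen_call`
#'   (`damaging`/`not_damaging`/`unknown`), `concordant` (both calls
#'   adverse) and `single_evidence` (exactly one call adverse).
#' @export
#' @examples
#' classify_predictions(data.frame(sift_score = 0, polyphen_score = 0.936))
classify_predictions <- function(scores, sift_cutoff = 0.05, polyphen_cutoff = 0.85) {
  stopifnot(sift_cutoff >= 0, sift_cutoff <= 1,
            polyphen_cutoff >= 0, polyphen_cutoff <= 1)
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!ok(scores$sift_score) || !ok(scores$polyphen_score)) {
    stop("scores must lie in [0,1]")
  }
  sift_call <- ifelse(is.na(scores$sift_score), "unknown",
                      ifelse(scores$sift_score <= sift_cutoff, "deleterious", "tolerated"))
  polyphen_call <- ifelse(is.na(scores$polyphen_score), "unknown",
                          ifelse(scores$polyphen_score >= polyphen_cutoff,
                                 "damaging", "not_damaging"))
  adverse <- (sift_call == "deleterious") + (polyphen_call == "damaging")
  scores$sift_call <- sift_call
  scores$polyphen_call <- polyphen_call
  scores$concordant <- adverse == 2L
  scores$single_evidence <- adverse == 1L
  scores
}
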