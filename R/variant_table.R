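# Variant catalogue: one row per distinct variant, carrier counts per
# cancer group, clinical and ClinVar labels. The record key is the rsID
# when present, otherwise the cDNA HGVS string.

VARIANT_COLUMNS <- c("hgvs_cdna", "hgvs_protein", "rsid", "carriers_bc",
                     "carriers_oc", "clinical_classification",
                     "clinvar_aggregate", "clinvar_review")

#' Construct a variant table
#'
#' @param records Data frame with the columns documented in
#'   [read_variant_table()].
#' @param cohort_sizes Named list or vector with elements `bc`, `oc`,
#'   `both` (patients with both diagnoses). The total cohort size is
#'   their sum.
#' @return An object of class `variant_table`: a list with `records`
#'   (the input plus parsed protein-change columns `key`, `ref`,
#'   `position`, `alt`, `consequence`) and `cohort_sizes` (with `total`
#'   added).
#' @export
variant_table <- function(records, cohort_sizes = default_cohort_sizes()) {
  cs <- as.list(cohort_sizes)
  stopifnot(all(c("bc", "oc", "both") %in% names(cs)))
  cs <- lapply(cs[c("bc", "oc", "both")], as.integer)
  cs$total <- cs$bc + cs$oc + cs$both
  missing <- setdiff(VARIANT_COLUMNS, names(records))
  if (length(missing)) {
    stop("variant table missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  records$rsid <- ifelse(is.na(records$rsid) | records$rsid == "", NA_character_,
                         records$rsid)
  records$carriers_bc <- as.integer(records$carriers_bc)
  records$carriers_oc <- as.integer(records$carriers_oc)
  if (nrow(records)) {
    if (any(is.na(records$carriers_bc)) || any(is.na(records$carriers_oc)) ||
        any(records$carriers_bc < 0L) || any(records$carriers_oc < 0L)) {
      stop("carrier counts must be non-negative integers")
    }
    low <- which(records$carriers_bc + records$carriers_oc < 1L)
    if (length(low)) {
      stop("catalogued variants must have at least one carrier (row ",
           paste(low, collapse = ", "), ")")
    }
    pc <- tryCatch(parse_protein_hgvs(records$hgvs_protein), error = function(e) e)
    if (inherits(pc, "error")) stop("protein HGVS parse failure: ", conditionMessage(pc))
    records$ref <- pc$ref
    records$position <- pc$position
    records$alt <- pc$alt
    records$consequence <- pc$consequence
    records$key <- ifelse(is.na(records$rsid), records$hgvs_cdna, records$rsid)
    dup <- records$key[duplicated(records$key)]
    if (length(dup)) stop("duplicate variant key(s): ", paste(unique(dup), collapse = ", "))
  } else {
    records$ref <- character(0)
    records$position <- integer(0)
    records$alt <- character(0)
    records$consequence <- character(0)
    records$key <- character(0)
  }
  structure(list(records = records, cohort_sizes = cs), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x$records), "variant(s),",
      sum(x$records$carriers_bc + x$records$carriers_oc), "carrier(s);",
      "cohort", x$cohort_sizes$total,
      sprintf("(BC %d / OC %d / BC+OC %d)\n",
              x$cohort_sizes$bc, x$cohort_sizes$oc, x$cohort_sizes$both))
  invisible(x)
}

#' Default cohort group sizes
#'
#' Reads the packaged cohort-size config (116 breast-cancer, 19
#' ovarian-cancer and 5 combined-diagnosis patients, 140 in total).
#'
#' @param path Optional path to a JSON file `{"bc":int,"oc":int,"both":int}`.
#' @return Named list with `bc`, `oc`, `both`.
#' @export
default_cohort_sizes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_sizes.json",
                        package = "brca2triage", mustWork = TRUE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a variant catalogue from TSV
#'
#' The file must be tab-separated, UTF-8, with a header row containing
#' exactly the columns `hgvs_cdna`, `hgvs_protein`, `rsid` (empty
#' allowed), `carriers_bc`, `carriers_oc`, `clinical_classification`,
#' `clinvar_aggregate` (semicolon-separated ClinVar assertion labels)
#' and `clinvar_review`.
#'
#' @param path Path to the TSV file.
#' @param cohort_sizes See [variant_table()].
#' @return A `variant_table`.
#' @export
#' @examples
#' vt <- read_variant_table(brca2_example("variants"))
#' vt
read_variant_table <- function(path, cohort_sizes = default_cohort_sizes()) {
  records <- utils::read.delim(path, sep = "\t", header = TRUE,
                               colClasses = "character",
                               na.strings = NULL, fileEncoding = "UTF-8",
                               check.names = FALSE)
  variant_table(records, cohort_sizes)
}

#' Paths to the packaged BRCA2 example data
#'
#' Small plain-text fixtures transcribed from a published catalogue of 13
#' germline BRCA2 variants found in a 140-patient breast/ovarian cancer
#' cohort: the variant table, the SIFT/PolyPhen score table, the
#' reference-population count table, and the domain-annotation config.
#'
#' @param which One of `"variants"`, `"predictions"`, `"references"`,
#'   `"domains"`.
#' @return Path to the packaged file.
#' @export
brca2_example <- function(which = c("variants", "predictions", "references", "domains")) {
  which <- match.arg(which)
  file <- switch(which,
                 variants = "brca2_variants.tsv",
                 predictions = "brca2_predictions.tsv",
                 references = "brca2_reference_counts.tsv",
                 domains = "brca2_domains.json")
  system.file("extdata", file, package = "brca2triage", mustWork = TRUE)
}
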