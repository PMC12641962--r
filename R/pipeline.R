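# End-to-end orchestration: run every analysis stage on a set of input
# tables and write the report bundle (fixed float formatting so repeated
# runs on identical inputs are byte-identical).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

check_file <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  path
}

#' Run the full variant-prioritization pipeline
#'
#' Stages: variant-table load, domain assignment, predictor
#' classification, missense property report, prioritization,
#' reference-frequency comparison (if references given) and
#' carrier-stratified cohort statistics (if patients given). Writes one
#' TSV per stage plus a JSON summary to `out_dir` and returns the
#' results invisibly.
#'
#' @param variants Path to a variant TSV or a [variant_table()].
#' @param predictions Path to a predictions TSV or a data frame.
#' @param references Optional path/data frame of reference counts.
#' @param patients Optional path/data frame of patients (needs a
#'   logical or `"TRUE"`/`"FALSE"` `carrier` column).
#' @param domains Path to a domain config JSON or a domain set.
#' @param sift_cutoff,polyphen_cutoff Predictor cutoffs.
#' @param cohort_sizes Passed to [read_variant_table()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return (Invisibly) a list with `assignments`, `profiles`,
#'   `priorities`, `frequency_comparisons`, `cohort_comparisons` and
#'   `summary`.
#' @export
run_pipeline <- function(variants, predictions, references = NULL,
                         patients = NULL, domains = brca2_domains(),
                         sift_cutoff = 0.05, polyphen_cutoff = 0.85,
                         cohort_sizes = default_cohort_sizes(),
                         out_dir = NULL) {
  vt <- stage("variants", {
    if (inherits(variants, "variant_table")) variants
    else read_variant_table(check_file(variants), cohort_sizes)
  })
  doms <- stage("domains", {
    if (is.character(domains)) load_domain_config(check_file(domains)) else domains
  })
  assignments <- stage("domain_mapper", assign_domains(vt, doms))
  profiles <- stage("insilico", {
    preds <- if (is.character(predictions)) read_predictions(check_file(predictions)) else predictions
    classify_predictions(preds, sift_cutoff, polyphen_cutoff)
  })
  priorities <- stage("priority_rubric",
                      prioritize_variants(vt, doms, profiles,
                                          sift_cutoff = sift_cutoff,
                                          polyphen_cutoff = polyphen_cutoff))
  freq <- NULL
  if (!is.null(references)) {
    freq <- stage("freq_compare", {
      refs <- if (is.character(references)) read_reference_counts(check_file(references)) else references
      compare_frequencies(vt, refs)
    })
  }
  cohort <- NULL
  if (!is.null(patients)) {
    cohort <- stage("cohort_stats", {
      pts <- if (is.character(patients)) {
        utils::read.delim(check_file(patients), sep = "\t", stringsAsFactors = FALSE)
      } else patients
      pts$carrier <- as.logical(pts$carrier)
      vars <- setdiff(names(pts), c("id", "group", "carrier"))
      comps <- lapply(vars, function(v) {
        cmp <- compare_by_carrier(pts, v)
        data.frame(variable = v, type = cmp$type,
                   p_value = round(cmp$p_value, 4), stringsAsFactors = FALSE)
      })
      do.call(rbind, comps)
    })
  }
  cf_all <- carrier_frequency(vt, "all")
  cf_bc <- carrier_frequency(vt, "BC")
  cf_oc <- carrier_frequency(vt, "OC")
  by_priority <- table(priorities$priority)
  by_domain <- table(assignments$domain[assignments$category == "inside"])
  summary <- list(
    n_variants = nrow(vt$records),
    n_carriers = cf_all$numerator,
    carrier_pct_total = cf_all$percent,
    carrier_pct_bc = cf_bc$percent,
    carrier_pct_oc = cf_oc$percent,
    counts_by_priority = as.list(stats::setNames(as.integer(by_priority),
                                                 names(by_priority))),
    counts_by_domain = as.list(stats::setNames(as.integer(by_domain),
                                               names(by_domain)))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(assignments, file.path(out_dir, "domain_assignments.tsv"))
    prof_out <- profiles
    for (col in c("sift_score", "polyphen_score")) {
      prof_out[[col]] <- ifelse(is.na(prof_out[[col]]), "",
                                sprintf("%.4f", prof_out[[col]]))
    }
    write_tsv(prof_out, file.path(out_dir, "prediction_profiles.tsv"))
    pri_out <- priorities
    pri_out$priority <- as.character(pri_out$priority)
    for (col in c("sift_score", "polyphen_score")) {
      pri_out[[col]] <- ifelse(is.na(pri_out[[col]]), "",
                               sprintf("%.4f", pri_out[[col]]))
    }
    write_tsv(pri_out, file.path(out_dir, "priorities.tsv"))
    if (!is.null(freq)) {
      freq_out <- freq
      freq_out$p_value <- sprintf("%.4f", freq_out$p_value)
      freq_out$odds_ratio <- sprintf("%.4f", freq_out$odds_ratio)
      freq_out$freq1_pct <- sprintf("%.2f", freq_out$freq1_pct)
      freq_out$freq2_pct <- sprintf("%.6f", freq_out$freq2_pct)
      write_tsv(freq_out, file.path(out_dir, "frequency_comparisons.tsv"))
    }
    if (!is.null(cohort)) {
      cohort_out <- cohort
      cohort_out$p_value <- sprintf("%.4f", cohort_out$p_value)
      write_tsv(cohort_out, file.path(out_dir, "cohort_comparisons.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(variants = vt, assignments = assignments, profiles = profiles,
                 priorities = priorities, frequency_comparisons = freq,
                 cohort_comparisons = cohort, summary = summary))
}
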