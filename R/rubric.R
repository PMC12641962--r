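# Stepwise Low/Moderate/High prioritization of variants.
#
# Rules, in order:
#   1. truncating_rule      frameshift or stop-gained -> High, stop.
#   2. domain_escalation    missense inside a critical domain -> +1.
#   3. predictor_escalation concordant adverse calls (SIFT deleterious
#                           AND PolyPhen damaging) -> +1.
#   4. single_predictor_cap exactly one adverse call -> +1, and the
#                           final level is capped at Moderate.
#   5. clinvar_escalation   any ClinVar assertion Pathogenic / Likely
#                           pathogenic (including inside conflicting
#                           aggregates) -> +1.
#   6. high_cap             ranks above High are clamped to High.
# Levels are ranks 0 (Low), 1 (Moderate), 2 (High).

PRIORITY_LEVELS <- c("Low", "Moderate", "High")
RUBRIC_RULES <- c("truncating_rule", "domain_escalation", "predictor_escalation",
                  "single_predictor_cap", "clinvar_escalation", "high_cap")

#' ClinVar evidence for the rubric
#'
#' @param labels Character vector of assertion labels, or a single
#'   semicolon-separated string (the `clinvar_aggregate` column format).
#' @return A list with `labels` and `has_path_or_likely` (`TRUE` when
#'   any label is Pathogenic or Likely pathogenic, case-insensitive).
#' @export
#' @examples
#' clinvar_evidence("Uncertain significance;Likely pathogenic")
clinvar_evidence <- function(labels) {
  if (length(labels) == 1L && grepl(";", labels)) {
    labels <- strsplit(labels, ";", fixed = TRUE)[[1]]
  }
  labels <- trimws(labels)
  labels <- labels[labels != ""]
  hit <- tolower(labels) %in% c("pathogenic", "likely pathogenic")
  list(labels = labels, has_path_or_likely = any(hit))
}

#' Assign a priority level to one variant
#'
#' @param consequence `"missense"`, `"frameshift"` or `"stop_gained"`.
#' @param assignment One row of [assign_domains()] output (needs
#'   `category` and `critical`).
#' @param profile One row of [classify_predictions()] output (needs
#'   `sift_call` and `polyphen_call`).
#' @param clinvar Result of [clinvar_evidence()].
#' @return A list with `level` (factor over Low < Moderate < High),
#'   `rank` (0/1/2) and `ledger`, a six-row data frame (`rule`,
#'   `applied`, `note`) from which the level is reproducible (see
#'   [priority_from_ledger()]).
#' @export
assign_priority <- function(consequence, assignment, profile, clinvar) {
  if (is.null(assignment) || is.na(assignment$category[1])) {
    stop("missing domain assignment: the rubric requires all evidence channels")
  }
  if (is.null(profile) || is.na(profile$sift_call[1]) || is.na(profile$polyphen_call[1])) {
    stop("missing prediction profile: the rubric requires all evidence channels")
  }
  ledger <- data.frame(rule = RUBRIC_RULES, applied = FALSE,
                       note = "", stringsAsFactors = FALSE)
  note <- function(rule, applied, text) {
    ledger[ledger$rule == rule, c("applied", "note")] <<- list(applied, text)
  }
  truncating <- consequence %in% c("frameshift", "stop_gained")
  if (truncating) {
    note("truncating_rule", TRUE, paste0(consequence, ": directly High"))
    rank <- 2L
    for (r in setdiff(RUBRIC_RULES, "truncating_rule")) note(r, FALSE, "not reached (truncating)")
  } else {
    note("truncating_rule", FALSE, "missense")
    rank <- 0L
    dom_hit <- assignment$category[1] == "inside" && isTRUE(assignment$critical[1])
    if (dom_hit) rank <- rank + 1L
    note("domain_escalation", dom_hit,
         if (dom_hit) paste0("inside critical domain '", assignment$domain[1], "': +1")
         else paste0("category=", assignment$category[1],
                     if (!is.na(assignment$domain[1])) paste0(" (", assignment$domain[1], ")") else "",
                     ": no escalation"))
    adverse <- (profile$sift_call[1] == "deleterious") +
      (profile$polyphen_call[1] == "damaging")
    cap_moderate <- FALSE
    if (adverse == 2L) {
      rank <- rank + 1L
      note("predictor_escalation", TRUE, "SIFT deleterious and PolyPhen damaging: +1")
      note("single_predictor_cap", FALSE, "concordant, no cap")
    } else if (adverse == 1L) {
      rank <- rank + 1L
      cap_moderate <- TRUE
      note("predictor_escalation", FALSE, "only one adverse call")
      note("single_predictor_cap", TRUE, "single adverse predictor: +1, capped at Moderate")
    } else {
      note("predictor_escalation", FALSE, "no adverse calls")
      note("single_predictor_cap", FALSE, "no adverse calls")
    }
    cv <- isTRUE(clinvar$has_path_or_likely)
    if (cv) rank <- rank + 1L
    note("clinvar_escalation", cv,
         if (cv) "ClinVar pathogenic/likely pathogenic assertion: +1"
         else "no pathogenic/likely pathogenic assertion")
    if (cap_moderate) rank <- min(rank, 1L)
    clamped <- rank > 2L
    note("high_cap", clamped, if (clamped) "clamped to High" else "within range")
    rank <- min(rank, 2L)
  }
  list(level = factor(PRIORITY_LEVELS[rank + 1L], levels = PRIORITY_LEVELS, ordered = TRUE),
       rank = rank, ledger = ledger)
}

#' Recompute a priority level from its rule ledger
#'
#' Replays the six recorded rule applications; used as an audit that the
#' reported level is reproducible from the ledger alone.
#'
#' @param ledger Six-row data frame from [assign_priority()].
#' @return Rank 0/1/2.
#' @export
priority_from_ledger <- function(ledger) {
  applied <- stats::setNames(ledger$applied, ledger$rule)
  if (applied[["truncating_rule"]]) return(2L)
  rank <- sum(applied[c("domain_escalation", "predictor_escalation",
                        "single_predictor_cap", "clinvar_escalation")])
  if (applied[["single_predictor_cap"]]) rank <- min(rank, 1L)
  min(rank, 2L)
}

compact_ledger <- function(ledger) {
  paste(paste0(sub("_rule$|_escalation$|_cap$", "", ledger$rule), "=",
               as.integer(ledger$applied)), collapse = ";")
}

#' Prioritize every variant in a table
#'
#' Joins the variant catalogue with domain assignments and prediction
#' profiles on the variant key, applies the rubric, and returns a report
#' ordered High to Low, then by protein position. ClinVar evidence is
#' taken from the table's `clinvar_aggregate` column unless an explicit
#' map is supplied.
#'
#' @param vt A [variant_table()].
#' @param domains Domain set (default: packaged BRCA2 annotation).
#' @param predictions Data frame from [read_predictions()] (raw scores;
#'   calls are derived here) or from [classify_predictions()].
#' @param clinvar Optional named list mapping variant key to
#'   [clinvar_evidence()]; defaults to evidence parsed from the table.
#' @param sift_cutoff,polyphen_cutoff Passed to
#'   [classify_predictions()].
#' @param properties Residue property table used for the missense
#'   property summary column.
#' @return A data frame with one row per variant: identification
#'   columns, domain assignment, scores and calls, `property_summary`,
#'   `clinvar`, `priority` (ordered factor) and `ledger` (compact rule
#'   trace). Full ledgers are attached as attribute `ledgers` (named
#'   list).
#' @export
#' @examples
#' vt <- read_variant_table(brca2_example("variants"))
#' preds <- read_predictions(brca2_example("predictions"))
#' prioritize_variants(vt, predictions = preds)
prioritize_variants <- function(vt, domains = brca2_domains(), predictions,
                                clinvar = NULL, sift_cutoff = 0.05,
                                polyphen_cutoff = 0.85,
                                properties = residue_properties()) {
  stopifnot(inherits(vt, "variant_table"))
  rec <- vt$records
  if (!nrow(rec)) {
    out <- data.frame(key = character(0), hgvs_cdna = character(0),
                      protein_change = character(0), rsid = character(0),
                      position = integer(0), consequence = character(0),
                      domain = character(0), category = character(0),
                      sift_score = numeric(0), sift_call = character(0),
                      polyphen_score = numeric(0), polyphen_call = character(0),
                      property_summary = character(0), clinvar = character(0),
                      priority = factor(character(0), levels = PRIORITY_LEVELS, ordered = TRUE),
                      ledger = character(0), stringsAsFactors = FALSE)
    attr(out, "ledgers") <- list()
    return(out)
  }
  assignments <- assign_domains(vt, domains)
  if (!("sift_call" %in% names(predictions))) {
    predictions <- classify_predictions(predictions, sift_cutoff, polyphen_cutoff)
  }
  missing <- setdiff(rec$key, predictions$key)
  if (length(missing)) {
    stop("no prediction profile for variant key(s): ", paste(missing, collapse = ", "))
  }
  pidx <- match(rec$key, predictions$key)
  results <- vector("list", nrow(rec))
  ledgers <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    cv <- if (!is.null(clinvar)) clinvar[[rec$key[i]]] else clinvar_evidence(rec$clinvar_aggregate[i])
    if (is.null(cv)) stop("no ClinVar evidence for variant key: ", rec$key[i])
    res <- assign_priority(rec$consequence[i], assignments[i, ], predictions[pidx[i], ], cv)
    results[[i]] <- res
    ledgers[[i]] <- res$ledger
  }
  names(ledgers) <- rec$key
  prop <- rep(NA_character_, nrow(rec))
  mis <- rec$consequence == "missense" & !is.na(rec$alt)
  if (any(mis)) {
    prop[mis] <- delta_report(property_delta(rec$ref[mis], rec$alt[mis], properties))
  }
  out <- data.frame(
    key = rec$key,
    hgvs_cdna = rec$hgvs_cdna,
    protein_change = format_protein_hgvs(rec),
    rsid = rec$rsid,
    position = rec$position,
    consequence = rec$consequence,
    domain = assignments$domain,
    category = assignments$category,
    sift_score = predictions$sift_score[pidx],
    sift_call = predictions$sift_call[pidx],
    polyphen_score = predictions$polyphen_score[pidx],
    polyphen_call = predictions$polyphen_call[pidx],
    property_summary = prop,
    clinvar = rec$clinvar_aggregate,
    priority = factor(vapply(results, function(r) as.character(r$level), character(1)),
                      levels = PRIORITY_LEVELS, ordered = TRUE),
    ledger = vapply(results, function(r) compact_ledger(r$ledger), character(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-as.integer(out$priority), out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ledgers") <- ledgers
  out
}
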