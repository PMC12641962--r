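# Seeded synthetic data with the statistical structure the analysis
# assumes: a two-arm (plus small combined-diagnosis) cohort with group-
# specific carrier prevalence, age distributions and carrier-shifted
# categorical covariates; and a variant panel whose records exercise
# every pipeline stage (parseable nomenclature, score mixtures, ClinVar
# label sets).

truncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

split_rest <- function(total, weights) {
  if (sum(weights) == 0) rep(0, length(weights)) else total * weights / sum(weights)
}

default_cohort_covariates <- function() {
  # Carrier-stratum probabilities follow the published carrier vs
  # non-carrier tables; where a stratum is not published, the group
  # marginal is used for both strata, and residual probability mass is
  # split in proportion to the group's marginal level counts.
  bmi_bc_pos <- c(split_rest(1 - 4 / 14, c(88, 8))[1], 4 / 14, split_rest(1 - 4 / 14, c(88, 8))[2])
  bmi_bc_neg <- c(split_rest(1 - 6 / 102, c(88, 8))[1], 6 / 102, split_rest(1 - 6 / 102, c(88, 8))[2])
  bmi_oc_pos <- c(split_rest(0.5, c(11, 3))[1], 0.5, split_rest(0.5, c(11, 3))[2])
  bmi_oc_neg <- c(split_rest(1 - 2 / 15, c(11, 3))[1], 2 / 15, split_rest(1 - 2 / 15, c(11, 3))[2])
  chemo_bc_pos <- c(5 / 14, split_rest(1 - 5 / 14, c(34, 4, 6)))
  chemo_bc_neg <- c(70 / 102, split_rest(1 - 70 / 102, c(34, 4, 6)))
  chemo_oc_pos <- c(0.25, split_rest(0.75, c(8, 1, 2)))
  chemo_oc_neg <- c(0.2, split_rest(0.8, c(8, 1, 2)))
  list(
    bmi_class = list(
      levels = c("normal", "overweight", "obese"),
      probs = list(bc = list(pos = bmi_bc_pos, neg = bmi_bc_neg),
                   oc = list(pos = bmi_oc_pos, neg = bmi_oc_neg),
                   both = list(pos = c(0, 0, 1), neg = c(0, 0, 1)))),
    menopause = list(
      levels = c("yes", "no"),
      probs = list(bc = list(pos = c(2 / 14, 12 / 14), neg = c(15 / 102, 87 / 102)),
                   oc = list(pos = c(0, 1), neg = c(0.8, 0.2)),
                   both = list(pos = c(0.6, 0.4), neg = c(0.6, 0.4)))),
    family_history = list(
      levels = c("bc_oc_pancreatic", "other", "none"),
      probs = list(bc = list(pos = c(1, 0, 0), neg = c(58 / 102, 16 / 102, 28 / 102)),
                   oc = list(pos = c(0.5, 0.25, 0.25), neg = c(0.6, 0.2, 0.2)),
                   both = list(pos = c(0.6, 0.2, 0.2), neg = c(0.6, 0.2, 0.2)))),
    chemo_response = list(
      levels = c("complete", "partial", "none", "recurrency"),
      probs = list(bc = list(pos = chemo_bc_pos, neg = chemo_bc_neg),
                   oc = list(pos = chemo_oc_pos, neg = chemo_oc_neg),
                   both = list(pos = c(0.8, 0, 0, 0.2), neg = c(0.8, 0, 0, 0.2)))),
    laterality = list(
      levels = c("unilateral", "bilateral"),
      probs = list(bc = list(pos = c(0.9, 0.1), neg = c(0.9, 0.1)),
                   oc = list(pos = c(0.25, 0.75), neg = c(13 / 15, 2 / 15)),
                   both = list(pos = c(1, 0), neg = c(1, 0)))),
    abortion = list(
      levels = c("yes", "no"),
      probs = list(bc = list(pos = c(0.16, 0.84), neg = c(0.16, 0.84)),
                   oc = list(pos = c(0.26, 0.74), neg = c(0.26, 0.74)),
                   both = list(pos = c(0, 1), neg = c(0, 1)))),
    breastfeeding = list(
      levels = c("yes", "no"),
      probs = list(bc = list(pos = c(0.69, 0.31), neg = c(0.69, 0.31)),
                   oc = list(pos = c(0.74, 0.26), neg = c(0.74, 0.26)),
                   both = list(pos = c(0.6, 0.4), neg = c(0.6, 0.4))))
  )
}

#' Specification of a synthetic two-arm cohort
#'
#' Defaults emulate the study conditions of the packaged BRCA2
#' catalogue: 116 breast-cancer (BC), 19 ovarian-cancer (OC) and 5
#' combined-diagnosis patients; carrier prevalence 14/116, 4/19 and 0;
#' group ages 46.9 +/- 13.3, 56.6 +/- 11.1 and 49.0 +/- 10.7 years
#' (normal, truncated to 18-95); and categorical covariates whose
#' carrier strata are shifted to the published carrier vs non-carrier
#' proportions (family history, overweight, chemotherapy response,
#' bilaterality).
#'
#' @param sizes Named integer vector `c(bc=, oc=, both=)`.
#' @param prevalence Carrier probability per group.
#' @param age Named list of `c(mean, sd)` per group.
#' @param age_menarche Same shape as `age`.
#' @param covariates Nested list: per variable, `levels` and `probs` --
#'   per group a list with `pos` (carrier) and `neg` probabilities over
#'   the levels.
#' @param seed Integer seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(sizes = c(bc = 116L, oc = 19L, both = 5L),
                        prevalence = c(bc = 14 / 116, oc = 4 / 19, both = 0),
                        age = list(bc = c(46.9, 13.3), oc = c(56.6, 11.1),
                                   both = c(49.0, 10.7)),
                        age_menarche = list(bc = c(12.2, 1.56), oc = c(11.8, 0.89),
                                            both = c(12.4, 0.54)),
                        covariates = default_cohort_covariates(),
                        seed = 1L) {
  stopifnot(all(c("bc", "oc", "both") %in% names(sizes)),
            all(sizes >= 0), all(prevalence >= 0), all(prevalence <= 1))
  for (v in names(covariates)) {
    cv <- covariates[[v]]
    for (g in names(cv$probs)) {
      for (s in c("pos", "neg")) {
        p <- cv$probs[[g]][[s]]
        if (length(p) != length(cv$levels) || any(p < 0) || any(p > 1) ||
            abs(sum(p) - 1) > 1e-8) {
          stop("invalid probabilities for covariate '", v, "', group '", g, "'")
        }
      }
    }
  }
  structure(list(sizes = sizes, prevalence = prevalence, age = age,
                 age_menarche = age_menarche, covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Deterministic given the spec and seed: identical calls produce
#' byte-identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides `spec$seed`.
#' @return A data frame with one row per patient: `id`, `group`
#'   (`"BC"`, `"OC"`, `"BC+OC"`), logical `carrier`, `age`,
#'   `age_menarche` and one character column per covariate.
#' @export
#' @examples
#' head(generate_cohort(cohort_spec(seed = 1)))
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  group_label <- c(bc = "BC", oc = "OC", both = "BC+OC")
  rows <- list()
  for (g in c("bc", "oc", "both")) {
    n <- as.integer(spec$sizes[[g]])
    if (n == 0L) next
    carrier <- stats::runif(n) < spec$prevalence[[g]]
    df <- data.frame(
      group = rep(group_label[[g]], n),
      carrier = carrier,
      age = round(truncnorm(n, spec$age[[g]][1], spec$age[[g]][2], 18, 95), 1),
      age_menarche = round(truncnorm(n, spec$age_menarche[[g]][1],
                                     spec$age_menarche[[g]][2], 8, 18), 1),
      stringsAsFactors = FALSE)
    for (v in names(spec$covariates)) {
      cv <- spec$covariates[[v]]
      lev_pos <- sample(seq_along(cv$levels), n, replace = TRUE,
                        prob = cv$probs[[g]]$pos)
      lev_neg <- sample(seq_along(cv$levels), n, replace = TRUE,
                        prob = cv$probs[[g]]$neg)
      df[[v]] <- cv$levels[ifelse(carrier, lev_pos, lev_neg)]
    }
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(0), carrier = logical(0),
                      age = numeric(0), age_menarche = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  cbind(data.frame(id = sprintf("P%04d", seq_len(nrow(out)))), out)
}

#' Specification of a synthetic variant panel
#'
#' @param n_variants Number of variants to emit.
#' @param consequence_probs Mixture over missense / frameshift /
#'   stop-gained (defaults to the 7/5/1 mix of the packaged catalogue).
#' @param position_range Residue positions sampled uniformly on this
#'   closed interval (default the 3418-residue protein).
#' @param adverse_weight Probability that each predictor score is drawn
#'   from its adverse component (SIFT <= 0.05 / PolyPhen >= 0.85)
#'   rather than its benign component; the two scores mix independently
#'   so concordant, single-evidence and benign profiles all occur.
#' @param score_missing Probability that a missense variant carries no
#'   scores at all (unannotated).
#' @param clinvar_probs Named probabilities over semicolon-separated
#'   ClinVar aggregate label sets.
#' @param carrier_lambda Carrier counts are `1 + Poisson(carrier_lambda)`,
#'   split between the BC and OC arms.
#' @param seed Integer seed used by [generate_panel()].
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_variants = 13L,
                       consequence_probs = c(missense = 7 / 13,
                                             frameshift = 5 / 13,
                                             stop_gained = 1 / 13),
                       position_range = c(1L, 3418L),
                       adverse_weight = 0.5,
                       score_missing = 1 / 7,
                       clinvar_probs = c("Pathogenic" = 0.25,
                                         "Pathogenic;Likely pathogenic" = 0.10,
                                         "Uncertain significance" = 0.30,
                                         "Uncertain significance;Likely benign" = 0.20,
                                         "Uncertain significance;Likely pathogenic" = 0.15),
                       carrier_lambda = 0.4,
                       seed = 1L) {
  stopifnot(n_variants >= 0,
            abs(sum(consequence_probs) - 1) < 1e-8,
            all(consequence_probs >= 0),
            all(names(consequence_probs) == c("missense", "frameshift", "stop_gained")),
            abs(sum(clinvar_probs) - 1) < 1e-8,
            adverse_weight >= 0, adverse_weight <= 1,
            score_missing >= 0, score_missing <= 1)
  structure(list(n_variants = as.integer(n_variants),
                 consequence_probs = consequence_probs,
                 position_range = as.integer(position_range),
                 adverse_weight = adverse_weight,
                 score_missing = score_missing,
                 clinvar_probs = clinvar_probs,
                 carrier_lambda = carrier_lambda,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic variant panel
#'
#' Every emitted record round-trips through [parse_protein_hgvs()];
#' frameshift and stop-gained variants carry no predictor scores.
#'
#' @param spec A [panel_spec()].
#' @param seed Overrides `spec$seed`.
#' @param cohort_sizes Passed to [variant_table()].
#' @return A list with `variants` (a [variant_table()]) and
#'   `predictions` (a score table joinable on `key`).
#' @export
#' @examples
#' panel <- generate_panel(panel_spec(n_variants = 20, seed = 7))
#' panel$variants
generate_panel <- function(spec, seed = spec$seed,
                           cohort_sizes = default_cohort_sizes()) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- spec$n_variants
  residues <- setdiff(AA_CODES$code3, "Ter")
  consequence <- sample(names(spec$consequence_probs), n, replace = TRUE,
                        prob = spec$consequence_probs)
  position <- sample(spec$position_range[1]:spec$position_range[2], n,
                     replace = TRUE)
  ref <- sample(residues, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(residues, r), 1L), character(1))
  hgvs_protein <- ifelse(consequence == "missense", paste0("p.", ref, position, alt),
                         ifelse(consequence == "stop_gained",
                                paste0("p.", ref, position, "Ter"),
                                paste0("p.", ref, position, "fs")))
  hgvs_cdna <- ifelse(consequence == "frameshift", paste0("c.", 3L * position, "del"),
                      paste0("c.", 3L * position - 2L, "A>G"))
  carriers <- 1L + stats::rpois(n, spec$carrier_lambda)
  carriers_bc <- stats::rbinom(n, carriers, 116 / 140)
  clinvar <- sample(names(spec$clinvar_probs), n, replace = TRUE,
                    prob = spec$clinvar_probs)
  clinical <- ifelse(vapply(clinvar, function(x) clinvar_evidence(x)$has_path_or_likely,
                            logical(1)),
                     "Pathogenic", "VUS")
  records <- data.frame(
    hgvs_cdna = hgvs_cdna,
    hgvs_protein = hgvs_protein,
    rsid = sprintf("rsS%06d", seq_len(max(n, 1L))[seq_len(n)]),
    carriers_bc = carriers_bc,
    carriers_oc = carriers - carriers_bc,
    clinical_classification = clinical,
    clinvar_aggregate = clinvar,
    clinvar_review = rep("synthetic", n),
    stringsAsFactors = FALSE
  )
  draw_score <- function(k, adverse_lo, adverse_hi, benign_lo, benign_hi) {
    adverse <- stats::runif(k) < spec$adverse_weight
    ifelse(adverse,
           stats::runif(k, adverse_lo, adverse_hi),
           stats::runif(k, benign_lo, benign_hi))
  }
  sift <- rep(NA_real_, n)
  poly <- rep(NA_real_, n)
  mis <- which(consequence == "missense")
  scored <- mis[stats::runif(length(mis)) >= spec$score_missing]
  sift[scored] <- round(draw_score(length(scored), 0, 0.05, 0.06, 1), 3)
  poly[scored] <- round(draw_score(length(scored), 0.85, 1, 0, 0.84), 3)
  predictions <- data.frame(key = records$rsid, sift_score = sift,
                            polyphen_score = poly, stringsAsFactors = FALSE)
  list(variants = variant_table(records, cohort_sizes),
       predictions = predictions)
}
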