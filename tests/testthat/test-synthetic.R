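test_that("generation is deterministic given spec and seed", {
  spec <- cohort_spec(seed = 13)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  ps <- panel_spec(n_variants = 50, seed = 13)
  a <- generate_panel(ps); b <- generate_panel(ps)
  expect_identical(a$variants$records, b$variants$records)
  expect_identical(a$predictions, b$predictions)
  # a different seed changes the draw
  expect_false(identical(generate_cohort(spec),
                         generate_cohort(spec, seed = 14)))
})

test_that("degenerate cohort specs behave", {
  empty <- generate_cohort(cohort_spec(sizes = c(bc = 0L, oc = 0L, both = 0L)))
  expect_equal(nrow(empty), 0L)
  all_carriers <- generate_cohort(cohort_spec(
    prevalence = c(bc = 1, oc = 1, both = 1), seed = 2))
  expect_true(all(all_carriers$carrier))
  expect_true(all(all_carriers$age >= 18))
  bad_cov <- default_cohort_covariates()
  bad_cov$menopause$probs$bc$pos <- c(0.7, 0.7)
  expect_error(cohort_spec(covariates = bad_cov), "invalid probabilities")
})

test_that("cohort sizes and carrier draws match the configured design", {
  cohort <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(cohort), 140L)
  expect_equal(unname(table(cohort$group)[c("BC", "OC", "BC+OC")]),
               c(116L, 19L, 5L), ignore_attr = TRUE)
  # mean carrier count across 200 seeds stays within 3 SE of the
  # binomial expectation (14 + 4 + 0 = 18)
  counts <- vapply(1:200, function(s) {
    sum(generate_cohort(cohort_spec(seed = s))$carrier)
  }, numeric(1))
  v <- 14 * (1 - 14 / 116) + 4 * (1 - 4 / 19)
  expect_lt(abs(mean(counts) - 18), 3 * sqrt(v / 200))
})

test_that("generated panels feed the rest of the pipeline unchanged", {
  panel <- generate_panel(panel_spec(n_variants = 300, seed = 7))
  rec <- panel$variants$records
  # round-trip through the parser
  pc <- parse_protein_hgvs(rec$hgvs_protein)
  expect_identical(parse_protein_hgvs(format_protein_hgvs(pc))[-1], pc[-1])
  # truncating variants never carry scores
  trunc_keys <- rec$key[rec$consequence != "missense"]
  scores <- panel$predictions[panel$predictions$key %in% trunc_keys, ]
  expect_true(all(is.na(scores$sift_score)) && all(is.na(scores$polyphen_score)))
  # and the panel prioritizes without schema adaptation
  pri <- prioritize_variants(panel$variants, predictions = panel$predictions)
  expect_equal(nrow(pri), 300L)
})

test_that("degenerate panel mixes follow the rubric", {
  all_fs <- generate_panel(panel_spec(
    n_variants = 40, seed = 3,
    consequence_probs = c(missense = 0, frameshift = 1, stop_gained = 0)))
  pri <- prioritize_variants(all_fs$variants, predictions = all_fs$predictions)
  expect_true(all(pri$priority == "High"))
  # adverse-score weight 0: no concordant predictor escalations
  benign <- generate_panel(panel_spec(n_variants = 200, seed = 4,
                                      adverse_weight = 0))
  prof <- classify_predictions(benign$predictions)
  expect_false(any(prof$concordant))
})
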