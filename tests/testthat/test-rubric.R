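fixture_priorities <- function(...) {
  prioritize_variants(load_fixture_variants(),
                      predictions = load_fixture_predictions(), ...)
}

test_that("ClinVar evidence detects P/LP labels inside aggregates", {
  expect_true(clinvar_evidence("Pathogenic")$has_path_or_likely)
  expect_true(clinvar_evidence("Uncertain significance;Likely pathogenic")$has_path_or_likely)
  expect_false(clinvar_evidence("Uncertain significance;Likely benign")$has_path_or_likely)
  expect_false(clinvar_evidence("")$has_path_or_likely)
  expect_equal(clinvar_evidence("A; B ;C")$labels, c("A", "B", "C"))
})

test_that("single-variant traces follow the stepwise rules", {
  asg <- function(cat, crit, dom = "X") {
    data.frame(category = cat, critical = crit, domain = dom,
               stringsAsFactors = FALSE)
  }
  prof <- function(s, p) data.frame(sift_call = s, polyphen_call = p)
  no_cv <- clinvar_evidence("Uncertain significance")
  plp <- clinvar_evidence("Pathogenic")

  # truncating: High regardless of everything else
  r <- assign_priority("frameshift", asg("outside", FALSE, NA),
                       prof("unknown", "unknown"), no_cv)
  expect_equal(as.character(r$level), "High")
  # critical domain + concordant predictors + ClinVar P/LP: clamped to High
  r <- assign_priority("missense", asg("inside", TRUE),
                       prof("deleterious", "damaging"), plp)
  expect_equal(as.character(r$level), "High")
  expect_true(r$ledger$applied[r$ledger$rule == "high_cap"])
  # critical domain + single predictor: capped at Moderate
  r <- assign_priority("missense", asg("inside", TRUE),
                       prof("deleterious", "not_damaging"), no_cv)
  expect_equal(as.character(r$level), "Moderate")
  # single predictor + ClinVar P/LP still capped at Moderate
  r <- assign_priority("missense", asg("outside", FALSE),
                       prof("deleterious", "not_damaging"), plp)
  expect_equal(as.character(r$level), "Moderate")
  # non-critical domain, no predictors, ClinVar Pathogenic: one step up
  r <- assign_priority("missense", asg("inside", FALSE),
                       prof("unknown", "unknown"), plp)
  expect_equal(as.character(r$level), "Moderate")
  # boundary category never escalates
  r <- assign_priority("missense", asg("boundary", FALSE),
                       prof("tolerated", "not_damaging"), no_cv)
  expect_equal(as.character(r$level), "Low")
  # missing evidence channels are errors
  expect_error(assign_priority("missense", asg(NA, FALSE),
                               prof("unknown", "unknown"), no_cv), "domain")
  expect_error(assign_priority("missense", asg("outside", FALSE),
                               prof(NA, NA), no_cv), "prediction")
})

test_that("the catalogue reproduces the published priority levels", {
  pri <- fixture_priorities()
  expected <- c(
    rs80359380 = "High", rs80359479 = "High", rs878853569 = "High",
    rs398122715 = "High", rs397507422 = "High", rs11571658 = "High",
    rs587782313 = "High",
    rs80359219 = "Moderate", rs1064795067 = "Moderate",
    rs587780646 = "Moderate", rs775030825 = "Moderate",
    rs1329182873 = "Low", "c.9812T>C" = "Low"
  )
  expect_equal(as.character(pri$priority[match(names(expected), pri$key)]),
               unname(expected))
  # report ordered High -> Low, then by position
  expect_true(!is.unsorted(rev(as.integer(pri$priority))))
})

test_that("withholding predictions never raises a level and demotes score-driven ones", {
  preds <- load_fixture_predictions()
  preds$sift_score <- NA_real_
  preds$polyphen_score <- NA_real_
  full <- fixture_priorities()
  pri <- prioritize_variants(load_fixture_variants(), predictions = preds)
  expect_true(all(pri$priority[match(full$key, pri$key)] <= full$priority))
  # without scores, missense levels come from domain and ClinVar alone:
  # only a P/LP assertion can then push a critical-domain variant to High
  mis <- pri[pri$consequence == "missense", ]
  plp <- vapply(mis$clinvar, function(x) clinvar_evidence(x)$has_path_or_likely,
                logical(1))
  expect_true(all(mis$priority[!plp] <= "Moderate"))
  # truncating rows unaffected
  expect_true(all(pri$priority[pri$consequence != "missense"] == "High"))
})

test_that("a missing prediction key is an error listing the key", {
  preds <- load_fixture_predictions()
  expect_error(prioritize_variants(load_fixture_variants(),
                                   predictions = preds[-1, ]),
               preds$key[1], fixed = TRUE)
})

test_that("levels are reproducible from the ledgers", {
  pri <- fixture_priorities()
  ledgers <- attr(pri, "ledgers")
  for (k in pri$key) {
    expect_equal(priority_from_ledger(ledgers[[k]]),
                 as.integer(pri$priority[pri$key == k]) - 1L)
  }
})

test_that("an empty table gives an empty report", {
  vt <- load_fixture_variants()
  empty <- variant_table(vt$records[0, setdiff(names(vt$records),
                                               c("key", "ref", "position", "alt",
                                                 "consequence"))])
  pri <- prioritize_variants(empty, predictions = load_fixture_predictions())
  expect_equal(nrow(pri), 0L)
})
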