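test_that("carrier-stratified comparisons reproduce the published tables", {
  # overweight in BC: 4/14 carriers vs 6/102 non-carriers (29% vs 6%)
  p <- compare_counts(c(4L, 10L), c(6L, 96L))
  expect_equal(round(p, 3), 0.019)
  # bilateral disease in OC: 3/4 vs 2/15 (75% vs 13%)
  p <- compare_counts(c(3L, 1L), c(2L, 13L))
  expect_equal(round(p, 3), 0.037)
  # family history in BC over its three categories (14/0/0 vs 58/16/28);
  # the three-level exact test gives the published 0.004
  p <- compare_counts(c(14L, 0L, 0L), c(58L, 16L, 28L))
  expect_equal(round(p, 3), 0.004)
  # complete chemotherapy response: 5/14 vs 70/102 (36% vs 69%)
  p <- compare_counts(c(5L, 9L), c(70L, 32L))
  expect_lt(abs(p - 0.032), 0.002)
})

test_that("two-level exact tests are the single Fisher implementation", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next
    expect_identical(compare_counts(c(k1, n1 - k1), c(k2, n2 - k2)),
                     fisher_exact2(k1, n1, k2, n2)$p_value)
  }
})

test_that("compare_by_carrier dispatches on variable type", {
  pts <- patients_from_counts("overweight", c("yes", "no"), c(4L, 10L), c(6L, 96L))
  cmp <- compare_by_carrier(pts, "overweight")
  expect_equal(cmp$type, "categorical")
  expect_equal(cmp$pct_positive, round(c(10, 4) / 14 * 100))
  expect_equal(round(cmp$p_value, 3), 0.019)

  pts$age <- c(rnorm(14, 43, 5), rnorm(102, 47, 5))
  cmp <- compare_by_carrier(pts, "age")
  expect_equal(cmp$type, "continuous")
  expect_equal(cmp$p_value,
               t.test(pts$age[pts$carrier], pts$age[!pts$carrier])$p.value)

  # identical strata: p = 1
  pts$flat <- "same"
  expect_equal(compare_by_carrier(pts, "flat")$p_value, 1)
  pts$const <- 5
  expect_equal(compare_by_carrier(pts, "const")$p_value, 1)
})

test_that("descriptive summaries report counts, percents and moments", {
  pts <- data.frame(group = c("BC", "BC", "BC", "OC"),
                    age = c(40, 50, 60, 55),
                    bmi_class = c("obese", "obese", "obese", "normal"),
                    stringsAsFactors = FALSE)
  s <- summarize_cohort(pts)
  bc_age <- s$continuous[s$continuous$group == "BC", ]
  expect_equal(bc_age$mean, 50)
  expect_equal(bc_age$sd, 10)
  # single-patient group: sd reported as 0 with a flag
  oc_age <- s$continuous[s$continuous$group == "OC", ]
  expect_equal(oc_age$sd, 0)
  expect_true(oc_age$sd_undefined)
  # exhaustive categorical: percentages sum to 100
  bc_bmi <- s$categorical[s$categorical$group == "BC" &
                            s$categorical$variable == "bmi_class", ]
  expect_equal(bc_bmi$pct, 100)
  expect_error(summarize_cohort(pts[0, ]), "empty")
})

test_that("a seeded synthetic BC arm recovers its age distribution", {
  cohort <- generate_cohort(cohort_spec(seed = 101))
  s <- summarize_cohort(cohort, variables = "age")
  bc <- s$continuous[s$continuous$group == "BC", ]
  se <- 13.3 / sqrt(116)
  expect_lt(abs(bc$mean - 46.9), 3 * se)
})
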