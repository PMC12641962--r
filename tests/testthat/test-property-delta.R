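test_that("substitution deltas match the published change vocabulary", {
  d <- property_delta(c("Leu", "Ala", "Glu", "Leu", "Leu", "Gln", "Glu"),
                      c("Arg", "Pro", "Gly", "Leu", "Ser", "Arg", "Leu"))
  # Leu -> Arg: larger, gains positive charge, less hydrophobic
  expect_equal(d$size_change[1], "increase")
  expect_equal(c(d$charge_ref[1], d$charge_alt[1]), c("neutral", "positive"))
  expect_equal(d$hydrophobicity_change[1], "decrease")
  expect_true(d$charge_gained[1])
  # Ala -> Pro: larger, proline flag
  expect_equal(d$size_change[2], "increase")
  expect_true(d$proline_introduced[2])
  expect_equal(c(d$charge_ref[2], d$charge_alt[2]), c("neutral", "neutral"))
  # Glu -> Gly: smaller, loses negative charge, more hydrophobic, glycine flag
  expect_equal(d$size_change[3], "decrease")
  expect_true(d$charge_lost[3] && d$glycine_introduced[3])
  expect_equal(d$hydrophobicity_change[3], "increase")
  # identity: everything similar, no flags
  expect_equal(d$size_change[4], "similar")
  expect_equal(d$hydrophobicity_change[4], "similar")
  expect_false(any(unlist(d[4, c("proline_introduced", "glycine_introduced",
                                 "charge_lost", "charge_gained")])))
  # Leu -> Ser: smaller and less hydrophobic
  expect_equal(d$size_change[5], "decrease")
  expect_equal(d$hydrophobicity_change[5], "decrease")
  # Gln -> Arg: larger, gains positive charge
  expect_equal(d$size_change[6], "increase")
  expect_true(d$charge_gained[6])
  # Glu -> Leu: loses negative charge, more hydrophobic
  expect_true(d$charge_lost[7])
  expect_equal(d$hydrophobicity_change[7], "increase")
})

test_that("stop tokens are rejected", {
  expect_error(property_delta("Ter", "Gly"), "Ter")
  expect_error(property_delta("Gly", "Ter"), "Ter")
})

test_that("deltas are antisymmetric", {
  residues <- setdiff(amino_acids()$code3, "Ter")
  set.seed(5)
  pairs <- t(replicate(80, sample(residues, 2)))
  fwd <- property_delta(pairs[, 1], pairs[, 2])
  rev <- property_delta(pairs[, 2], pairs[, 1])
  flip <- c(increase = "decrease", decrease = "increase", similar = "similar")
  expect_equal(unname(flip[fwd$size_change]), rev$size_change)
  expect_equal(unname(flip[fwd$hydrophobicity_change]), rev$hydrophobicity_change)
  expect_equal(fwd$charge_ref, rev$charge_alt)
  expect_equal(fwd$charge_alt, rev$charge_ref)
})

test_that("report lines use arrow notation", {
  expect_equal(delta_report(property_delta("Leu", "Arg")),
               "↑ Size, Neutral → Positive, ↓ Hydrophobicity")
  expect_match(delta_report(property_delta("Ala", "Pro")), "Proline")
  expect_equal(delta_report(property_delta("Leu", "Leu")), "no property change")
})

test_that("charge classes follow physiological-pH convention", {
  props <- residue_properties()
  expect_setequal(props$code3[props$charge_class == "negative"], c("Asp", "Glu"))
  expect_setequal(props$code3[props$charge_class == "positive"], c("Lys", "Arg"))
  expect_equal(props$charge_class[props$code3 == "His"], "neutral")
  expect_equal(nrow(props), 20L)
})
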