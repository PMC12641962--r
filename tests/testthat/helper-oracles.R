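# Independent oracles and shared fixture loaders for the test suite.

# Two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, using stats::dhyper point probabilities (a code path
# independent of the package's log-space lchoose implementation).
fisher_enum_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  support <- max(0, K - n2):min(K, n1)
  probs <- dhyper(support, n1, n2, K)
  obs <- probs[support == k1]
  min(sum(probs[probs <= obs * (1 + 1e-7)]), 1)
}

# Brute-force interval scan: membership over all non-boundary-only
# intervals, then minimum distance to any annotated edge.
domain_scan_oracle <- function(position, domains, window) {
  vapply(position, function(p) {
    for (i in seq_len(nrow(domains))) {
      if (!domains$boundary_only[i] && domains$start[i] <= p && p <= domains$end[i]) {
        return("inside")
      }
    }
    d <- Inf
    for (i in seq_len(nrow(domains))) {
      d <- min(d, abs(p - domains$start[i]), abs(p - domains$end[i]))
    }
    if (d <= window) "boundary" else "outside"
  }, character(1))
}

load_fixture_variants <- function() read_variant_table(brca2_example("variants"))
load_fixture_predictions <- function() read_predictions(brca2_example("predictions"))
load_fixture_references <- function() read_reference_counts(brca2_example("references"))

# Reconstruct a patient table from stratified level counts: one block of
# carriers, one of non-carriers.
patients_from_counts <- function(variable, levels, counts_pos, counts_neg,
                                 group = "BC") {
  data.frame(
    group = group,
    carrier = rep(c(TRUE, FALSE), c(sum(counts_pos), sum(counts_neg))),
    value = c(rep(levels, counts_pos), rep(levels, counts_neg)),
    stringsAsFactors = FALSE
  ) |> (\(d) {names(d)[3] <- variable; d})()
}
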