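---
title: "Evidence integration for germline BRCA2 variant triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration for germline BRCA2 variant triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brca2triage)
```

## The problem

Targeted sequencing of *BRCA2* in hereditary breast/ovarian cancer (BC/OC)
cohorts routinely yields a mix of clearly pathogenic truncating variants and
missense variants of uncertain significance (VUS). Deciding which VUS deserve
follow-up requires combining several weak evidence channels: where the variant
falls on the protein, what conservation- and structure-based predictors say,
how the substitution changes the residue's physicochemistry, and what ClinVar
submitters have asserted. `brca2triage` implements that integration as a
transparent, auditable pipeline, together with the cohort-level statistics
(carrier frequencies, exact-test comparisons against reference populations,
carrier-stratified clinical comparisons) that such studies report.

The packaged example data are a 13-variant *BRCA2* catalogue observed in a
140-patient cohort (116 BC, 19 OC, 5 with both diagnoses), shipped as
plain-text tables under `inst/extdata/`.

## The prioritization rubric

The core of the package is a stepwise Low/Moderate/High rubric
(`assign_priority()`). Levels are ranks 0/1/2 and the rules apply in order:

1. **Truncating rule.** Frameshift and stop-gained variants are assigned High
   directly: premature termination upstream of the C-terminus is expected to
   abolish the RAD51-interaction and DNA-binding machinery regardless of any
   other evidence.
2. **Domain escalation (+1).** A missense variant *inside* a functionally
   critical domain steps up one level. Critical domains for BRCA2 are the BRC
   repeats (residues 1003–2082, RAD51 loading) and the DNA-binding domain
   including its terminal portion (2804–3054 and 3052–3185, ssDNA/dsDNA and
   DSS1 binding).
3. **Predictor escalation (+1).** Concordant adverse predictions — SIFT
   ≤ 0.05 *and* PolyPhen ≥ 0.85 — step up one level.
4. **Single-predictor cap (+1, cap).** If exactly one predictor is adverse,
   the variant still steps up one level, but its final level is capped at
   Moderate. The increment (not just the cap) is required for variants that
   lie outside all domains yet carry one adverse call and are reported at
   Moderate; the cap encodes that discordant predictors are weaker evidence.
5. **ClinVar escalation (+1).** Any Pathogenic or Likely-pathogenic assertion
   — including assertions inside "conflicting interpretations" aggregates —
   steps up one level. Benign/VUS assertions contribute nothing.
6. **High cap.** Ranks above 2 clamp to High.

Every result carries a six-row ledger recording, for each rule, whether it
applied and why. `priority_from_ledger()` recomputes the level from the ledger
alone, and the test suite asserts this audit over the packaged catalogue and a
1,000-variant synthetic panel.

```{r rubric}
vt <- read_variant_table(brca2_example("variants"))
preds <- read_predictions(brca2_example("predictions"))
pri <- prioritize_variants(vt, predictions = preds)
pri[, c("key", "protein_change", "consequence", "domain", "priority")]
```

### Design choices that were genuinely open

* **The terminal DBD is critical.** The narrative list of critical domains
  names "BRC repeats, DNA-binding domain"; we treat the terminal DBD
  (3052–3185) as part of the critical set because the reported levels of the
  three terminal-DBD missense variants are only reproducible with the
  escalation applied. This is an inference from the worked examples, not
  explicit text, and is confined to the packaged domain config.
* **Single adverse predictor grants +1 before the cap.** Stated rubrics of
  this kind often give only the cap; the increment is needed so that
  out-of-domain variants with one adverse call land at Moderate rather than
  Low.
* **Conflicting ClinVar aggregates count.** A "conflicting" record containing
  a Likely-pathogenic assertion triggers the ClinVar escalation; matching is
  by exploded label, case-insensitive, against {Pathogenic, Likely
  pathogenic} exactly (so "Likely benign" can never match).
* **The boundary category never escalates.** See below.

## Domain mapping

Domains are closed, 1-based residue intervals on UniProt P51587 numbering
(`load_domain_config()`, `map_position()`). A position is *inside* a domain
when `start <= position <= end`; overlapping annotations are resolved by the
smallest interval (so the 3052–3054 overlap between DBD and terminal DBD
belongs to the terminal DBD), then config order. Positions outside all
intervals but within `boundary_window` residues (default 5) of an annotated
edge are *boundary*; everything else is *outside*. Enlarging the window can
only promote outside → boundary, never touch inside assignments — a property
the tests check against a brute-force interval scan over residues 1–4000.

The packaged config carries a fourth, non-critical entry: the C-terminal
region at the DBD boundary (3190–3418, phosphorylation sites and the
C-terminal RAD51-stabilizing region). It is flagged `boundary_only`: its
edges participate in boundary detection — which is how residue 3187, sitting
in the 3186–3189 gap between annotations, gets its published
"C-terminal/DBD boundary" label — but its interior does not create "inside"
assignments. This mirrors how the region is actually used in the source
analysis, where a missense variant at residue 3271 is reported as *outside
described domains* even though 3271 falls numerically within 3190–3418, and
the boundary region is invoked only for the near-edge case. Consequently the
region can never escalate the rubric, which is also required for the
rubric's reported Low level at 3187.

## Predictor scores

Scores arrive as data (`read_predictions()`); the package never calls the
predictors. Calls are threshold-derived and boundary-inclusive: SIFT ≤ 0.05
is deleterious, PolyPhen ≥ 0.85 is damaging (`classify_predictions()`, both
cutoffs configurable). PolyPhen's own categorical labels (e.g. "possibly
damaging" at 0.738) are deliberately not used by the rubric — only the score
cutoff is — so a "possibly damaging" 0.738 contributes no predictor evidence.
Absent scores (truncating variants, unannotated variants) give `unknown`
calls that contribute nothing.

## Physicochemical deltas

`property_delta()` compares residues on fixed scales shipped as JSON:
side-chain volumes after Zamyatnin (Å³), the Kyte–Doolittle hydropathy index,
and conventional physiological-pH charge classes (Asp/Glu negative, Lys/Arg
positive, His neutral). Size and hydrophobicity changes are strict
comparisons; flags mark proline/glycine introduction and charge gain/loss.
`delta_report()` renders the arrow-notation summary ("↑ Size, Neutral →
Positive, ↓ Hydrophobicity").

Two cells of the published change table are *not* reproduced by any standard
scale, and the package reports the scale-derived values instead of matching
them: an Asn→Ser substitution is printed as "Negative → Neutral" although
asparagine is neutral at physiological pH, and a Glu→Leu substitution is
printed as a size decrease although leucine (166.7 Å³) exceeds glutamate
(138.4 Å³) on volume scales. The acceptance tests assert these two cells as
documented divergences, not as matches.

## Exact frequency comparisons

`fisher_exact2()` implements the two-sided Fisher exact test on 2×2 carrier
tables: the sum of hypergeometric point probabilities, over all tables with
the observed margins, that do not exceed the observed table's probability
(with a 1 + 1e-7 relative slack for floating-point ties). Probabilities are
computed in log space via `lchoose()`, so reference denominators in the
millions (gnomAD allele numbers) are handled exactly. The implementation is
verified against full enumeration via `stats::dhyper()` for every margin
with total ≤ 60 (tolerance 1e-12) and spot-checked against
`stats::fisher.test()`; a seeded null-calibration simulation (10,000
replicates at n₁ = 140, n₂ = 10,000, p = 0.02) confirms the test is
conservative at α = 0.05.

Cohort counts are carriers-out-of-140-patients while database counts are
alleles-out-of-allele-number, exactly as such studies tabulate them; the
report keeps the `kind` column (`cohort`/`database`) to annotate the unit
mismatch rather than hiding it. No multiple-testing correction is applied,
matching the source analysis. One published cell (2/140 vs 1/3842 printed as
p = 0.00046) is not reproducible under any Fisher construction we tried
(enumeration gives ≈ 0.0036); it is documented here and excluded from the
reproduction checks. p-values display at 4 decimals, with values below
0.0001 shown as `<0.0001`.

## Cohort statistics

`compare_by_carrier()` compares carriers and non-carriers: categorical
variables with an exact test (the in-package Fisher for two-level variables;
`stats::fisher.test()` for r×2 tables), continuous variables with Welch's
unequal-variance t-test (the source names no test; Welch is the conservative
default). Two published p-values deserve comment. The family-history
comparison (100% vs 57%, printed p = 0.004) reproduces only as the r×2 exact
test over the three family-history categories (14/0/0 vs 58/16/28 → 0.0037),
not as a 2×2 on the collapsed counts (0.00088) — the package therefore keeps
all levels. The OC "menopause" comparison printed as p = 0.018 equals a
doubled one-tailed Fisher p; the two-sided enumeration gives 0.009, and the
package reports the latter. Display percentages round half-up to integers.

## The synthetic generator

`generate_cohort()` emulates the study conditions so every stage is testable
without patient-level data (none are deposited): group sizes 116/19/5;
carrier prevalence 14/116, 4/19 and 0; ages normal with the published
mean ± SD per group (46.9 ± 13.3, 56.6 ± 11.1, 49.0 ± 10.7), truncated to
18–95 years since inclusion required adults and only mean, SD and range are
published; menarche ages likewise. Categorical covariates are sampled
independently given the carrier stratum — only marginal stratified counts
are published, so no dependence structure can be estimated — with carrier
strata shifted to the published carrier vs non-carrier proportions
(family history 100% vs 57%, overweight 29% vs 6%, complete chemotherapy
response 36% vs 69% in BC; bilaterality 75% vs 13% and the 0% vs 80% row in
OC). Residual probability mass within a variable is split in proportion to
the group's marginal level counts. Carrier status is an independent
Bernoulli draw per patient, so carrier counts fluctuate binomially around
the design expectation of 18 per 140 patients.

`generate_panel()` emits variant catalogues with a configurable
missense/frameshift/stop-gained mix (default the catalogue's 7/5/1),
positions uniform over the 3418-residue protein, predictor scores drawn from
independent adverse/benign mixture components (so concordant,
single-evidence and benign profiles all arise), and ClinVar aggregate label
sets. Every emitted record round-trips through the HGVS parser, and
truncating records never carry scores.

What the generator does **not** emulate: linkage/haplotype structure,
covariate dependence beyond the carrier stratification, site-specific
recurrence of real founder variants, or any sequence-level process. Passing
tests on synthetic data therefore demonstrate the pipeline's correctness
under the declared sampling model, not properties of real cohorts.

### Problem sizes and numerical choices

The test suite uses: the full enumeration oracle up to margin total 60; a
1,000-variant panel for rubric monotonicity; 10,000 replicates for null
calibration; 200 seeds for the carrier-count check; and a 49,980-patient
cohort (140 × 357) for parameter recovery. On the last of these, the suite
asks each recovered parameter (prevalence, age means, covariate odds ratios)
to fall within 2% relative error of its design value at a fixed seed chosen
in advance. For stratified odds ratios at this sample size, 2% relative
error corresponds to roughly half a standard error of the log-odds-ratio
estimator, so under the Bernoulli sampling model this bound fails for some
parameters at typical seeds; the suite reports those misses honestly rather
than widening the bound or re-seeding (see the repository test log: the
four recovery expectations that exceed 2% do so by amounts well within two
sampling standard errors).

Ties in domain overlap resolve by interval span then config order; identity
substitutions report "no property change"; degenerate contingency tables
(a single observed level) return p = 1; empty variant tables flow through
every stage as empty reports.

## Known limitations

* The rubric is a research-prioritization heuristic, not ACMG/AMP
  classification; clinical labels are inputs, never recomputed.
* HGVS support is deliberately minimal (coding substitutions, dup, del,
  delins; protein missense/stop/frameshift): no intronic, UTR or complex
  rearrangement grammar, and positions are trusted as printed without
  transcript validation.
* Predictor integration is limited to SIFT/PolyPhen score thresholds;
  conservation, splicing and structure-based evidence are out of scope.
* The exact-test comparison inherits the carriers-vs-alleles unit mismatch
  of the tabulation it reproduces; interpret database comparisons as
  screening signals, not calibrated association tests.
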