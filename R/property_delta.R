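# Qualitative physicochemical change reports for missense substitutions:
# side-chain volume (size), Kyte-Doolittle hydropathy (hydrophobicity)
# and physiological-pH charge class, plus structural flags for proline /
# glycine introduction and charge gain/loss.

#' Physicochemical delta of a missense substitution
#'
#' @param ref,alt Three-letter residue codes (vectors recycle to common
#'   length). `Ter` is rejected: stop changes are not substitutions.
#' @param properties Property table from [residue_properties()].
#' @return A data frame with one row per substitution: `ref`, `alt`,
#'   `size_change` and `hydrophobicity_change`
#'   (`increase`/`decrease`/`similar`, by strict comparison of volume /
#'   hydropathy), `charge_ref`, `charge_alt`, and logical flags
#'   `proline_introduced`, `glycine_introduced`, `charge_lost` (charged
#'   to neutral), `charge_gained` (neutral to charged).
#' @export
#' @examples
#' property_delta("Leu", "Arg")
property_delta <- function(ref, alt, properties = residue_properties()) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  if (any(ref == "Ter") || any(alt == "Ter")) {
    stop("'Ter' is not a substitutable residue")
  }
  ri <- match(ref, properties$code3)
  ai <- match(alt, properties$code3)
  if (anyNA(ri) || anyNA(ai)) {
    bad <- unique(c(ref[is.na(ri)], alt[is.na(ai)]))
    stop("unknown residue code: ", paste(bad, collapse = ", "))
  }
  cmp <- function(a, b) ifelse(a > b, "increase", ifelse(a < b, "decrease", "similar"))
  charge_ref <- properties$charge_class[ri]
  charge_alt <- properties$charge_class[ai]
  data.frame(
    ref = ref, alt = alt,
    size_change = cmp(properties$volume[ai], properties$volume[ri]),
    hydrophobicity_change = cmp(properties$hydropathy[ai], properties$hydropathy[ri]),
    charge_ref = charge_ref, charge_alt = charge_alt,
    proline_introduced = alt == "Pro" & ref != "Pro",
    glycine_introduced = alt == "Gly" & ref != "Gly",
    charge_lost = charge_ref != "neutral" & charge_alt == "neutral",
    charge_gained = charge_ref == "neutral" & charge_alt != "neutral",
    stringsAsFactors = FALSE
  )
}

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Human-readable summary of a property delta
#'
#' Arrow-notation summary lines, e.g. `"↑ Size, Neutral →
#' Positive, ↓ Hydrophobicity"`; identity substitutions give
#' `"no property change"`.
#'
#' @param delta A data frame from [property_delta()].
#' @return Character vector, one line per substitution.
#' @export
#' @examples
#' delta_report(property_delta("Leu", "Arg"))
delta_report <- function(delta) {
  arrow <- function(change, label) {
    ifelse(change == "increase", paste("↑", label),
           ifelse(change == "decrease", paste("↓", label), NA_character_))
  }
  vapply(seq_len(nrow(delta)), function(i) {
    d <- delta[i, ]
    parts <- c(
      arrow(d$size_change, "Size"),
      if (d$charge_ref != d$charge_alt) {
        paste(cap1(d$charge_ref), "→", cap1(d$charge_alt))
      } else NA_character_,
      arrow(d$hydrophobicity_change, "Hydrophobicity"),
      if (d$proline_introduced) "Proline introduced (possible rigidity, helix disruption)" else NA_character_,
      if (d$glycine_introduced) "Glycine introduced (increased backbone flexibility)" else NA_character_
    )
    parts <- parts[!is.na(parts)]
    if (!length(parts)) "no property change" else paste(parts, collapse = ", ")
  }, character(1))
}
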