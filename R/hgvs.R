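# Minimal HGVS parsing covering the nomenclature used in germline BRCA2
# variant tables: protein-level "p." strings (missense, stop-gained,
# frameshift) and coding "c." edits (substitution, dup, del, delins).
# Positions are trusted as printed; no transcript validation is done.

#' Parse protein-level HGVS strings
#'
#' Accepts the `p.` nomenclature used for coding variants:
#' `p.Ala3122Pro` (missense), `p.Glu2947Ter` (stop gained), and
#' `p.Gln1089fs` or `p.Val3079Phefs` (frameshift; an inserted residue
#' printed before `fs` is discarded, so both frameshift spellings
#' normalize to the same value).
#'
#' @param x Character vector of protein HGVS strings (with or without a
#'   surrounding `"(...)"`).
#' @return A data frame with one row per input and columns `input`,
#'   `ref` (three-letter code), `position` (1-based residue index),
#'   `alt` (three-letter code, `"Ter"` for stop gained, `NA` for
#'   frameshift) and `consequence` (`"missense"`, `"stop_gained"`,
#'   `"frameshift"`).
#' @export
#' @examples
#' parse_protein_hgvs(c("p.Gln1089fs", "p.Glu2947Ter", "p.Ala3122Pro"))
parse_protein_hgvs <- function(x) {
  stopifnot(is.character(x))
  x0 <- sub("^\\((.*)\\)$", "\\1", trimws(x))
  m <- regmatches(x0, regexec("^p\\.([A-Z][a-z]{2})([0-9]+)(.*)$", x0))
  out <- lapply(seq_along(x0), function(i) {
    parts <- m[[i]]
    if (length(parts) != 4L) {
      stop("malformed protein HGVS: '", x[i], "' (expected 'p.<Ref><pos><suffix>')")
    }
    ref <- parts[2]
    if (!is_aa_code3(ref) || ref == "Ter") {
      stop("unknown reference residue '", ref, "' in '", x[i], "'")
    }
    pos <- as.integer(parts[3])
    if (is.na(pos) || pos < 1L) stop("non-positive position in '", x[i], "'")
    suffix <- parts[4]
    if (grepl("fs", suffix, fixed = TRUE)) {
      ins <- sub("fs.*$", "", suffix)
      if (!(ins == "" || (is_aa_code3(ins) && ins != "Ter"))) {
        stop("unknown residue '", ins, "' before 'fs' in '", x[i], "'")
      }
      list(ref = ref, position = pos, alt = NA_character_, consequence = "frameshift")
    } else if (suffix == "Ter") {
      list(ref = ref, position = pos, alt = "Ter", consequence = "stop_gained")
    } else if (is_aa_code3(suffix)) {
      list(ref = ref, position = pos, alt = suffix, consequence = "missense")
    } else {
      stop("unknown residue or suffix '", suffix, "' in '", x[i], "'")
    }
  })
  data.frame(
    input = x,
    ref = vapply(out, `[[`, character(1), "ref"),
    position = vapply(out, `[[`, integer(1), "position"),
    alt = vapply(out, `[[`, character(1), "alt"),
    consequence = vapply(out, `[[`, character(1), "consequence"),
    stringsAsFactors = FALSE
  )
}

#' Format a parsed protein change back to canonical HGVS
#'
#' Inverse of [parse_protein_hgvs()] up to frameshift normalization:
#' frameshift changes always print as `p.<Ref><pos>fs`.
#'
#' @param pc A data frame as returned by [parse_protein_hgvs()].
#' @return Character vector of `p.` strings.
#' @export
format_protein_hgvs <- function(pc) {
  suffix <- ifelse(pc$consequence == "frameshift", "fs", pc$alt)
  paste0("p.", pc$ref, pc$position, suffix)
}

#' Parse coding-DNA HGVS edit descriptors
#'
#' Extracts the edit kind and coding positions from `c.` strings:
#' `c.3188A>G` (substitution), `c.3264dup`, `c.6275_6276del`,
#' `c.6415_6416delinsAT`. Position ranges `a_b` are supported for all
#' edit kinds. No validation against a transcript sequence is performed.
#'
#' @param x Character vector of cDNA HGVS strings.
#' @return A data frame with columns `input`, `start`, `end` (equal to
#'   `start` for single-position edits) and `edit_kind` (one of
#'   `"sub"`, `"dup"`, `"del"`, `"delins"`).
#' @export
#' @examples
#' parse_cdna_hgvs(c("c.3188A>G", "c.6415_6416delinsAT", "c.3264dup"))
parse_cdna_hgvs <- function(x) {
  stopifnot(is.character(x))
  x0 <- trimws(x)
  m <- regmatches(x0, regexec("^c\\.([0-9]+)(?:_([0-9]+))?(.*)$", x0))
  out <- lapply(seq_along(x0), function(i) {
    parts <- m[[i]]
    if (length(parts) != 4L) stop("malformed cDNA HGVS: '", x[i], "'")
    start <- as.integer(parts[2])
    end <- if (parts[3] == "") start else as.integer(parts[3])
    if (end < start) stop("inverted position range in '", x[i], "'")
    suffix <- parts[4]
    kind <- if (grepl("^delins[ACGT]*$", suffix)) {
      "delins"
    } else if (grepl("^del[ACGT]*$", suffix)) {
      "del"
    } else if (grepl("^dup[ACGT]*$", suffix)) {
      "dup"
    } else if (grepl("^[ACGT]+>[ACGT]+$", suffix)) {
      "sub"
    } else {
      stop("unparseable edit '", suffix, "' in '", x[i], "'")
    }
    list(start = start, end = end, edit_kind = kind)
  })
  data.frame(
    input = x,
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    edit_kind = vapply(out, `[[`, character(1), "edit_kind"),
    stringsAsFactors = FALSE
  )
}
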