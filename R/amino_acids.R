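# Canonical residue vocabulary shared by the HGVS parser and the
# physicochemical delta module. "Ter" is the stop token (one-letter "*").

AA_CODES <- data.frame(
  code3 = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
            "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
            "Tyr", "Val", "Ter"),
  code1 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
            "I", "L", "K", "M", "F", "P", "S", "T", "W",
            "Y", "V", "*"),
  stringsAsFactors = FALSE
)

#' Canonical amino-acid codes
#'
#' The 20 canonical residues plus the stop token `Ter`, with the bijection
#' between three-letter and one-letter codes (`Ter` maps to `"*"`).
#'
#' @return A data frame with columns `code3` and `code1` (21 rows).
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() AA_CODES

#' @rdname amino_acids
#' @param code3 Character vector of three-letter residue codes.
#' @return `aa_one_letter()` returns the matching one-letter codes.
#' @export
aa_one_letter <- function(code3) {
  idx <- match(code3, AA_CODES$code3)
  if (anyNA(idx)) {
    stop("unknown residue code: ", paste(unique(code3[is.na(idx)]), collapse = ", "))
  }
  AA_CODES$code1[idx]
}

is_aa_code3 <- function(x) x %in% AA_CODES$code3

#' Physicochemical properties of the canonical residues
#'
#' Residue side-chain volumes (Zamyatnin, 1972; cubic angstroms), the
#' Kyte-Doolittle hydropathy index, and the conventional charge class at
#' physiological pH (Asp/Glu negative, Lys/Arg positive, all others --
#' including His -- neutral). These scales drive [property_delta()].
#'
#' The table is shipped as plain JSON under `extdata` so an alternative
#' scale can be supplied via `path`.
#'
#' @param path Optional path to a JSON file of the same shape
#'   (`{residue: {volume, hydropathy, charge_class}}`).
#' @return A data frame with columns `code3`, `volume`, `hydropathy`,
#'   `charge_class` (20 rows; `Ter` has no properties).
#' @export
#' @examples
#' residue_properties()
residue_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_properties.json",
                        package = "brca2triage", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path)
  props <- data.frame(
    code3 = names(raw),
    volume = vapply(raw, function(r) as.numeric(r$volume), numeric(1)),
    hydropathy = vapply(raw, function(r) as.numeric(r$hydropathy), numeric(1)),
    charge_class = vapply(raw, function(r) as.character(r$charge_class), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  bad <- setdiff(props$code3, AA_CODES$code3)
  if (length(bad)) stop("unknown residue in properties table: ", paste(bad, collapse = ", "))
  missing <- setdiff(setdiff(AA_CODES$code3, "Ter"), props$code3)
  if (length(missing)) stop("properties table missing residues: ", paste(missing, collapse = ", "))
  if (!all(props$charge_class %in% c("positive", "negative", "neutral"))) {
    stop("charge_class must be one of positive/negative/neutral")
  }
  props
}
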