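# Mapping of protein residue positions onto annotated functional-domain
# intervals. Intervals are closed and 1-based (UniProt residue numbering).
#
# A position is "inside" a domain when start <= position <= end for some
# domain entry; among several containing domains the smallest interval
# wins (then config order). Positions outside all domains but within
# `boundary_window` residues of an annotated edge are "boundary";
# everything else is "outside".
#
# Entries flagged `boundary_only` describe regions invoked in the
# literature only for near-edge assignments (for BRCA2, the C-terminal
# region abutting the DNA-binding domain): their edges participate in
# boundary detection, but their interior does not create "inside"
# assignments and they never escalate the prioritization rubric.

#' Load a domain-annotation config
#'
#' @param path Path to a JSON file of the form
#'   `{"boundary_window": int, "domains": [{"name", "start", "end",
#'   "critical", "boundary_only"?}, ...]}` (`boundary_only` defaults to
#'   false).
#' @return A data frame with columns `name`, `start`, `end`, `critical`,
#'   `boundary_only`, in file order, with the boundary window attached as
#'   attribute `boundary_window`.
#' @export
#' @examples
#' dom <- load_domain_config(brca2_example("domains"))
#' dom
load_domain_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  window <- if (!is.null(cfg$boundary_window)) as.integer(cfg$boundary_window) else 5L
  entries <- cfg$domains
  if (is.null(entries)) entries <- list()
  dom <- data.frame(
    name = vapply(entries, function(e) as.character(e$name), character(1)),
    start = vapply(entries, function(e) as.integer(e$start), integer(1)),
    end = vapply(entries, function(e) as.integer(e$end), integer(1)),
    critical = vapply(entries, function(e) isTRUE(e$critical), logical(1)),
    boundary_only = vapply(entries, function(e) isTRUE(e$boundary_only), logical(1)),
    stringsAsFactors = FALSE
  )
  domain_set(dom, boundary_window = window)
}

#' @rdname load_domain_config
#' @param domains Data frame with at least `name`, `start`, `end`,
#'   `critical` (optionally `boundary_only`).
#' @param boundary_window Non-negative integer, residues.
#' @export
domain_set <- function(domains, boundary_window = 5L) {
  if (is.null(domains$boundary_only)) domains$boundary_only <- rep(FALSE, nrow(domains))
  if (nrow(domains)) {
    if (any(domains$start < 1L) || any(domains$start > domains$end)) {
      bad <- which(domains$start > domains$end | domains$start < 1L)
      stop("invalid interval for domain(s): ", paste(domains$name[bad], collapse = ", "))
    }
    dup <- domains$name[duplicated(domains$name)]
    if (length(dup)) stop("duplicate domain name(s): ", paste(unique(dup), collapse = ", "))
  }
  if (boundary_window < 0L) stop("boundary_window must be >= 0")
  attr(domains, "boundary_window") <- as.integer(boundary_window)
  domains
}

#' Default BRCA2 domain annotation
#'
#' Four UniProt P51587 regions: the RAD51-binding BRC repeats
#' (1003-2082), the DNA-binding domain (2804-3054), the terminal portion
#' of the DBD (3052-3185) -- all three marked critical for the
#' prioritization rubric -- and the non-critical C-terminal region at the
#' DBD boundary (3190-3418), configured `boundary_only`.
#'
#' @return A domain set (see [load_domain_config()]).
#' @export
brca2_domains <- function() {
  load_domain_config(brca2_example("domains"))
}

#' Map residue positions onto a domain set
#'
#' @param position Integer vector of 1-based residue positions.
#' @param domains A domain set from [load_domain_config()] /
#'   [domain_set()].
#' @param boundary_window Residues; defaults to the window stored in the
#'   domain set (5 for the packaged BRCA2 config).
#' @return A data frame with one row per position: `position`,
#'   `category` (`"inside"`, `"boundary"`, `"outside"`), `domain` (the
#'   containing domain, or for boundary positions the entry with the
#'   nearest edge; `NA` outside), `critical` (logical; `FALSE` unless
#'   inside a critical domain) and `distance` (0 inside, residues to the
#'   nearest annotated edge otherwise).
#' @export
#' @examples
#' map_position(c(1089, 2947, 3187, 613), brca2_domains())
map_position <- function(position, domains, boundary_window = NULL) {
  if (is.null(boundary_window)) {
    boundary_window <- attr(domains, "boundary_window")
    if (is.null(boundary_window)) boundary_window <- 5L
  }
  stopifnot(all(position >= 1L), boundary_window >= 0L)
  n <- length(position)
  category <- rep("outside", n)
  domain <- rep(NA_character_, n)
  critical <- rep(FALSE, n)
  distance <- rep(NA_integer_, n)
  if (!nrow(domains)) {
    return(data.frame(position = position, category = category, domain = domain,
                      critical = critical, distance = distance,
                      stringsAsFactors = FALSE))
  }
  span <- domains$end - domains$start
  for (i in seq_len(n)) {
    p <- position[i]
    inside <- which(!domains$boundary_only & domains$start <= p & p <= domains$end)
    if (length(inside)) {
      pick <- inside[order(span[inside], inside)][1]
      category[i] <- "inside"
      domain[i] <- domains$name[pick]
      critical[i] <- domains$critical[pick]
      distance[i] <- 0L
    } else {
      edge_dist <- pmin(abs(p - domains$start), abs(p - domains$end))
      pick <- order(edge_dist, seq_len(nrow(domains)))[1]
      distance[i] <- as.integer(edge_dist[pick])
      if (edge_dist[pick] <= boundary_window) {
        category[i] <- "boundary"
        domain[i] <- domains$name[pick]
      }
    }
  }
  data.frame(position = position, category = category, domain = domain,
             critical = critical, distance = distance, stringsAsFactors = FALSE)
}

#' Domain assignment for every variant in a table
#'
#' @param vt A [variant_table()].
#' @inheritParams map_position
#' @return A data frame keyed by variant key with the columns of
#'   [map_position()].
#' @export
#' @examples
#' assign_domains(read_variant_table(brca2_example("variants")), brca2_domains())
assign_domains <- function(vt, domains = brca2_domains(), boundary_window = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  rec <- vt$records
  if (!nrow(rec)) {
    return(data.frame(key = character(0), position = integer(0),
                      category = character(0), domain = character(0),
                      critical = logical(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- map_position(rec$position, domains, boundary_window)
  cbind(data.frame(key = rec$key, stringsAsFactors = FALSE), out)
}
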