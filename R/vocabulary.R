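#' Canonical subcellular location vocabularies
#'
#' Bacterial protein localization is predicted against a fixed set of
#' compartments: five for Gram-negative organisms (extracellular,
#' outer membrane, periplasm, inner membrane, cytoplasm) and four for
#' Gram-positive organisms (extracellular, cell wall, inner membrane,
#' cytoplasm). The canonical order is fixed: it defines score-matrix
#' column order and the tie-breaking order of every argmax decision.
#'
#' @param kind `"gram_negative"` or `"gram_positive"`.
#' @return An object of class `location_vocabulary`: a list with
#'   `kind`, `locations` (ordered character vector of canonical names)
#'   and `aliases` (named character vector mapping normalized free-text
#'   location strings to canonical names).
#' @examples
#' location_vocabulary("gram_negative")$locations
#' @export
location_vocabulary <- function(kind = c("gram_negative", "gram_positive")) {
  kind <- match.arg(kind)
  locations <- switch(kind,
    gram_negative = c("extracellular", "outer_membrane", "periplasm",
                      "inner_membrane", "cytoplasm"),
    gram_positive = c("extracellular", "cell_wall", "inner_membrane",
                      "cytoplasm"))
  alias_map <- c(
    "extracellular"        = "extracellular",
    "extracellular region" = "extracellular",
    "extracellular space"  = "extracellular",
    "secreted"             = "extracellular",
    "outer membrane"       = "outer_membrane",
    "periplasm"            = "periplasm",
    "periplasmic"          = "periplasm",
    "periplasmic space"    = "periplasm",
    "inner membrane"       = "inner_membrane",
    "cytoplasmic membrane" = "inner_membrane",
    "plasma membrane"      = "inner_membrane",
    "cell membrane"        = "inner_membrane",
    "cytoplasm"            = "cytoplasm",
    "cytosol"              = "cytoplasm",
    "cell wall"            = "cell_wall")
  aliases <- alias_map[alias_map %in% locations]
  structure(list(kind = kind, locations = locations, aliases = aliases),
            class = "location_vocabulary")
}

# lower-case, trim, collapse runs of whitespace/underscores to one space
.norm_location <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[_[:space:]]+", " ", x)
}

#' Resolve free-text location strings to canonical names
#'
#' Matching is case-insensitive; internal whitespace and underscores are
#' collapsed, so `"Cell wall"`, `"cell_wall"` and `"CELL  WALL"` all
#' resolve to `cell_wall`.
#'
#' @param x Character vector of location strings.
#' @param vocabulary A [location_vocabulary()].
#' @return Character vector of canonical location names.
#' @export
resolve_location <- function(x, vocabulary) {
  stopifnot(inherits(vocabulary, "location_vocabulary"))
  canonical <- vocabulary$aliases[.norm_location(x)]
  bad <- is.na(canonical)
  if (any(bad)) {
    stop("unknown location string(s) for ", vocabulary$kind, " vocabulary: ",
         paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
  }
  unname(canonical)
}

#' @export
print.location_vocabulary <- function(x, ...) {
  cat("<location_vocabulary> ", x$kind, ": ",
      paste(x$locations, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' One-hot encode a predicted location
#'
#' Label-only base predictors report a single compartment; it is encoded
#' as 1 at the location's canonical index and 0 elsewhere so that
#' label-only and probabilistic predictors are commensurable.
#'
#' @param predicted_location Location string (aliases accepted).
#' @param vocabulary A [location_vocabulary()].
#' @return Named numeric vector of length `m` summing to 1.
#' @examples
#' one_hot_encode("periplasm", location_vocabulary("gram_negative"))
#' @export
one_hot_encode <- function(predicted_location, vocabulary) {
  canonical <- resolve_location(predicted_location, vocabulary)
  stopifnot(length(canonical) == 1L)
  v <- stats::setNames(numeric(length(vocabulary$locations)),
                       vocabulary$locations)
  v[canonical] <- 1
  v
}
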