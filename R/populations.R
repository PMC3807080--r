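# Population taxonomy: nine geographical groups used throughout the curation
# pipeline. The synonym table is shipped as data (extdata) so users can extend
# it; unknown labels are hard errors because every downstream classification
# depends on correct grouping.

.pop_canonical <- c(
  "European", "EastAsian", "WestAsian", "SouthAsian", "SouthAmerican",
  "CentralAmerican", "NorthAfrican", "SouthAfrican", "AfricanAmerican"
)

#' Canonical population labels
#'
#' The nine geographical population groups used to assess reproducibility of
#' genetic associations. Every study population must resolve to exactly one of
#' these via [resolve_population()].
#'
#' @return Character vector of the nine canonical labels.
#' @export
#' @examples
#' population_labels()
population_labels <- function() .pop_canonical

# normalization applied to both synonyms and queries: case-insensitive,
# whitespace-collapsed, hyphens and underscores treated as spaces
.pop_normalize <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[-_]+", " ", x)
  gsub("[[:space:]]+", " ", x)
}

.pop_env <- new.env(parent = emptyenv())

#' Population synonym table
#'
#' Mapping from reported study-population labels (e.g. "European American",
#' "South-East Asian") to the nine canonical groups. Loaded once from the
#' packaged tab-separated table; `path` allows substituting an extended table.
#'
#' @param path Optional path to an alternative two-column TSV
#'   (`synonym`, `canonical`).
#' @return Tibble with columns `synonym` and `canonical`.
#' @export
population_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pop_env$synonyms)) return(.pop_env$synonyms)
    path <- system.file("extdata", "population_synonyms.tsv",
                        package = "ravarkit", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("synonym", "canonical") %in% names(tab)))
  bad <- setdiff(unique(tab$canonical), .pop_canonical)
  if (length(bad) > 0) {
    stop("synonym table maps to non-canonical population(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- .pop_normalize(tab$synonym)
  if (anyDuplicated(key)) {
    dup <- unique(tab$synonym[duplicated(key)])
    stop("synonym table is ambiguous for: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(synonym = tab$synonym, canonical = tab$canonical)
  if (cache) .pop_env$synonyms <- out
  out
}

#' Resolve a reported population label to its canonical group
#'
#' Lookup is case-insensitive and whitespace-normalized (hyphens and
#' underscores count as spaces), so `"south-east asian"` and
#' `"South-East Asian"` both resolve to `"EastAsian"`. Canonical labels
#' resolve to themselves. Unknown labels raise an error naming the offending
#' label: silent coercion would corrupt the population grouping on which the
#' reproducibility classes rest.
#'
#' @param raw_label Character vector of reported labels.
#' @return Character vector of canonical labels, same length as `raw_label`.
#' @export
#' @examples
#' resolve_population(c("European American", "South-East Asian"))
resolve_population <- function(raw_label) {
  if (length(raw_label) == 0) return(character(0))
  if (!is.character(raw_label) || anyNA(raw_label) || any(!nzchar(trimws(raw_label)))) {
    stop("population labels must be non-empty strings", call. = FALSE)
  }
  syn <- population_synonyms()
  map <- stats::setNames(syn$canonical, .pop_normalize(syn$synonym))
  hit <- map[.pop_normalize(raw_label)]
  if (anyNA(hit)) {
    unknown <- unique(raw_label[is.na(hit)])
    stop("unknown population label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(hit)
}
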