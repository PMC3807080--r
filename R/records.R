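# Association records: one row = one variant x one study x one population.
# The tabular contract mirrors what is extracted from the literature: P-value,
# odds ratio and risk allele as published, case/control counts, genotyping
# coverage (genome-wide vs selected markers) and study design.

.assoc_required_cols <- c(
  "study_id", "variant_id", "risk_allele", "p_value", "odds_ratio",
  "n_cases", "n_controls", "population", "coverage", "design"
)
.coverage_levels <- c("genome_wide", "selected")
.design_levels <- c("gwas", "followup", "meta_of_gwas", "combined_gwas_replication")

#' Validate a table of association records
#'
#' Checks the field-level invariants of an association table and canonicalizes
#' its population labels. Required columns: `study_id`, `variant_id`,
#' `risk_allele` (optional values), `p_value`, `odds_ratio` (optional values),
#' `n_cases`, `n_controls`, `population`, `coverage`, `design`. An optional
#' `phenotype_note` column is carried through, as is any `locus_id` column.
#'
#' Enforced invariants: `p_value` in (0, 1]; `odds_ratio` > 0 when present;
#' `n_cases` and `n_controls` >= 1; `coverage` in `{genome_wide, selected}`;
#' `design` in `{gwas, followup, meta_of_gwas, combined_gwas_replication}`;
#' `(variant_id, study_id, population)` unique within the table.
#'
#' @param records Data frame of association records.
#' @return Validated tibble with `population` canonicalized.
#' @export
validate_association_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.assoc_required_cols, names(records))
  if (length(missing_cols) > 0) {
    stop("association table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail <- function(row, msg) {
    stop(sprintf("invalid association record (row %d): %s", row, msg),
         call. = FALSE)
  }
  first_bad <- function(ok, msg) {
    if (!all(ok)) fail(which(!ok)[1], msg)
  }

  first_bad(!is.na(records$study_id) & nzchar(records$study_id),
            "study_id must be non-empty")
  first_bad(!is.na(records$variant_id) & nzchar(records$variant_id),
            "variant_id must be non-empty")
  p <- records$p_value
  first_bad(!is.na(p) & p > 0 & p <= 1, "p_value must lie in (0, 1]")
  or <- records$odds_ratio
  first_bad(is.na(or) | or > 0, "odds_ratio must be positive when present")
  first_bad(!is.na(records$n_cases) & records$n_cases >= 1 &
              records$n_cases == round(records$n_cases),
            "n_cases must be a positive integer")
  first_bad(!is.na(records$n_controls) & records$n_controls >= 1 &
              records$n_controls == round(records$n_controls),
            "n_controls must be a positive integer")
  first_bad(records$coverage %in% .coverage_levels,
            paste("coverage must be one of:",
                  paste(.coverage_levels, collapse = ", ")))
  first_bad(records$design %in% .design_levels,
            paste("design must be one of:",
                  paste(.design_levels, collapse = ", ")))

  records$population <- resolve_population(records$population)

  key <- paste(records$variant_id, records$study_id, records$population,
               sep = "\r")
  if (anyDuplicated(key)) {
    fail(which(duplicated(key))[1],
         "duplicate (variant_id, study_id, population) key")
  }
  records
}

#' Read an association table from tab-separated text
#'
#' The file must carry a header row with the canonical column names (see
#' [validate_association_records()]). Empty strings and `"."` denote missing
#' values for the optional `risk_allele` and `odds_ratio` fields. Every row is
#' validated; the first failure is reported with its row number.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @return Validated tibble of association records.
#' @export
read_association_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.assoc_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("association table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  blank_to_na <- function(x) ifelse(x == "" | x == ".", NA_character_, x)
  num <- function(x, col) {
    x <- blank_to_na(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("malformed numeric in column '%s' (row %d): '%s'",
                   col, bad[1], x[bad[1]]), call. = FALSE)
    }
    out
  }
  records <- tibble::tibble(
    study_id = raw$study_id,
    variant_id = raw$variant_id,
    risk_allele = blank_to_na(raw$risk_allele),
    p_value = num(raw$p_value, "p_value"),
    odds_ratio = num(raw$odds_ratio, "odds_ratio"),
    n_cases = num(raw$n_cases, "n_cases"),
    n_controls = num(raw$n_controls, "n_controls"),
    population = raw$population,
    coverage = raw$coverage,
    design = raw$design
  )
  if ("phenotype_note" %in% names(raw)) {
    records$phenotype_note <- blank_to_na(raw$phenotype_note)
  }
  if ("locus_id" %in% names(raw)) {
    records$locus_id <- blank_to_na(raw$locus_id)
  }
  validate_association_records(records)
}

#' Write an association table as tab-separated text
#'
#' Inverse of [read_association_table()]: missing optional values are written
#' as empty strings and numeric columns keep full precision so values
#' (including extreme p-values such as 1e-299) round-trip exactly.
#'
#' @param records Association records (validated or validatable).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(records, path) {
  records <- validate_association_records(records)
  out <- records
  out$p_value <- .fmt_num(out$p_value, digits = 15)
  out$odds_ratio <- .fmt_num(out$odds_ratio, digits = 15)
  out$n_cases <- .fmt_num(out$n_cases, digits = 15)
  out$n_controls <- .fmt_num(out$n_controls, digits = 15)
  .write_tsv(out, path)
}
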